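#include <Rcpp.h>
using namespace Rcpp;

// Exact Kalman recursion for the unit-variance OUF position process on
// irregular times. The state is (position, velocity) with stationary
// covariance diag(1, 1/(tau_r*tau_v)); positions are observed without
// noise. The filter is run simultaneously on the x series, the y series
// and a constant-ones series so the stationary mean can be profiled out by
// generalized least squares, and returns the innovation decomposition
// quantities of the correlation matrix R:
//   logdet = log|R|,  S11 = 1' R^-1 1,  Sx1 = x' R^-1 1,  Sxx = x' R^-1 x
// (and the y analogues).
// [[Rcpp::export]]
List ouf_profile_cpp(NumericVector times, NumericVector x, NumericVector y,
                     double tau_r, double tau_v) {
  int n = times.size();
  double a = 1.0 / tau_r, b = 1.0 / tau_v;
  double vv = a * b; // stationary velocity variance (unit position variance)

  // predicted state means for the three signals and shared covariance
  double mx[2] = {0, 0}, my[2] = {0, 0}, m1[2] = {0, 0};
  double P00 = 1.0, P01 = 0.0, P11 = vv;

  double logdet = 0, S11 = 0, Sx1 = 0, Sy1 = 0, Sxx = 0, Syy = 0;

  for (int i = 0; i < n; i++) {
    double s = P00;
    double ex = x[i] - mx[0];
    double ey = y[i] - my[0];
    double e1 = 1.0 - m1[0];
    logdet += std::log(s);
    S11 += e1 * e1 / s;
    Sx1 += ex * e1 / s;
    Sy1 += ey * e1 / s;
    Sxx += ex * ex / s;
    Syy += ey * ey / s;

    // exact-observation update: K = P[,0]/s
    double K0 = 1.0, K1 = P01 / s;
    mx[0] += K0 * ex; mx[1] += K1 * ex;
    my[0] += K0 * ey; my[1] += K1 * ey;
    m1[0] += K0 * e1; m1[1] += K1 * e1;
    // P <- P - outer(P[,0], P[0,]) / s
    double uP00 = 0.0, uP01 = 0.0, uP11 = P11 - P01 * P01 / s;

    if (i == n - 1) break;
    double dt = times[i + 1] - times[i];
    double ea = std::exp(-a * dt), eb = std::exp(-b * dt), den = b - a;
    double F00 = (b * ea - a * eb) / den;
    double F01 = (ea - eb) / den;
    double F10 = a * b * (eb - ea) / den;
    double F11 = (b * eb - a * ea) / den;

    // m_pred = F m
    double nmx0 = F00 * mx[0] + F01 * mx[1], nmx1 = F10 * mx[0] + F11 * mx[1];
    double nmy0 = F00 * my[0] + F01 * my[1], nmy1 = F10 * my[0] + F11 * my[1];
    double nm10 = F00 * m1[0] + F01 * m1[1], nm11 = F10 * m1[0] + F11 * m1[1];
    mx[0] = nmx0; mx[1] = nmx1;
    my[0] = nmy0; my[1] = nmy1;
    m1[0] = nm10; m1[1] = nm11;

    // P_pred = F P F' + Q,  Q = Pinf - F Pinf F'
    double FP00 = F00 * uP00 + F01 * uP01, FP01 = F00 * uP01 + F01 * uP11;
    double FP10 = F10 * uP00 + F11 * uP01, FP11 = F10 * uP01 + F11 * uP11;
    double PP00 = FP00 * F00 + FP01 * F01;
    double PP01 = FP00 * F10 + FP01 * F11;
    double PP11 = FP10 * F10 + FP11 * F11;
    // Q entries from Pinf = diag(1, vv)
    double Q00 = 1.0 - (F00 * F00 + vv * F01 * F01);
    double Q01 = -(F00 * F10 + vv * F01 * F11);
    double Q11 = vv - (F10 * F10 + vv * F11 * F11);
    P00 = PP00 + Q00;
    P01 = PP01 + Q01;
    P11 = PP11 + Q11;
    if (P00 < 1e-300) P00 = 1e-300; // guard against underflow at tiny gaps
  }

  return List::create(_["logdet"] = logdet, _["S11"] = S11,
                      _["Sx1"] = Sx1, _["Sy1"] = Sy1,
                      _["Sxx"] = Sxx, _["Syy"] = Syy);
}
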