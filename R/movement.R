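# Continuous-time movement models per moving window: exact Gaussian-process
# maximum likelihood for the IID / OU / OUF families evaluated in O(n) by
# sequential conditioning (innovation / Kalman decomposition) on irregular
# times, AICc selection, and the derived movement metrics.

#' Empirical semivariogram of a track subset
#'
#' 2-D convention: the semivariance at lag tau is the mean over fix pairs in
#' the lag bin of |position difference|^2 / 4, so the sill of a stationary
#' isotropic process equals the per-axis variance. Bins are multiples of the
#' nominal fix interval.
#'
#' @param subset data.frame with `t`, `x`, `y`.
#' @param interval bin width in seconds; default the median fix interval.
#' @return data.frame(lag, semivariance, n_pairs).
#' @export
empirical_variogram <- function(subset, interval = NULL) {
  n <- nrow(subset)
  if (n < 2L) stop("need at least 2 fixes")
  tt <- as.numeric(subset$t)
  if (is.null(interval)) interval <- median(diff(sort(tt)))
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  lag <- tt[jj] - tt[ii]
  sq <- ((subset$x[jj] - subset$x[ii])^2 +
         (subset$y[jj] - subset$y[ii])^2) / 4
  bin <- round(lag / interval)
  sv <- tapply(sq, bin, mean)
  np <- tapply(sq, bin, length)
  data.frame(lag = as.numeric(names(sv)) * interval,
             semivariance = as.numeric(sv), n_pairs = as.numeric(np))
}

# innovation-decomposition statistics of the unit-variance correlation
# structure R for each family: logdet = log|R| and the quadratic forms
# needed to profile the mean and variance out of the likelihood.
.profile_stats <- function(tt, x, y, family, tau_r = NULL, tau_v = NULL) {
  n <- length(tt)
  if (family == "IID") {
    list(logdet = 0, S11 = n, Sx1 = sum(x), Sy1 = sum(y),
         Sxx = sum(x^2), Syy = sum(y^2))
  } else if (family == "OU") {
    phi <- exp(-diff(tt) / tau_r)
    s <- c(1, 1 - phi^2)
    e1 <- c(1, 1 - phi)
    ex <- c(x[1], x[-1] - phi * x[-n])
    ey <- c(y[1], y[-1] - phi * y[-n])
    list(logdet = sum(log(s)), S11 = sum(e1^2 / s),
         Sx1 = sum(ex * e1 / s), Sy1 = sum(ey * e1 / s),
         Sxx = sum(ex^2 / s), Syy = sum(ey^2 / s))
  } else {
    ouf_profile_cpp(tt, x, y, tau_r, tau_v)
  }
}

# profiled ML given structure stats: GLS mean, pooled isotropic variance,
# and the joint log-likelihood over both axes.
.profile_ml <- function(st, n) {
  mux <- st$Sx1 / st$S11
  muy <- st$Sy1 / st$S11
  Qx <- st$Sxx - st$Sx1^2 / st$S11
  Qy <- st$Syy - st$Sy1^2 / st$S11
  sigma2 <- (Qx + Qy) / (2 * n)
  ll <- -(n * log(2 * pi) + n * log(sigma2) + st$logdet + n)
  list(mean = c(mux, muy), sigma2 = sigma2, loglik = ll)
}

#' Exact Gaussian-process log-likelihood of a movement model
#'
#' Evaluates the joint log-density of both coordinate axes under the
#' model's family and parameters via the O(n) innovation decomposition
#' (no profiling; all parameters taken from `model`).
#'
#' @param subset track subset (`t`, `x`, `y`).
#' @param model an `rm_model` or a list with fields `family`, `mean`,
#'   `sigma2`, `tau_range`, `tau_velocity`.
#' @return scalar log-likelihood.
#' @export
loglik_movement <- function(subset, model) {
  tt <- as.numeric(subset$t)
  n <- length(tt)
  st <- .profile_stats(tt, subset$x, subset$y, model$family,
                       model$tau_range, model$tau_velocity)
  qf <- function(S_dd, S_d1, mu) S_dd - 2 * mu * S_d1 + mu^2 * st$S11
  Qx <- qf(st$Sxx, st$Sx1, model$mean[1])
  Qy <- qf(st$Syy, st$Sy1, model$mean[2])
  -0.5 * (2 * n * log(2 * pi) + 2 * n * log(model$sigma2) + 2 * st$logdet +
            (Qx + Qy) / model$sigma2)
}

#' Fit a continuous-time movement model by exact maximum likelihood
#'
#' Per-axis Gaussian process with isotropic variance: IID (white noise about
#' a mean), OU (exponential position autocovariance, range residency) or OUF
#' (autocorrelated velocity, finite mean speed). The stationary mean and the
#' variance are profiled out analytically, leaving a 1-D (OU) or 2-D (OUF)
#' optimization over timescales, started from variogram-informed values with
#' fixed restarts.
#'
#' @param subset track subset with `t`, `x`, `y` (projected metres).
#' @param family "IID", "OU" or "OUF".
#' @param min_fixes minimum fixes to attempt a fit.
#' @return object of class `rm_model`: family, mean, sigma2, tau_range,
#'   tau_velocity, loglik, n, effective_n_area, converged.
#' @export
fit_movement_model <- function(subset, family = c("IID", "OU", "OUF"),
                               min_fixes = 8) {
  family <- match.arg(family)
  tt <- as.numeric(subset$t)
  n <- length(tt)
  if (n < min_fixes) stop("too few fixes (", n, ") for a model fit")
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  x <- subset$x; y <- subset$y
  span <- tt[n] - tt[1]
  dt_med <- median(diff(tt))

  if (var(x) + var(y) < 1e-12) {          # degenerate geometry
    return(.rm_model("IID", c(mean(x), mean(y)), 1e-12, NULL, NULL,
                     loglik = NA_real_, n = n, n_eff = n, converged = FALSE))
  }

  if (family == "IID") {
    ml <- .profile_ml(.profile_stats(tt, x, y, "IID"), n)
    return(.rm_model("IID", ml$mean, ml$sigma2, NULL, NULL, ml$loglik, n,
                     n_eff = n, converged = TRUE))
  }

  if (family == "OU") {
    nll <- function(ltau) -.profile_ml(
      .profile_stats(tt, x, y, "OU", tau_r = exp(ltau)), n)$loglik
    opt <- optimize(nll, c(log(dt_med / 10), log(span * 10)))
    tau <- exp(opt$minimum)
    ml <- .profile_ml(.profile_stats(tt, x, y, "OU", tau_r = tau), n)
    return(.rm_model("OU", ml$mean, ml$sigma2, tau, NULL, ml$loglik, n,
                     n_eff = span / tau, converged = TRUE))
  }

  # OUF: theta = (log tau_r, logit of tau_v / tau_r), tau_v < tau_r enforced
  nll <- function(th) {
    tr <- exp(th[1])
    tv <- tr * plogis(th[2]) * 0.999
    if (!is.finite(tr) || !is.finite(tv) || tv <= 0) return(1e10)
    val <- tryCatch(
      -.profile_ml(.profile_stats(tt, x, y, "OUF", tr, tv), n)$loglik,
      error = function(e) 1e10)
    if (!is.finite(val)) 1e10 else val
  }
  ou <- fit_movement_model(subset, "OU", min_fixes)
  tr0 <- max(ou$tau_range, dt_med)
  starts <- list(c(log(tr0), qlogis(min(0.9, dt_med / 2 / tr0))),
                 c(log(tr0), qlogis(min(0.9, dt_med / tr0 / 4))),
                 c(log(4 * tr0), qlogis(0.25)))
  best <- NULL
  for (s0 in starts) {
    o <- optim(s0, nll, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  tau_r <- exp(best$par[1])
  tau_v <- tau_r * plogis(best$par[2]) * 0.999
  ml <- .profile_ml(.profile_stats(tt, x, y, "OUF", tau_r, tau_v), n)
  .rm_model("OUF", ml$mean, ml$sigma2, tau_r, tau_v, ml$loglik, n,
            n_eff = span / tau_r,
            converged = best$convergence == 0 && best$value < 1e9)
}

.rm_model <- function(family, mean, sigma2, tau_r, tau_v, loglik, n, n_eff,
                      converged) {
  structure(list(family = family, mean = mean, sigma2 = sigma2,
                 tau_range = tau_r, tau_velocity = tau_v,
                 loglik = loglik, n = n, effective_n_area = n_eff,
                 converged = converged),
            class = "rm_model")
}

#' @export
print.rm_model <- function(x, ...) {
  cat(sprintf("<rm_model %s> n=%d  sigma2=%.1f m^2", x$family, x$n, x$sigma2))
  if (!is.null(x$tau_range))
    cat(sprintf("  tau_r=%.2f h", x$tau_range / 3600))
  if (!is.null(x$tau_velocity))
    cat(sprintf("  tau_v=%.2f h", x$tau_velocity / 3600))
  cat(sprintf("  logLik=%.2f\n", x$loglik))
  invisible(x)
}

# free parameters per family under isotropy (mean 2, variance 1, timescales)
.rm_k <- c(IID = 3, OU = 4, OUF = 5)

#' Small-sample AIC of a fitted movement model
#' @param model an `rm_model`. The observation count is the number of scalar
#'   coordinates, twice the fix count.
#' @export
aicc <- function(model) {
  k <- .rm_k[[model$family]]
  N <- 2 * model$n
  -2 * model$loglik + 2 * k + 2 * k * (k + 1) / (N - k - 1)
}

#' Fit all candidate families and select by AICc
#'
#' Fits IID, OU and OUF (skipping any family with too few observations for
#' its AICc to be defined) and returns the minimum-AICc model; exact ties
#' break toward fewer parameters. Returns `NULL` with a reason attribute if
#' every fit fails.
#'
#' @inheritParams fit_movement_model
#' @param families candidate families, in increasing parameter order.
#' @export
select_model <- function(subset, families = c("IID", "OU", "OUF"),
                         min_fixes = 8) {
  fits <- list()
  for (fam in families) {
    k <- .rm_k[[fam]]
    if (nrow(subset) < k + 2 || 2 * nrow(subset) - k - 1 <= 0) next
    f <- tryCatch(fit_movement_model(subset, fam, min_fixes),
                  error = function(e) NULL)
    if (!is.null(f) && isTRUE(f$converged) && is.finite(f$loglik))
      fits[[fam]] <- f
  }
  if (length(fits) == 0L) {
    out <- NULL
    attr(out, "reason") <- "all model fits failed"
    return(out)
  }
  ic <- vapply(fits, aicc, numeric(1))
  # fits are in increasing-k order, so strict improvement breaks ties
  # toward parsimony
  best <- names(fits)[1]
  for (fam in names(fits)[-1]) if (ic[[fam]] < ic[[best]] - 1e-9) best <- fam
  model <- fits[[best]]
  attr(model, "aicc") <- ic
  model
}

#' Diffusion rate of a fitted model
#'
#' One quarter of the maximal growth rate of the 2-D mean square
#' displacement over time lag, from the family's closed-form MSD. For OU
#' this is `sigma2 / tau_range` exactly; for OUF the maximizing lag is
#' located numerically on a log-spaced grid and refined. Undefined (NA) for
#' IID, which has no autocorrelation timescale.
#'
#' @param model an `rm_model`.
#' @return diffusion in km^2/day, or NA for IID.
#' @export
diffusion_rate <- function(model) {
  to_km2_day <- 86400 / 1e6
  if (model$family == "IID") {
    out <- NA_real_
    attr(out, "reason") <- "no autocorrelation timescale"
    return(out)
  }
  if (model$family == "OU")
    return(model$sigma2 / model$tau_range * to_km2_day)
  tr <- model$tau_range; tv <- model$tau_velocity
  # d MSD / d tau = 4 sigma2 (e^(-tau/tr) - e^(-tau/tv)) / (tr - tv)
  slope <- function(ltau) {
    tau <- exp(ltau)
    (exp(-tau / tr) - exp(-tau / tv)) / (tr - tv)
  }
  grid <- seq(log(tv / 100), log(tr * 100), length.out = 200)
  i <- which.max(vapply(grid, slope, numeric(1)))
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(slope, c(lo, hi), maximum = TRUE)
  model$sigma2 * opt$objective * to_km2_day
}

#' Mean daily distance travelled under a fitted OUF model
#'
#' Plug-in stationary mean speed: the 2-D velocity is Gaussian with per-axis
#' variance `sigma2 / (tau_range * tau_velocity)`, so the mean speed is
#' `sigma_v * sqrt(pi/2)` (Rayleigh mean) and the daily distance is that
#' times 86 400 s. Only the OUF family has autocorrelated velocity and hence
#' a finite mean speed; OU/IID return NA with a reason.
#'
#' @param model an `rm_model`.
#' @return km/day, or NA when the family has no velocity autocorrelation.
#' @export
mean_daily_distance <- function(model) {
  if (model$family != "OUF") {
    out <- NA_real_
    attr(out, "reason") <- "no velocity autocorrelation"
    return(out)
  }
  sigma_v <- sqrt(model$sigma2 / (model$tau_range * model$tau_velocity))
  sigma_v * sqrt(pi / 2) * 86400 / 1000
}

#' Filter window estimates by home-range plausibility
#'
#' Estimates whose 95% home-range area exceeds `hr_cap` (strictly) are
#' marked invalid with reason "range-residency": such windows lack range
#' residency and produce excessively large areas.
#'
#' @param estimates data.frame of window estimates with an `hr95_area` (km^2)
#'   column and logical `valid`.
#' @param hr_cap cap in km^2 (default 10).
#' @return list(estimates, report = c(removed, total, pct)).
#' @export
filter_estimates <- function(estimates, hr_cap = 10) {
  bad <- !is.na(estimates$hr95_area) & estimates$hr95_area > hr_cap &
    estimates$valid
  estimates$valid[bad] <- FALSE
  estimates$exclusion_reason[bad] <- "range-residency"
  n_tot <- sum(!is.na(estimates$hr95_area))
  list(estimates = estimates,
       report = c(removed = sum(bad), total = n_tot,
                  pct = if (n_tot > 0) 100 * sum(bad) / n_tot else 0))
}
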