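---
title: "Models and methods behind rutmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rutmove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rutmove)
```

rutmove implements a treatment/control biologging analysis of
breeding-season movement and activity in white-tailed deer. This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic data do and do not establish.

## Continuous-time movement models

Each coordinate axis of a projected track is modelled as a stationary
Gaussian process around a home-range centre, isotropic across axes (one
shared variance; the data offer no evidence for anisotropy in 7-day
windows, and halving the parameter count matters at 168 fixes):

* **IID** — white noise, variance $\sigma^2$: no autocorrelation.
* **OU** — autocovariance $\sigma^2 e^{-\tau/\tau_r}$: range residency with
  range-crossing timescale $\tau_r$.
* **OUF** — autocovariance
  $\sigma^2(\tau_r e^{-\tau/\tau_r} - \tau_v e^{-\tau/\tau_v})/(\tau_r-\tau_v)$:
  adds an autocorrelated velocity with timescale $\tau_v < \tau_r$, giving
  a finite mean speed.

The log-likelihood is evaluated exactly in $O(n)$ by sequential Gaussian
conditioning: OU is an AR(1) recursion on the irregular gaps; OUF runs a
2-state (position, velocity) Kalman filter (in C++) whose transition matrix
is the closed-form matrix exponential of the companion form with rates
$1/\tau_r, 1/\tau_v$. Positions are observed without error (a GPS
error model is out of scope). The stationary mean is profiled out by
generalized least squares via a parallel filter pass on a constant series,
and the variance is profiled in closed form, so optimization is a 1-D
search over $\log\tau_r$ (OU) or a 2-D Nelder–Mead over
$(\log\tau_r, \mathrm{logit}(\tau_v/\tau_r))$ with three fixed starts
(OUF). Tests verify the filter equals a dense multivariate-normal
log-density to $10^{-6}$ relative on random irregular instances.

Model selection uses AICc with $k = 3, 4, 5$ free parameters and the
observation count taken as the number of scalar coordinates ($2n$); exact
ties break toward fewer parameters. With a 10-minute default velocity
timescale and 1-h fixes, OUF wins for roughly 60% of windows — the same
partial-availability regime the original collars produced for daily
distance.

The simulator draws from the *exact* Gaussian transition of each family
(no Euler discretization), so simulation-based tests compare estimators
against their true generating values with no discretization bias.
Seasonal modulation rescales a unit-variance process so the marginal
variance tracks $\sigma^2(t)$ exactly while autocorrelation is unchanged.

## Windows, time axis, cleaning

Windows are 7 days long sliding by 3, half-open $[s, s+7)$ so no fix is
counted twice at a boundary, with starts at multiples of 3 on the
days-after-1-August axis. That axis is calendar-based in local time
(America/New_York): whole local days plus the fraction of the clock day,
so 10 November 00:00 is exactly day 101 across the autumn DST change.
The only cost is that the repeated 01:00–02:00 hour at the fall-back
transition maps two instants to one index — irrelevant at 1-h fixes after
duplicate-timestamp removal. A window needs at least 24 fixes for a fit
attempt (below that even the IID fit is unstable); failures are flagged,
never dropped silently.

Cleaning removes fixes outside deployment, duplicate timestamps (first
kept), and any fix requiring straight-line speeds above 5 m/s from *both*
neighbours — deer sprint faster briefly but do not sustain it across 1-h
gaps. The speed rule iterates to a fixed point, which makes cleaning
idempotent. Tracks are projected to a local plane with a spherical
azimuthal equidistant projection centred at the animal-year's median fix
(mean Earth radius 6 371 008.8 m); over the ≤20 km extents of deer ranges
the distortion is far below GPS noise. Animals tracked under 28 days are
excluded (closed threshold: 28.0 days is included).

## Home range, diffusion, speed, excursivity

The utilization distribution is a Gaussian-kernel density over the
window's fixes on a 201×201 grid spanning the fitted mean ±5σ̂ (expanded
to cover all fixes), with per-axis bandwidth
$h^2 = \hat\sigma^2 N_{\mathrm{eff}}^{-1/3}$ and
$N_{\mathrm{eff}} = \mathrm{span}/\hat\tau_r$ — the Gaussian reference
rule with the autocorrelation-corrected effective sample size that
distinguishes the estimator from naive KDE. Kernel smoothing inflates the
density's variance by $h^2$, which at moderate $N_{\mathrm{eff}}$ biases
HDR areas upward by tens of percent, so the kernel centres are shrunk
about their centroid to preserve the empirical variance; in the
stationary-OU limit the 95% area is then unbiased against the closed form
$-2\pi\sigma^2\ln(0.05)$ (verified to 5% in the mean over seeds).
Windows with $N_{\mathrm{eff}} < 3$ are flagged as lacking range
residency, and estimates above 10 km² are removed post hoc with reason
"range-residency" (strictly greater: 10.0 km² is retained).

Diffusion is one quarter of the maximal slope of the 2-D mean square
displacement: $\sigma^2/\tau_r$ exactly for OU; for OUF the maximizing lag
is found on a log grid with refinement (the closed-form argmax
$\tau^* = \tau_r\tau_v\ln(\tau_r/\tau_v)/(\tau_r-\tau_v)$ serves as the
test oracle). Mean daily distance is the plug-in stationary mean speed
$\sigma_v\sqrt{\pi/2}\cdot 86\,400$ with
$\sigma_v^2=\sigma^2/(\tau_r\tau_v)$, a deliberate simplification of
trajectory-conditional speed estimation: the trend models consume only the
window mean, which this matches in expectation for OUF. OU/IID windows
have no finite mean speed and return an absent value with a reason.

Excursivity is the daily mean HDR mass at the animal's fixes under its
annual UD: the probability mass of the smallest highest-density region
containing each fix. The direction (large = peripheral) makes "more
excursive during the rut" an increasing signal. The convention could
equally have been a radial CDF; HDR mass was chosen because it is
invariant to the density's parameterization and
probability-integral-transform uniform for stationary use (long-run daily
mean 0.5, verified), which gives the trend models a calibrated baseline.
Before beta-family fitting the values are clamped into
$[10^{-6}, 1-10^{-6}]$ (open support).

## Accelerometer states

Static acceleration is the per-axis mean of each non-overlapping 2-s
interval (64 samples at 32 Hz); VeDBA is the norm of the dynamic
(static-subtracted) triaxial signal, summarized as the natural log of the
interval mean — the base only shifts thresholds, not state identities.
Intervals with exactly zero dynamic acceleration are the no-activity
state. Per collar, the low/medium and medium/high cutpoints are the two
deepest interior local minima of a Gaussian-kernel density (Silverman
bandwidth, 512-point grid) of the finite log-VeDBA values; the zero point
mass is excluded from the density. KDE minima replace raw histogram
minima because bin-width sensitivity makes the latter irreproducible; a
collar with fewer than two minima raises a "non-trimodal" error with
diagnostics, and a month-by-month recomputation flags drifts above 0.5
log units. A value exactly at a cutpoint takes the lower state. Daily
transition counts use within-day consecutive pairs only; the cross-
midnight pair is ambiguous in a "daily number" and is excluded by
convention.

The simulator emits a semi-Markov state sequence with gamma dwell times
and draws each active interval's log VeDBA from its state's emission
distribution (defaults: means 0, 2.5, 5, SD 0.35 — valleys near the
published 1.12/4.2 example thresholds). These values live on the collar's
digitization scale, not literal g (e^4.2 g would exceed the ±4 g sensor);
only the ordering and separation matter to the state machinery. The raw
32 Hz waveform is built as gravity (a fixed random per-collar orientation,
emulating device placement) plus an alternating-sign dynamic component of
constant magnitude within each interval, so the per-interval log mean
VeDBA is recovered *exactly* by the analysis path — which is what lets
the seasonal pipeline work from per-interval emissions directly without
synthesizing terabytes of waveform.

## Trend models

Four location-scale models (gamma for home range, daily distance,
diffusion; beta for excursivity) and two mean models (beta for the no/low
activity proportion, negative binomial with profiled dispersion for daily
transitions) share the same three terms in each linear predictor:
per-group (sex × site) intercepts and cubic-regression-spline smooths of
study day ($k = 10$ by default, configurable because sensitivity to much
larger bases was a concern in the original analysis), a year smooth
multiplied by ±1 so the two study years' curves are exact negatives at
every day (the "equal weight per year" constraint, implemented at the
prediction level), and a random intercept per
animal-year with its own variance component (which keeps group-level
uncertainty honestly calibrated), and per-animal-year centred smooths
($k = 5$) with a full-rank penalty (smoothness plus ridge) and one shared
smoothing parameter, so individuals shrink to their group curve like
random effects.

Bases and difference penalties come from mgcv's `smoothCon`; the fitting
is the package's own, because no available package offers a beta
location-scale family: penalized Fisher scoring over the stacked mean and
scale coefficients using the families' expected information (orthogonal
cross-blocks for gamma; the full 2×2 information for beta), with step
halving and analytic scores. Smoothing parameters maximize the Laplace
approximate marginal likelihood
$\ell_p(\hat\beta) + \tfrac12\log|S_\lambda|_+ - \tfrac12\log|H+S_\lambda|$
by damped generalized Fellner–Schall updates
($\lambda_j \leftarrow \lambda_j\,[\mathrm{rank}_j/\lambda_j -
\mathrm{tr}(V_p S_j)]/\hat\beta^\top S_j \hat\beta$, capped at a factor
of 20 per sweep), whose fixed point is a stationary point of the criterion;
the selection mode is recorded in the fit, and fixed-$\lambda$ fits are the
fallback mode. Credible bands additionally carry a first-order
smoothing-parameter-uncertainty correction: the coefficient covariance is
inflated by $J V_\rho J^\top$ with $J = \partial\hat\beta/\partial\rho$
and $V_\rho$ the inverse (diagonal) curvature of the criterion — without
it, bands conditional on $\hat\lambda$ undercover by several percent.
Dense linear algebra is used for small designs and sparse (Matrix)
cross-products for large block-sparse ones.

Group curves are population-level: group intercept and smooth only, the
year term zero on average and individual terms excluded. Bands are
Gaussian 95% credible intervals on the linear predictor from the joint
posterior covariance $(H+S_\lambda)^{-1}$ — including, for location-scale
families, the correlation with the scale coefficients — mapped through
the inverse link. The deviation-from-constant test is a Wald-type
quadratic form of a group's smooth coefficients in the rank-truncated
inverse posterior covariance with rank the rounded effective degrees of
freedom; it is approximate, and simulation shows it holds the 5% level
under the null (type-I ≈ 0.05 over 200 replicates).

Deviance explained is $1 - D_{\mathrm{model}}/D_{\mathrm{null}}$ with the
saturated likelihood at each observation's own mean and the null an
intercept-only *mean* at the model's fitted per-observation scale.
Holding the scale fixed in the null isolates the mean structure; refitting
it would let the null absorb the signal into dispersion and drive the
statistic toward zero for every location-scale model.

## Synthetic cohort: what it emulates, and what passing tests show

The generator reproduces the design facts of the field study: final
sample sizes of 21/11, 21/10, 22/10 and 20/9 females/males per site-year;
two August-to-early-summer years; 1-h fix schedules with 5% dropout;
32 Hz ±4 g accelerometers; a male ranging-intensity elevation peaking at
day 111 (20 November, inside the 10–30 Nov peak rut) with a stronger
default at the control site; optional female extra-estrus elevation bouts
(~36 h every 25 days, 5 Jan–1 Apr, ×3 diffusion — the elevation magnitude
is a free parameter, as no estimate of it exists) on the treatment site;
and per-site daily mortality hazards (6 and 3 ×10⁻⁴) yielding study-like
overall mortality near 10%. Baseline OUF parameters (σ² = 3–5 ×10⁴ m²,
τ_r = 6 h, τ_v = 10 min) give ~0.5–1 km² home ranges and place daily
distance availability near the 60% the original collars achieved.

What the synthetic data do *not* contain: GPS measurement error and DOP
structure, habitat selection and landscape boundaries, social behaviour,
dispersal or range shifts (hence no >10 km² estimates in desk runs),
activity seasonality (the activity generator is stationary), and any
non-Gaussian movement. Passing tests therefore establish that the
estimators recover what they claim from data satisfying their assumptions
— calibration, not field validity.

## Problem sizes

Desk runs and tests use reduced designs chosen to keep the full suite in
the tens of minutes while leaving every check informative: the analysis
scripts simulate 20 animals over ~200 days; likelihood oracles use n ≤
100; the home-range Gaussian-limit check uses 40-day tracks (N_eff ≈ 480)
over 20 seeds; speed recovery uses 100 7-day windows; trend-model recovery
uses 2 groups × 8 animals × 40 windows over 50 seeds and the null
calibration 2 × 5 × 25 over 200 seeds; the end-to-end checks run male-only
cohorts of 8 animals. The study-sized design (124 animals, two years)
runs through the same code paths via `sim_cohort_config()` defaults.

## Known limitations

* The diffusion estimator follows the verbal definition (max MSD slope / 4)
  and can differ numerically from other implementations of time-dependent
  diffusion extraction.
* The plug-in mean speed underestimates the uncertainty a trajectory-
  conditional estimator would carry; only point trends are consumed here.
* The Wald smooth test and the credible bands are approximate; both are
  simulation-calibrated at the sizes above, slightly conservative for the
  test and near-nominal (≈93–96%) for the bands.
* AICc ties and near-ties at small τ_v make OU-vs-OUF selection (and hence
  speed availability) sensitive to the fix schedule — which is the real
  phenomenon behind partial speed availability, but worth remembering when
  changing `fix_interval`.
* The exclusion ledger reports animal-years; animals tracked in both years
  appear once per year (the original accounting is ambiguous on this, and
  both conventions can be derived from the metadata).
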