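# Shared oracles and simulation helpers, independent of the package's own
# computation paths.

# dense multivariate-Gaussian log-density of a track under the stated
# family and parameters: the brute-force oracle for the O(n) filter
dense_gp_loglik <- function(tt, x, y, family, mean, sigma2,
                            tau_r = NULL, tau_v = NULL) {
  n <- length(tt)
  L <- abs(outer(tt, tt, "-"))
  R <- switch(family,
    IID = diag(n),
    OU  = exp(-L / tau_r),
    OUF = (tau_r * exp(-L / tau_r) - tau_v * exp(-L / tau_v)) / (tau_r - tau_v))
  C <- sigma2 * R
  ch <- chol(C)
  ll <- 0
  for (d in list(x - mean[1], y - mean[2])) {
    z <- backsolve(ch, d, transpose = TRUE)
    ll <- ll - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
  }
  ll
}

# gamma-location-scale cohort with a known sinusoidal group log-mean curve
# and constant individual level shifts; amplitude defaults to the log of
# the ~3x rut elevation the study design implies
sim_gammals_cohort <- function(seed, groups = c("A", "B"), n_an = 8,
                               n_day = 40, amp = 1.1, ind_sd = 0.2,
                               day_max = 150, scale_amp = 0.3) {
  set.seed(seed)
  rows <- list()
  for (g in seq_along(groups)) for (a in seq_len(n_an)) {
    day <- seq(0, day_max, length.out = n_day)
    f_g <- 0.5 * g + amp * sin(2 * pi * day / day_max + g)
    f_a <- rnorm(1, 0, ind_sd)
    eta2 <- -1.5 + scale_amp * cos(2 * pi * day / day_max)
    mu <- exp(f_g + f_a)
    shape <- exp(-eta2)
    rows[[length(rows) + 1L]] <- data.frame(
      day = day, value = rgamma(n_day, shape, shape / mu),
      group = groups[g], animal = paste0(groups[g], "_", a), true_eta = f_g)
  }
  do.call(rbind, rows)
}

# two identical groups, constant mean: the null for group-difference tests
sim_null_cohort <- function(seed, n_an = 5, n_day = 25, ind_sd = 0.2) {
  set.seed(seed)
  rows <- list()
  for (g in c("A", "B")) for (a in seq_len(n_an)) {
    day <- seq(0, 150, length.out = n_day)
    mu <- exp(1 + rnorm(1, 0, ind_sd))
    rows[[length(rows) + 1L]] <- data.frame(
      day = day, value = rgamma(n_day, 4, 4 / mu),
      group = g, animal = paste0(g, a))
  }
  do.call(rbind, rows)
}

# local minima of a three-component Gaussian mixture density, found on a
# fine grid + refinement: the analytic oracle for threshold detection
mixture_minima <- function(means, sds, weights) {
  dens <- function(x) {
    out <- 0
    for (i in seq_along(means))
      out <- out + weights[i] * dnorm(x, means[i], sds[i])
    out
  }
  xs <- seq(min(means), max(means), length.out = 4000)
  ys <- dens(xs)
  i <- 2:(length(ys) - 1L)
  idx <- i[ys[i] < ys[i - 1L] & ys[i] < ys[i + 1L]]
  vapply(idx, function(j)
    optimize(dens, c(xs[j - 1L], xs[j + 1L]))$minimum, numeric(1))
}

# hourly POSIXct sequence starting at a study-year origin
hourly_times <- function(days, start = "2021-09-01 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  seq(t0, t0 + days * 86400, by = 3600)
}
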