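# Synthetic biologging cohort: exact continuous-time movement simulation,
# accelerometer emission, fix schedules and mortality. The generator mirrors
# the field study's design (two sites x two sexes x two years, 1-h GPS fixes,
# 32 Hz triaxial accelerometers) so every downstream stage can be exercised
# and validated without the restricted raw data.

#' Simulate a range-resident position process by exact Gaussian transitions
#'
#' Draws a track from a stationary Ornstein-Uhlenbeck (OU) position process
#' or its velocity-autocorrelated extension (OUF) at arbitrary, irregular
#' times. Sampling uses the exact Gaussian transition density of the process
#' (no Euler discretization): for OU the next position is
#' `mean + e^(-dt/tau_r) (current - mean)` plus noise with per-axis variance
#' `sigma2 (1 - e^(-2 dt/tau_r))`; for OUF the joint position-velocity
#' Gaussian transition is used. The per-axis marginal variance is exactly
#' `sigma2` at every time.
#'
#' `sigma2` may be a vector over `times`, in which case a unit-variance
#' process is simulated and rescaled so the marginal variance tracks
#' `sigma2[i]` exactly while the autocorrelation structure is unchanged;
#' this is how seasonal ranging intensity is modulated.
#'
#' @param times strictly increasing numeric timestamps (seconds) or POSIXct.
#' @param mean_location length-2 numeric, home-range centre (m).
#' @param sigma2 per-axis spatial variance (m^2); scalar or vector along `times`.
#' @param tau_range range-crossing timescale (s); `NULL` for an IID process.
#' @param tau_velocity velocity timescale (s), `NULL` for OU; must be
#'   strictly less than `tau_range`.
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with columns `t`, `x`, `y` (metres).
#' @export
sim_position_process <- function(times, mean_location = c(0, 0), sigma2,
                                 tau_range = NULL, tau_velocity = NULL,
                                 seed = NULL) {
  tt <- as.numeric(times)
  n <- length(tt)
  if (n < 1L) stop("need at least one timestamp")
  if (any(diff(tt) <= 0)) stop("timestamps must be strictly increasing")
  if (any(sigma2 <= 0)) stop("sigma2 must be strictly positive")
  if (!is.null(tau_range) && tau_range <= 0) stop("tau_range must be positive")
  if (!is.null(tau_velocity)) {
    if (is.null(tau_range)) stop("tau_velocity requires tau_range")
    if (tau_velocity <= 0 || tau_velocity >= tau_range)
      stop("need 0 < tau_velocity < tau_range")
  }
  s2 <- rep_len(sigma2, n)
  if (!is.null(seed)) set.seed(seed)

  u <- vapply(1:2, function(ax) {
    if (is.null(tau_range)) {
      rnorm(n)                                   # IID unit-variance fixes
    } else if (is.null(tau_velocity)) {
      .sim_ou_unit(tt, tau_range)
    } else {
      .sim_ouf_unit(tt, tau_range, tau_velocity)
    }
  }, numeric(n))

  data.frame(
    t = tt,
    x = mean_location[1] + sqrt(s2) * u[, 1],
    y = mean_location[2] + sqrt(s2) * u[, 2]
  )
}

# unit-variance OU sampled by the exact AR(1) transition on irregular gaps
.sim_ou_unit <- function(tt, tau) {
  n <- length(tt)
  phi <- exp(-diff(tt) / tau)
  x <- numeric(n)
  x[1] <- rnorm(1)
  if (n > 1L) {
    eps <- rnorm(n - 1L, sd = sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi[i - 1L] * x[i - 1L] + eps[i - 1L]
  }
  x
}

# unit-variance OUF: exact transition of the (position, velocity) state.
# Stationary covariance is diag(1, 1/(tau_r * tau_v)); the transition matrix
# is the matrix exponential of the companion form with rates 1/tau_r, 1/tau_v.
.sim_ouf_unit <- function(tt, tau_r, tau_v) {
  n <- length(tt)
  a <- 1 / tau_r
  b <- 1 / tau_v
  Pinf <- diag(c(1, a * b))
  z <- c(rnorm(1), rnorm(1, sd = sqrt(a * b)))
  x <- numeric(n)
  x[1] <- z[1]
  if (n == 1L) return(x)
  gaps <- diff(tt)
  ug <- unique(gaps)
  trans <- lapply(ug, function(dt) {
    ea <- exp(-a * dt); eb <- exp(-b * dt); den <- b - a
    Phi <- matrix(c((b * ea - a * eb) / den, a * b * (eb - ea) / den,
                    (ea - eb) / den,         (b * eb - a * ea) / den),
                  2, 2)
    Q <- Pinf - Phi %*% Pinf %*% t(Phi)
    Q <- (Q + t(Q)) / 2
    L <- tryCatch(t(chol(Q)), error = function(e) {
      ev <- eigen(Q, symmetric = TRUE)
      ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
    })
    list(Phi = Phi, L = L)
  })
  idx <- match(gaps, ug)
  for (i in 2:n) {
    tr <- trans[[idx[i - 1L]]]
    z <- drop(tr$Phi %*% z + tr$L %*% rnorm(2))
    x[i] <- z[1]
  }
  x
}

#' Thin a track to a fix schedule with dropout
#'
#' Retains only fixes on the schedule grid (multiples of `interval` from the
#' first fix), then drops each scheduled fix independently with probability
#' `dropout_prob`, emulating failed GPS acquisitions. Collars in the study
#' design attempt one fix per hour.
#'
#' @param track data.frame with a numeric/POSIXct `t` column.
#' @param interval schedule spacing in seconds (default 3600).
#' @param dropout_prob probability in `[0, 1]` that a scheduled fix is lost.
#' @param seed optional integer seed.
#' @return the thinned track; if empty, it carries `attr(, "empty") = TRUE`.
#' @export
apply_fix_schedule <- function(track, interval = 3600, dropout_prob = 0,
                               seed = NULL) {
  if (interval <= 0) stop("interval must be positive")
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0, 1]")
  tt <- as.numeric(track$t)
  on_grid <- abs((tt - tt[1]) %% interval) < 1e-6 |
    abs((tt - tt[1]) %% interval - interval) < 1e-6
  out <- track[on_grid, , drop = FALSE]
  if (dropout_prob > 0 && nrow(out) > 0) {
    if (!is.null(seed)) set.seed(seed)
    keep <- runif(nrow(out)) >= dropout_prob
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  if (nrow(out) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Seasonal ranging-intensity profile
#'
#' Multiplier on the spatial variance as a function of days after 1 August.
#' Males receive a Gaussian breeding-season bump centred in the 10-30 Nov
#' peak-rut window; unbred females on a site with extra estrus cycling
#' receive short recurring elevation bouts between 5 Jan and 1 Apr.
#'
#' @param day numeric days after 1 August.
#' @param sex "F" or "M"; @param site "treatment" or "control".
#' @param male_peak_mult named multipliers `c(treatment=, control=)` at the
#'   peak of the male rut bump (day `male_peak_day`).
#' @param male_peak_day,male_peak_sd centre (default 111 = 20 Nov) and width
#'   (days) of the male bump.
#' @param extra_estrus named logicals per site enabling female estrus bouts.
#' @param estrus_mult,estrus_period_days,estrus_duration_days bout height,
#'   recurrence (~25 d) and length (~1.5 d) of the extra-estrus elevation.
#' @return multiplier vector, >= 1.
#' @export
seasonal_profile <- function(day, sex, site,
                             male_peak_mult = c(treatment = 1.5, control = 3),
                             male_peak_day = 111, male_peak_sd = 12,
                             extra_estrus = c(treatment = TRUE, control = FALSE),
                             estrus_mult = 3, estrus_period_days = 25,
                             estrus_duration_days = 1.5) {
  m <- rep(1, length(day))
  if (sex == "M") {
    amp <- male_peak_mult[[site]] - 1
    m <- m + amp * exp(-0.5 * ((day - male_peak_day) / male_peak_sd)^2)
  } else if (isTRUE(extra_estrus[[site]])) {
    # bouts start at day 157 (5 Jan) and recur every ~25 days until 1 Apr
    in_window <- day >= 157 & day <= 243
    phase <- (day - 157) %% estrus_period_days
    bout <- in_window & phase < estrus_duration_days
    m[bout] <- estrus_mult
  }
  m
}

#' Configuration for a synthetic study cohort
#'
#' Defaults mirror the field study's design: final Table-1 sample sizes
#' (females/males 21/11 and 21/10 in year 1, 22/10 and 20/9 in year 2 at the
#' treatment and control sites), two August-to-early-summer study years,
#' 1-h fix schedules with dropout, and per-sex OU/OUF base parameters.
#'
#' @param seed integer master seed.
#' @param n_per_group data.frame(site, sex, year, n); default Table-1 sizes.
#' @param year_starts,year_ends POSIXct deployment-season bounds per year.
#' @param fix_interval nominal fix spacing (s).
#' @param fix_dropout_prob per-fix acquisition failure probability.
#' @param accel_rate accelerometer sampling rate (samples/s).
#' @param base_params list per sex with `sigma2` (m^2), `tau_range` (s),
#'   `tau_velocity` (s). Deer-scale defaults give ~0.5-1 km^2 baseline
#'   95% home ranges with a ~6 h range-crossing timescale.
#' @param male_peak_mult,extra_estrus,estrus_mult see [seasonal_profile()].
#' @param mortality_hazard named per-day death probabilities per site.
#' @param track_days nominal tracked span in days (before mortality or
#'   device failure truncation).
#' @param short_track_frac fraction of animals whose device fails early
#'   (tracked < 28 days), exercising the inclusion filter.
#' @return a list of class `rm_cohort_config`.
#' @export
sim_cohort_config <- function(seed = 1L,
                              n_per_group = NULL,
                              year_starts = NULL, year_ends = NULL,
                              fix_interval = 3600, fix_dropout_prob = 0.05,
                              accel_rate = 32,
                              base_params = list(
                                F = list(sigma2 = 3e4, tau_range = 6 * 3600,
                                         tau_velocity = 600),
                                M = list(sigma2 = 5e4, tau_range = 6 * 3600,
                                         tau_velocity = 600)),
                              male_peak_mult = c(treatment = 1.5, control = 3),
                              extra_estrus = c(treatment = TRUE, control = FALSE),
                              estrus_mult = 3,
                              mortality_hazard = c(treatment = 3e-4, control = 6e-4),
                              track_days = 280, short_track_frac = 0.08) {
  if (is.null(n_per_group)) {
    n_per_group <- data.frame(
      site = rep(c("treatment", "control"), each = 2, times = 2),
      sex  = rep(c("F", "M"), times = 4),
      year = rep(c(1L, 2L), each = 4),
      n    = c(21L, 11L, 21L, 10L, 22L, 10L, 20L, 9L))
  }
  if (is.null(year_starts))
    year_starts <- as.POSIXct(c("2021-08-01", "2022-08-01"), tz = "UTC")
  if (is.null(year_ends))
    year_ends <- as.POSIXct(c("2022-05-30", "2023-06-20"), tz = "UTC")
  stopifnot(all(n_per_group$n >= 0),
            fix_dropout_prob >= 0, fix_dropout_prob < 1,
            all(mortality_hazard >= 0), all(mortality_hazard < 1),
            all(year_starts < year_ends),
            year_ends[1] <= year_starts[2])
  for (p in base_params)
    stopifnot(p$sigma2 > 0, p$tau_range > 0,
              is.null(p$tau_velocity) || p$tau_velocity > 0)
  structure(list(seed = seed, n_per_group = n_per_group,
                 year_starts = year_starts, year_ends = year_ends,
                 fix_interval = fix_interval,
                 fix_dropout_prob = fix_dropout_prob,
                 accel_rate = accel_rate, base_params = base_params,
                 male_peak_mult = male_peak_mult, extra_estrus = extra_estrus,
                 estrus_mult = estrus_mult,
                 mortality_hazard = mortality_hazard,
                 track_days = track_days,
                 short_track_frac = short_track_frac),
            class = "rm_cohort_config")
}

# site reference coordinates (approximate study locations)
.site_centers <- list(treatment = c(lon = -74.15, lat = 40.58),
                      control   = c(lon = -73.839, lat = 41.107))

#' Simulate a full seasonal GPS cohort
#'
#' Generates one track per animal: a range-resident OUF process around an
#' individual home-range centre, with the spatial variance modulated by
#' [seasonal_profile()] (male rut bump peaking 10-30 Nov; optional female
#' extra-estrus bouts 5 Jan-1 Apr), thinned to the 1-h fix schedule with
#' dropout. Deterministic given the config (including its seed).
#'
#' @param config an [sim_cohort_config()] object.
#' @return list with `tracks` (named list of data.frames: `t` POSIXct UTC,
#'   `lon`, `lat`, plus true planar `x`, `y`) and `meta` (animal metadata
#'   with true generating parameters).
#' @export
simulate_seasonal_cohort <- function(config) {
  stopifnot(inherits(config, "rm_cohort_config"))
  if (sum(config$n_per_group$n) == 0L) stop("empty cohort")
  set.seed(config$seed)
  tracks <- list()
  meta <- NULL
  R_earth <- 6371008.8
  for (g in seq_len(nrow(config$n_per_group))) {
    row <- config$n_per_group[g, ]
    if (row$n == 0L) next
    yr <- row$year
    t0 <- config$year_starts[yr]
    t1 <- config$year_ends[yr]
    for (i in seq_len(row$n)) {
      id <- sprintf("%s_%s_Y%d_%02d", substr(row$site, 1, 2), row$sex, yr, i)
      ctr <- .site_centers[[row$site]]
      center <- c(ctr["lon"] + runif(1, -0.02, 0.02),
                  ctr["lat"] + runif(1, -0.015, 0.015))
      deploy <- t0 + round(runif(1, 0, 20)) * 86400
      span_days <- min(config$track_days, as.numeric(t1 - deploy, units = "days"))
      if (runif(1) < config$short_track_frac)
        span_days <- runif(1, 5, 26)        # early device failure
      end <- deploy + span_days * 86400
      tt <- seq(as.numeric(deploy), as.numeric(end), by = config$fix_interval)
      day <- (tt - as.numeric(t0)) / 86400
      bp <- config$base_params[[row$sex]]
      mult <- seasonal_profile(day, row$sex, row$site,
                               male_peak_mult = config$male_peak_mult,
                               extra_estrus = config$extra_estrus,
                               estrus_mult = config$estrus_mult)
      pp <- sim_position_process(tt, c(0, 0), sigma2 = bp$sigma2 * mult,
                                 tau_range = bp$tau_range,
                                 tau_velocity = bp$tau_velocity)
      pp <- apply_fix_schedule(pp, config$fix_interval,
                               config$fix_dropout_prob)
      lat <- center[2] + pp$y / R_earth * 180 / pi
      lon <- center[1] + pp$x / (R_earth * cos(center[2] * pi / 180)) * 180 / pi
      tr <- data.frame(t = as.POSIXct(pp$t, origin = "1970-01-01", tz = "UTC"),
                       lon = lon, lat = lat, x = pp$x, y = pp$y)
      tracks[[id]] <- tr
      meta <- rbind(meta, data.frame(
        animal_id = id, sex = row$sex, site = row$site, study_year = yr,
        deploy_date = deploy, end_date = end, fate = "drop-off",
        center_lon = center[1], center_lat = center[2],
        sigma2 = bp$sigma2, tau_range = bp$tau_range,
        tau_velocity = bp$tau_velocity))
    }
  }
  rownames(meta) <- NULL
  list(tracks = tracks, meta = meta)
}

#' Truncate a cohort by simulated mortality and tabulate deaths by group
#'
#' Each animal dies on a geometric day with its site's daily hazard; tracks
#' ending before the scheduled end are truncated and the fate recorded. The
#' returned 2x2 tables (rows treatment/control, columns died/survived) feed
#' Fisher's exact comparison of mortality between sites.
#'
#' @param cohort list(tracks, meta) from [simulate_seasonal_cohort()].
#' @param hazard named per-day death probabilities per site; defaults to
#'   the generating config's values if attached, else `c(3e-4, 6e-4)`.
#' @param seed optional integer seed.
#' @return list(tracks, meta, tables) where `tables` has `overall`, `M`, `F`.
#' @export
simulate_mortality <- function(cohort, hazard = c(treatment = 3e-4, control = 6e-4),
                               seed = NULL) {
  stopifnot(all(hazard >= 0), all(hazard < 1))
  if (!is.null(seed)) set.seed(seed)
  meta <- cohort$meta
  tracks <- cohort$tracks
  died <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    h <- hazard[[meta$site[i]]]
    span <- as.numeric(difftime(meta$end_date[i], meta$deploy_date[i],
                                units = "days"))
    if (h <= 0) next
    dday <- rgeom(1, h) + 1          # day of death, geometric
    if (dday < span) {
      died[i] <- TRUE
      new_end <- meta$deploy_date[i] + dday * 86400
      tr <- tracks[[meta$animal_id[i]]]
      tracks[[meta$animal_id[i]]] <- tr[as.numeric(tr$t) <= new_end, , drop = FALSE]
      meta$end_date[i] <- new_end
      meta$fate[i] <- sample(c("DVC", "unknown"), 1)
    }
  }
  meta$died <- died
  tab <- function(keep) {
    m <- meta[keep, ]
    t(vapply(c("treatment", "control"), function(s) {
      c(died = sum(m$died[m$site == s]), survived = sum(!m$died[m$site == s]))
    }, numeric(2)))
  }
  list(tracks = tracks, meta = meta,
       tables = list(overall = tab(rep(TRUE, nrow(meta))),
                     M = tab(meta$sex == "M"), F = tab(meta$sex == "F")))
}

# ---- accelerometer ground truth --------------------------------------------

#' Construct an activity-state timeline
#'
#' Ground truth for the accelerometer simulator: contiguous, non-overlapping
#' segments labelled with one of the four activity states (no, low, medium,
#' high) plus per-state log-VeDBA emission means and standard deviations.
#' The "no" state emits exactly zero dynamic acceleration; the remaining
#' emission means must be strictly increasing.
#'
#' @param segments data.frame(start, end, state).
#' @param emission_mean,emission_sd named vectors for states low/medium/high
#'   on the log-VeDBA scale (collar digitization units).
#' @return object of class `rm_timeline`.
#' @export
activity_timeline <- function(segments,
                              emission_mean = c(low = 0, medium = 2.5, high = 5),
                              emission_sd = c(low = 0.35, medium = 0.35, high = 0.35)) {
  stopifnot(all(segments$end > segments$start),
            all(segments$state %in% c("no", "low", "medium", "high")))
  if (nrow(segments) > 1L) {
    stopifnot(all(abs(segments$start[-1] - segments$end[-nrow(segments)]) < 1e-9))
  }
  stopifnot(all(diff(emission_mean[c("low", "medium", "high")]) > 0))
  structure(list(segments = segments, emission_mean = emission_mean,
                 emission_sd = emission_sd),
            class = "rm_timeline")
}

#' Simulate a semi-Markov activity timeline
#'
#' States alternate with gamma-distributed dwell times; transition targets
#' are drawn from a fixed kernel excluding self-transitions, giving the
#' trimodal (plus zero point mass) log-VeDBA structure the state-detection
#' stage assumes.
#'
#' @param duration_s total span in seconds.
#' @param mean_dwell named mean dwell times (s) per state.
#' @param seed optional integer seed.
#' @param ... passed to [activity_timeline()].
#' @export
simulate_activity_timeline <- function(duration_s,
                                       mean_dwell = c(no = 900, low = 300,
                                                      medium = 420, high = 150),
                                       seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  states <- c("no", "low", "medium", "high")
  cur <- sample(states, 1)
  t <- 0
  seg <- list()
  while (t < duration_s) {
    dwell <- rgamma(1, shape = 2, scale = mean_dwell[[cur]] / 2)
    dwell <- max(dwell, 4)                      # at least two 2-s intervals
    seg[[length(seg) + 1L]] <- data.frame(start = t, end = min(t + dwell, duration_s),
                                          state = cur)
    t <- t + dwell
    cur <- sample(setdiff(states, cur), 1)
  }
  activity_timeline(do.call(rbind, seg), ...)
}

#' Per-2-s true log mean VeDBA of a timeline
#'
#' Emits the log mean VeDBA value of every 2-s interval directly from the
#' timeline's emission model (`-Inf` for the "no" state). This is exactly
#' the value [vedba_intervals()] recovers from the corresponding raw 32 Hz
#' stream produced by [simulate_accelerometer()], which constructs each
#' interval's dynamic acceleration with zero interval mean and constant
#' per-sample magnitude.
#'
#' @param timeline an `rm_timeline`.
#' @param seed optional integer seed.
#' @return data.frame(start, state, log_mean_vedba).
#' @export
timeline_vedba <- function(timeline, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- max(timeline$segments$end)
  starts <- seq(0, dur - 2, by = 2)
  idx <- findInterval(starts, timeline$segments$start)
  st <- timeline$segments$state[idx]
  v <- rep(-Inf, length(st))
  act <- st != "no"
  v[act] <- rnorm(sum(act), mean = timeline$emission_mean[st[act]],
                  sd = timeline$emission_sd[st[act]])
  data.frame(start = starts, state = st, log_mean_vedba = v)
}

#' Simulate a raw triaxial accelerometer stream
#'
#' Output is a static gravity component plus a zero-mean dynamic component.
#' Within each 2-s interval the dynamic component has exactly zero mean per
#' axis (alternating-sign construction along a random unit direction) and
#' constant per-sample magnitude `exp(v)`, where `v` is the interval's
#' emitted log mean VeDBA; "no"-state intervals are exactly gravity.
#'
#' @param timeline an `rm_timeline` covering the requested span.
#' @param rate samples per second (default 32).
#' @param gravity_orientation unit 3-vector of the static component (per
#'   collar, emulating device placement on the neck).
#' @param seed optional integer seed.
#' @return list(acc = n x 3 matrix in sensor units, truth = per-interval
#'   data.frame from [timeline_vedba()]).
#' @export
simulate_accelerometer <- function(timeline, rate = 32,
                                   gravity_orientation = c(0, 0, 1),
                                   seed = NULL) {
  if (rate <= 0) stop("rate must be positive")
  if (nrow(timeline$segments) == 0L) stop("empty timeline")
  g <- gravity_orientation / sqrt(sum(gravity_orientation^2))
  truth <- timeline_vedba(timeline, seed = seed)
  spi <- round(2 * rate)                       # samples per 2-s interval
  n <- spi * nrow(truth)
  acc <- matrix(rep(g, each = n), n, 3)
  sgn <- rep_len(c(1, -1), spi)
  for (i in seq_len(nrow(truth))) {
    v <- truth$log_mean_vedba[i]
    if (!is.finite(v)) next
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    rows <- ((i - 1L) * spi + 1L):(i * spi)
    acc[rows, ] <- acc[rows, ] + exp(v) * sgn %o% u
  }
  list(acc = acc, truth = truth, rate = rate, gravity = g)
}
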