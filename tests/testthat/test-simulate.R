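# Synthetic biologging generator: exact-transition movement simulation,
# fix schedules, seasonal cohorts, accelerometer emission and mortality.

test_that("stationary limit: huge gaps give i.i.d. Gaussian fixes", {
  set.seed(1)
  tt <- seq(0, by = 1e9, length.out = 1e4)   # gaps >> tau_r
  tr <- sim_position_process(tt, c(50, -20), sigma2 = 400, tau_range = 3600)
  expect_equal(mean(tr$x), 50, tolerance = 0.05 * 20)
  expect_equal(var(tr$x), 400, tolerance = 0.1 * 400)
  expect_equal(var(tr$y), 400, tolerance = 0.1 * 400)
  expect_lt(abs(cor(tr$x[-1], tr$x[-1e4])), 0.05)
})

test_that("degenerate or invalid simulation inputs error", {
  expect_error(sim_position_process(c(0, 0, 1), c(0, 0), 1, 100),
               "strictly increasing")
  expect_error(sim_position_process(c(0, 1), c(0, 0), -1, 100), "sigma2")
  expect_error(sim_position_process(c(0, 1), c(0, 0), 1, 100,
                                    tau_velocity = 200), "tau_velocity")
})

test_that("OU autocovariance matches the closed form", {
  # lag-1 (1-h) autocorrelation of a tau_r = 1 day OU is e^(-1/24)
  set.seed(2)
  r1 <- replicate(60, {
    tt <- seq(0, 28 * 86400, by = 3600)
    tr <- sim_position_process(tt, c(0, 0), 100, tau_range = 86400)
    n <- length(tt)
    cor(tr$x[-1], tr$x[-n])
  })
  se <- sd(r1) / sqrt(length(r1))
  expect_lt(abs(mean(r1) - exp(-1 / 24)), 4 * se + 1e-3)

  # increment variance over gap dt is sigma2 * (1 - e^(-2 dt / tau_r))
  set.seed(3)
  tt <- seq(0, by = 1800, length.out = 1e5)
  tr <- sim_position_process(tt, c(0, 0), 250, tau_range = 7200)
  v_emp <- var(diff(tr$x))
  v_th <- 250 * (1 - exp(-2 * 1800 / 7200)) * 2  # var of x_t - phi x_{t-1}...
  # increments x_{t+dt} - x_t have variance 2 sigma2 (1 - e^(-dt/tau))
  v_th <- 2 * 250 * (1 - exp(-1800 / 7200))
  mc_se <- v_th * sqrt(2 / length(tt))
  expect_lt(abs(v_emp - v_th), 3 * mc_se)
})

test_that("OUF marginal variance and position autocovariance are exact", {
  set.seed(4)
  tt <- seq(0, by = 3600, length.out = 4e4)
  s2 <- 900; tr_ <- 6 * 3600; tv <- 1800
  tr <- sim_position_process(tt, c(0, 0), s2, tr_, tv)
  expect_equal(var(tr$x), s2, tolerance = 0.1 * s2)
  acf1 <- cor(tr$x[-1], tr$x[-length(tt)])
  th <- (tr_ * exp(-3600 / tr_) - tv * exp(-3600 / tv)) / (tr_ - tv)
  expect_equal(acf1, th, tolerance = 0.05)
})

test_that("fix schedule thinning is an identity without dropout and counts
           follow the binomial expectation with it", {
  tr <- data.frame(t = seq(0, 3600 * 99, by = 3600), x = 1:100, y = 1:100)
  expect_identical(apply_fix_schedule(tr, 3600, 0), tr)

  empty <- apply_fix_schedule(tr, 3600, 1, seed = 1)
  expect_equal(nrow(empty), 0L)
  expect_true(isTRUE(attr(empty, "empty")))

  tr2 <- data.frame(t = seq(0, 3600 * 999, by = 3600))
  kept <- replicate(60, nrow(apply_fix_schedule(tr2, 3600, 0.25)))
  se <- sqrt(1000 * 0.25 * 0.75) / sqrt(60)
  expect_lt(abs(mean(kept) - 750), 4 * se)
})

test_that("flat seasonal profile gives a stationary track and a November
           doubling doubles the realized male fix variance", {
  expect_equal(seasonal_profile(0:300, "F", "control"), rep(1, 301))
  # male profile peaks inside 10-30 Nov (days 101-121)
  prof <- seasonal_profile(0:300, "M", "control")
  expect_true(which.max(prof) - 1 >= 101 && which.max(prof) - 1 <= 121)

  set.seed(5)
  ratio <- replicate(50, {
    tt <- seq(0, by = 3600, length.out = 2000)
    mult <- rep(c(1, 2), each = 1000)
    tr <- sim_position_process(tt, c(0, 0), 1e4 * mult, tau_range = 3600)
    var(tr$x[1001:2000]) / var(tr$x[1:1000])
  })
  expect_equal(mean(ratio), 2, tolerance = 0.15)
})

test_that("extra-estrus bouts recur every ~25 days only in the enabled window", {
  prof <- seasonal_profile(0:300, "F", "treatment", estrus_mult = 3)
  elevated <- which(prof > 1) - 1
  expect_true(all(elevated >= 157 & elevated <= 243))
  expect_true(length(elevated) > 0)
  starts <- elevated[c(TRUE, diff(elevated) > 1)]
  expect_equal(unique(diff(starts)), 25)
  off <- seasonal_profile(0:300, "F", "treatment",
                          extra_estrus = c(treatment = FALSE, control = FALSE))
  expect_equal(off, rep(1, 301))
})

test_that("cohort simulation is deterministic and mirrors the configured
           group sizes", {
  npg <- data.frame(site = c("treatment", "control"),
                    sex = c("F", "M"), year = 1L, n = c(3L, 2L))
  cfg <- sim_cohort_config(seed = 9, n_per_group = npg, track_days = 40,
                           short_track_frac = 0)
  c1 <- simulate_seasonal_cohort(cfg)
  c2 <- simulate_seasonal_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(length(c1$tracks), 5L)
  expect_equal(nrow(c1$meta), 5L)
  expect_setequal(unique(c1$meta$sex), c("F", "M"))
})

test_that("default cohort sizes mirror the study's final sample", {
  cfg <- sim_cohort_config()
  expect_equal(sum(cfg$n_per_group$n), 124L)
  expect_equal(cfg$n_per_group$n[cfg$n_per_group$year == 1], c(21L, 11L, 21L, 10L))
})

test_that("mortality truncation follows the hazard and builds 2x2 tables", {
  npg <- data.frame(site = rep(c("treatment", "control"), each = 2),
                    sex = rep(c("F", "M"), 2), year = 1L, n = 5L)
  cfg <- sim_cohort_config(seed = 10, n_per_group = npg, track_days = 60,
                           short_track_frac = 0)
  coh <- simulate_seasonal_cohort(cfg)
  none <- simulate_mortality(coh, c(treatment = 0, control = 0), seed = 1)
  expect_false(any(none$meta$died))
  expect_equal(none$tables$overall[, "died"],
               c(treatment = 0, control = 0))
  all_die <- simulate_mortality(coh, c(treatment = 0.9999, control = 0.9999),
                                seed = 1)
  expect_true(all(all_die$meta$died))
})

test_that("accelerometer emission: pure gravity in the no state, exact
           sample counts, and exact log-VeDBA recovery", {
  tl <- activity_timeline(data.frame(start = 0, end = 120, state = "no"))
  sim <- simulate_accelerometer(tl, rate = 32, gravity_orientation = c(0, 0, 1),
                                seed = 1)
  expect_equal(nrow(sim$acc), 60 * 64)      # 64 samples per 2-s interval
  expect_true(all(sim$acc[, 1] == 0 & sim$acc[, 3] == 1))

  tl2 <- simulate_activity_timeline(1800, seed = 2)
  sim2 <- simulate_accelerometer(tl2, seed = 3)
  v <- vedba_intervals(sim2$acc, 32)
  expect_equal(v$log_mean_vedba, sim2$truth$log_mean_vedba, tolerance = 1e-12)
  # all "no" intervals give exactly zero VeDBA
  expect_true(all(is.infinite(v$log_mean_vedba[sim2$truth$state == "no"])))
})

test_that("two well-separated emission modes create a detectable valley", {
  set.seed(6)
  seg <- data.frame(start = seq(0, 7198, by = 2),
                    end = seq(2, 7200, by = 2),
                    state = rep(c("low", "high"), 1800))
  tl <- activity_timeline(seg, emission_mean = c(low = 0, medium = 3, high = 6),
                          emission_sd = c(low = 1, medium = 1, high = 1))
  v <- timeline_vedba(tl, seed = 7)
  d <- density(v$log_mean_vedba)
  i <- 2:(length(d$y) - 1)
  n_min <- sum(d$y[i] < d$y[i - 1] & d$y[i] < d$y[i + 1] &
                 d$y[i] > 0.01 * max(d$y))
  expect_gte(n_min, 1)
})
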