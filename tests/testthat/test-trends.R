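# Hierarchical location-scale trend models: design construction, fitting
# against closed-form oracles, bands, deviance and group contrasts.

test_that("design matrices satisfy the structural contracts", {
  d <- sim_gammals_cohort(50, n_an = 3, n_day = 20)
  d$year <- factor(rep(c(1, 2), length.out = nrow(d)))
  des <- build_design(d, k_group = 6, k_year = 4, k_ind = 3)
  expect_equal(nrow(des$X), nrow(d))

  # penalties are positive semi-definite
  for (b in des$blocks) {
    ev <- eigen((b$S + t(b$S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-10))
  }

  # the year-term pair at any day sums to zero over the two years
  nd1 <- data.frame(day = c(10, 60, 120), group = "A.1", year = "1")
  nd2 <- transform(nd1, year = "2")
  lev <- des$group_levels[1]
  nd1$group <- lev; nd2$group <- lev
  X1 <- predict_rows(des, nd1); X2 <- predict_rows(des, nd2)
  yr_cols <- unlist(lapply(des$blocks, function(b)
    if (b$term == "year") b$idx))
  expect_equal(X1[, yr_cols] + X2[, yr_cols],
               matrix(0, 3, length(yr_cols)), ignore_attr = TRUE)

  # dropping all smooth terms reduces the design to group intercepts
  des0 <- build_design(d, terms = character(0))
  expect_equal(ncol(des0$X), length(unique(d$group)))
  expect_true(all(des0$X %in% c(0, 1)))

  expect_error(predict_rows(des, data.frame(day = 1, group = "nope")),
               "unseen group")
})

test_that("intercept-only gamma location-scale matches the ML gamma solved
           from its score equations", {
  set.seed(51)
  y <- rgamma(600, shape = 3.2, rate = 3.2 / 5)
  fit <- fit_hgamls(y, intercept_design(length(y)), intercept_design(length(y)),
                    family = "gammals")
  mu_hat <- exp(fit$beta[1])
  expect_equal(mu_hat, mean(y), tolerance = 1e-6)
  # shape solves log(a) - digamma(a) = log(mean y) - mean(log y)
  rhs <- log(mean(y)) - mean(log(y))
  a_oracle <- uniroot(function(a) log(a) - digamma(a) - rhs,
                      c(1e-3, 1e3), tol = 1e-12)$root
  a_fit <- exp(-fit$beta[2])
  expect_equal(a_fit, a_oracle, tolerance = 1e-5)
})

test_that("intercept-only beta fit of symmetric data returns mean 0.5", {
  set.seed(52)
  y <- rbeta(800, 4, 4)
  y <- c(y, 1 - y)                         # exactly symmetric around 0.5
  fit <- fit_hgamls(y, intercept_design(length(y)), family = "betals")
  expect_equal(plogis(fit$beta[1]), 0.5, tolerance = 1e-4)
})

test_that("negative-binomial trend fit recovers the mean and a profiled
           dispersion near the truth", {
  set.seed(53)
  y <- rnbinom(800, size = 4, mu = 7)
  fit <- fit_hgamls(y, intercept_design(length(y)), family = "nb")
  expect_equal(exp(fit$beta[1]), mean(y), tolerance = 1e-5)
  expect_equal(exp(fit$beta[2]), 4, tolerance = 0.35)
})

test_that("penalized-likelihood ascent: gradient vanishes at the reported
           optimum", {
  d <- sim_gammals_cohort(54, n_an = 4, n_day = 25)
  fit <- fit_trend_model(d, "gammals", k_group = 6, k_ind = 3)
  expect_lt(max(abs(fit$grad)), 1e-3 * (1 + abs(fit$penalized_loglik)))
})

test_that("a sinusoidal gamma-ls group structure is recovered with a
           calibrated band (single-seed check)", {
  d <- sim_gammals_cohort(55, n_an = 8, n_day = 40)
  fit <- fit_trend_model(d, "gammals", k_group = 8, k_ind = 3)
  grid <- unique(d[, c("day", "group", "true_eta")])
  pb <- predict_band(fit, grid)
  rmse <- sqrt(mean((log(pb$fit) - grid$true_eta)^2))
  expect_lt(rmse / 1.1, 0.15)
  expect_gt(mean(grid$true_eta > log(pb$lo) & grid$true_eta < log(pb$hi)),
            0.85)
})

test_that("intercept-only models give constant bands and band width shrinks
           with sample size", {
  set.seed(56)
  y <- rgamma(300, 4, 4 / 3)
  fit <- fit_hgamls(y, intercept_design(length(y)), family = "gammals")
  # an intercept-only design predicts one constant value with one s.e.
  Xp <- predict_rows(fit$design_mean, data.frame(day = 1:5, group = "x"))
  expect_true(all(Xp == 1))

  d1 <- sim_gammals_cohort(57, n_an = 4, n_day = 20)
  d4 <- do.call(rbind, lapply(1:4, function(i)
    sim_gammals_cohort(57 + i, n_an = 4, n_day = 20)))
  d4$animal <- paste0(d4$animal, rep(1:4, each = nrow(d1)))
  f1 <- fit_trend_model(d1, "gammals", k_group = 6, k_ind = 3)
  f4 <- fit_trend_model(d4, "gammals", k_group = 6, k_ind = 3)
  g <- data.frame(day = seq(5, 145, by = 10), group = "A")
  w1 <- with(predict_band(f1, g), mean(log(hi) - log(lo)))
  w4 <- with(predict_band(f4, g), mean(log(hi) - log(lo)))
  expect_lt(w4, w1)
})

test_that("deviance explained is 0 for the intercept model, ~1 for a
           near-saturated fit, and non-decreasing under nesting", {
  set.seed(58)
  y <- rgamma(400, 4, 4 / 3)
  f0 <- fit_hgamls(y, intercept_design(length(y)), intercept_design(length(y)),
                   family = "gammals")
  expect_equal(f0$deviance_explained, 0, tolerance = 1e-9)

  # noiseless structured response: flexible fit explains almost everything
  d <- sim_gammals_cohort(59, n_an = 4, n_day = 30)
  d$value <- exp(d$true_eta)               # no residual noise
  d$value <- d$value * exp(rnorm(nrow(d), 0, 0.01))
  fit <- fit_trend_model(d, "gammals", k_group = 10, k_ind = 3)
  expect_gt(fit$deviance_explained, 0.99)

  # nesting with effectively unpenalized fits
  d2 <- sim_gammals_cohort(60, n_an = 4, n_day = 30)
  dm_int <- build_design(d2, terms = character(0))
  f_int <- fit_hgamls(d2$value, dm_int, family = "gammals")
  f_grp <- fit_hgamls(d2$value, build_design(d2, k_group = 6,
                                             terms = "group"),
                      family = "gammals",
                      lambda = list(mean.group = 1e-8))
  f_full <- fit_hgamls(d2$value, build_design(d2, k_group = 6, k_ind = 3),
                       family = "gammals",
                       lambda = list(mean.group = 1e-8,
                                     mean.ind_level = 1e-8,
                                     mean.individual = 1e-8))
  expect_lte(f_int$deviance_explained, f_grp$deviance_explained + 1e-9)
  expect_lte(f_grp$deviance_explained, f_full$deviance_explained + 1e-8)
})

test_that("identical groups give an exactly zero difference curve", {
  d <- sim_gammals_cohort(61, n_an = 4, n_day = 25)
  fit <- fit_trend_model(d, "gammals", k_group = 6, k_ind = 3)
  gd <- group_difference_curve(fit, "A", "A", seq(0, 150, by = 10))
  expect_equal(gd$curve$diff, rep(0, nrow(gd$curve)))
  expect_equal(gd$curve$hi + gd$curve$lo, rep(0, nrow(gd$curve)))
})

test_that("betar and nb trend fits run on proportion and count responses
           with the mean-only scale contract", {
  set.seed(62)
  n_day <- 30
  rows <- list()
  for (g in c("A", "B")) for (a in 1:4) {
    day <- seq(0, 150, length.out = n_day)
    mu <- plogis(0.5 + 0.8 * sin(2 * pi * day / 150) + rnorm(1, 0, 0.2))
    rows[[length(rows) + 1]] <- data.frame(
      day = day, prop = rbeta(n_day, mu * 20, (1 - mu) * 20),
      count = rnbinom(n_day, mu = 30 * mu, size = 6),
      group = g, animal = paste0(g, a))
  }
  d <- do.call(rbind, rows)
  d$value <- d$prop
  fb <- fit_trend_model(d, "betar", k_group = 6, k_ind = 3)
  expect_equal(ncol(fb$design_scale$X), 1L)     # scale predictor: intercept
  pb <- predict_band(fb, data.frame(day = 75, group = "A"))
  expect_true(pb$fit > 0 && pb$fit < 1)

  d$value <- d$count
  fn <- fit_trend_model(d, "nb", k_group = 6, k_ind = 3)
  expect_true(all(predict_band(fn, data.frame(day = c(10, 75, 140),
                                              group = "B"))$fit > 0))
  expect_gt(fn$deviance_explained, 0.1)
})

test_that("extrapolation beyond the fitted day range is flagged", {
  d <- sim_gammals_cohort(63, n_an = 3, n_day = 15)
  fit <- fit_trend_model(d, "gammals", k_group = 6, k_ind = 3)
  pb <- predict_band(fit, data.frame(day = c(75, 500), group = "A"))
  expect_equal(pb$extrapolated, c(FALSE, TRUE))
})
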