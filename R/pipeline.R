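# End-to-end pipeline: behavioral-period labels, Fisher's exact mortality
# comparison, and the simulate -> clean -> window -> metrics -> excursivity
# -> activity -> trends orchestration with its exclusion ledger and manifest.

# study-axis day ranges (days after 1 Aug, inclusive on both endpoints):
# 22 Sep-18 Oct, 20 Oct-4 Jan, 10 Nov-30 Nov, 5 Jan-1 Apr
.periods <- data.frame(
  label = c("peak-breeding", "breeding", "pre-breeding",
            "post-breeding/extra-estrus"),
  from = c(101, 80, 52, 157),
  to   = c(121, 156, 78, 243))

#' Behavioral period of a study day
#'
#' Labels days after 1 August with the study's behavioral periods:
#' pre-breeding (22 Sep-18 Oct, days 52-78), breeding (20 Oct-4 Jan, days
#' 80-156), peak breeding (10 Nov-30 Nov, days 101-121, nested within
#' breeding and reported preferentially) and post-breeding/extra estrus
#' (5 Jan-1 Apr, days 157-243). Endpoints are inclusive; the printed
#' calendar gaps (19 Oct; 2-4 Jan is inside breeding but 19 Oct is not)
#' map to "other" rather than being absorbed.
#'
#' @param day numeric days after 1 August (fractions allowed).
#' @param nested if TRUE, return a list of all matching labels per day.
#' @return character vector (or list when `nested`).
#' @export
behavioral_period <- function(day, nested = FALSE) {
  d <- floor(day)
  all_of <- function(di) {
    hit <- .periods$label[di >= .periods$from & di <= .periods$to]
    if (length(hit) == 0L) "other" else hit
  }
  if (nested) return(lapply(d, all_of))
  vapply(d, function(di) all_of(di)[1], character(1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional inference by full enumeration of the hypergeometric
#' support given the table margins: the two-sided p-value sums the
#' probabilities of all tables at most as probable as the observed one
#' (with a 1e-7 relative tie tolerance), and the odds ratio is the
#' conditional maximum-likelihood estimate solving the noncentral
#' hypergeometric mean equation. Degenerate margins give p = 1 and an
#' absent odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integers
#'   (rows = groups, columns = outcomes).
#' @return list(odds_ratio, p_value).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- round(as.matrix(tab))
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("negative entries")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(odds_ratio = NA_real_, p_value = 1))
  a_obs <- tab[1, 1]
  supp <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(supp, r1, r2, c1)
  p_obs <- dhyper(a_obs, r1, r2, c1)
  p <- sum(pr[pr <= p_obs * (1 + 1e-7)])
  # conditional MLE of the odds ratio
  lw <- lchoose(r1, supp) + lchoose(r2, c1 - supp)
  mean_a <- function(lpsi) {
    lt <- lw + supp * lpsi
    w <- exp(lt - max(lt))
    sum(supp * w) / sum(w)
  }
  or <- if (a_obs == min(supp)) 0
  else if (a_obs == max(supp)) Inf
  else exp(uniroot(function(l) mean_a(l) - a_obs, c(-30, 30))$root)
  list(odds_ratio = or, p_value = min(1, p))
}

#' Pipeline configuration
#'
#' Desk-scale defaults: a reduced cohort (a few animals per sex and site,
#' one study year) with the full study's movement structure, so a complete
#' run finishes in minutes. Pass `cohort_config = sim_cohort_config()` for
#' the study-sized design.
#'
#' @param seed master seed for the whole run.
#' @param cohort_config an [sim_cohort_config()]; default a reduced cohort.
#' @param window_size,window_slide moving-window scheme (days).
#' @param hr_cap home-range plausibility cap (km^2).
#' @param min_fixes minimum fixes per window.
#' @param k_group,k_year,k_ind trend-model basis dimensions.
#' @param activity_minutes_per_day accelerometer minutes simulated per
#'   animal-day for the activity stage.
#' @param fit_trends,fit_activity stage switches.
#' @param out_dir optional output directory for CSV artifacts + manifest.
#' @export
pipeline_config <- function(seed = 1L, cohort_config = NULL,
                            window_size = 7, window_slide = 3, hr_cap = 10,
                            min_fixes = 24, k_group = 8, k_year = 4,
                            k_ind = 4, activity_minutes_per_day = 20,
                            fit_trends = TRUE, fit_activity = TRUE,
                            out_dir = NULL) {
  if (is.null(cohort_config)) {
    npg <- data.frame(
      site = rep(c("treatment", "control"), each = 2),
      sex = rep(c("F", "M"), 2), year = 1L, n = c(4L, 3L, 4L, 3L))
    cohort_config <- sim_cohort_config(seed = seed, n_per_group = npg,
                                       track_days = 170,
                                       short_track_frac = 0.1)
  }
  list(seed = seed, cohort_config = cohort_config,
       window_size = window_size, window_slide = window_slide,
       hr_cap = hr_cap, min_fixes = min_fixes, k_group = k_group,
       k_year = k_year, k_ind = k_ind,
       activity_minutes_per_day = activity_minutes_per_day,
       fit_trends = fit_trends, fit_activity = fit_activity,
       out_dir = out_dir)
}

# clean + project + study-day-axis one cohort; returns tracks with x, y,
# day columns plus cleaning reports
.prepare_tracks <- function(tracks, meta, year_starts) {
  out <- list(); reports <- list()
  for (id in names(tracks)) {
    m <- meta[meta$animal_id == id, ]
    tr <- project_to_plane(tracks[[id]])
    cl <- clean_track(tr, deploy_date = m$deploy_date, end_date = m$end_date)
    tr <- cl$track
    if (nrow(tr) > 0)
      tr$day <- day_index(tr$t, year_starts[m$study_year])
    out[[id]] <- tr
    reports[[id]] <- cl$report
  }
  list(tracks = out, reports = reports)
}

# moving-window movement metrics for one prepared track
.window_metrics <- function(track, meta_row, size, slide, min_fixes, level = 0.95) {
  wins <- make_windows(track, size = size, slide = slide,
                       min_fixes = min_fixes)
  rows <- lapply(wins, function(w) {
    base <- data.frame(animal_id = meta_row$animal_id, sex = meta_row$sex,
                       site = meta_row$site, year = meta_row$study_year,
                       window_start_day = w$start_day, model_family = NA,
                       hr95_area = NA_real_, diffusion = NA_real_,
                       daily_distance = NA_real_, n_fixes = w$n,
                       n_eff = NA_real_, valid = FALSE,
                       exclusion_reason = NA_character_)
    if (!w$valid) {
      base$exclusion_reason <- "too few fixes"
      return(base)
    }
    model <- select_model(w$fixes, min_fixes = min_fixes)
    if (is.null(model)) {
      base$exclusion_reason <- attr(model, "reason")
      return(base)
    }
    ak <- akde_area(w$fixes, model, level = level, grid_n = 101)
    base$model_family <- model$family
    base$n_eff <- model$effective_n_area
    if (is.na(ak$area)) {
      base$exclusion_reason <- ak$reason
      return(base)
    }
    base$hr95_area <- ak$area
    base$diffusion <- as.numeric(diffusion_rate(model))
    base$daily_distance <- as.numeric(mean_daily_distance(model))
    base$valid <- TRUE
    base
  })
  do.call(rbind, rows)
}

# per-animal activity stage: simulated timelines -> per-interval log mean
# VeDBA -> per-collar thresholds -> daily budgets
.activity_stage <- function(meta, minutes_per_day, year_starts) {
  daily <- list()
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    d0 <- floor(day_index(m$deploy_date, year_starts[m$study_year]))
    d1 <- floor(day_index(m$end_date, year_starts[m$study_year]))
    days <- seq(max(d0, 0), d1)
    if (length(days) < 28) next
    per_day <- lapply(days, function(d) {
      tl <- simulate_activity_timeline(minutes_per_day * 60)
      v <- timeline_vedba(tl)
      v$day <- d
      v
    })
    v <- do.call(rbind, per_day)
    thr <- tryCatch(find_state_thresholds(v$log_mean_vedba,
                                          min_n = min(1e4, sum(is.finite(v$log_mean_vedba)))),
                    error = function(e) NULL)
    if (is.null(thr)) next
    st <- label_states(v$log_mean_vedba, thr)
    da <- daily_activity(st, v$day)
    da$animal_id <- m$animal_id; da$sex <- m$sex; da$site <- m$site
    da$year <- m$study_year
    daily[[m$animal_id]] <- da
  }
  do.call(rbind, daily)
}

.trend_data <- function(df, value_col) {
  out <- data.frame(day = if ("window_start_day" %in% names(df))
    df$window_start_day + 3.5 else df$day,
    value = df[[value_col]],
    group = interaction(df$sex, df$site, drop = TRUE),
    animal = interaction(df$animal_id, df$year, drop = TRUE))
  if (length(unique(df$year)) == 2L) out$year <- factor(df$year)
  out[is.finite(out$value), ]
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes simulate -> mortality -> clean/project -> inclusion filters ->
#' moving-window movement metrics -> home-range filtering -> annual
#' utilization distributions and daily excursivity -> accelerometer
#' activity states -> trend models -> Fisher mortality comparison, and
#' assembles the exclusion ledger and a reproducibility manifest. Fully
#' deterministic given the config (every stage draws from the seeded RNG
#' stream).
#'
#' @param config a [pipeline_config()].
#' @return list with `estimates`, `hr_report`, `excursivity`, `activity`,
#'   `trends` (fitted models + prediction curves), `mortality`, `ledger`,
#'   `meta`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  set.seed(config$seed)
  cc <- config$cohort_config
  cohort <- simulate_seasonal_cohort(cc)
  mort <- simulate_mortality(cohort, cc$mortality_hazard)
  n_captured <- nrow(mort$meta)

  prep <- .prepare_tracks(mort$tracks, mort$meta, cc$year_starts)
  incl <- apply_inclusion_filters(prep$tracks, mort$meta)
  meta <- incl$meta

  estimates <- do.call(rbind, lapply(meta$animal_id, function(id) {
    .window_metrics(incl$tracks[[id]], meta[meta$animal_id == id, ],
                    config$window_size, config$window_slide,
                    config$min_fixes)
  }))
  filt <- filter_estimates(estimates, hr_cap = config$hr_cap)
  estimates <- filt$estimates

  # annual UDs and daily excursivity
  exc <- list()
  for (id in meta$animal_id) {
    tr <- incl$tracks[[id]]
    ud <- tryCatch(fit_annual_ud(tr, grid_n = 151), error = function(e) NULL)
    if (is.null(ud)) next
    de <- daily_excursivity(ud, tr)
    m <- meta[meta$animal_id == id, ]
    de$animal_id <- id; de$sex <- m$sex; de$site <- m$site
    de$year <- m$study_year
    exc[[id]] <- de
  }
  excursivity <- do.call(rbind, exc)

  activity <- if (config$fit_activity)
    .activity_stage(meta, config$activity_minutes_per_day, cc$year_starts)
  else NULL

  trends <- list()
  if (config$fit_trends) {
    fit1 <- function(df, col, family) {
      td <- .trend_data(df, col)
      if (nrow(td) < 50) return(NULL)
      fit <- fit_trend_model(td, family = family, k_group = config$k_group,
                             k_year = config$k_year, k_ind = config$k_ind)
      grid <- expand.grid(day = seq(min(td$day), max(td$day), by = 1),
                          group = levels(td$group))
      list(fit = fit, curves = predict_band(fit, grid), data_n = nrow(td))
    }
    valid_est <- estimates[estimates$valid, ]
    trends$hr <- fit1(valid_est, "hr95_area", "gammals")
    trends$distance <- fit1(valid_est, "daily_distance", "gammals")
    trends$diffusion <- fit1(valid_est, "diffusion", "gammals")
    if (!is.null(excursivity)) {
      ex <- excursivity; ex$window_start_day <- NULL
      trends$excursivity <- fit1(ex, "mean_q", "betals")
    }
    if (!is.null(activity)) {
      trends$state <- fit1(activity, "prop_no_low", "betar")
      trends$transitions <- fit1(activity, "n_transitions", "nb")
    }
  }

  mortality <- lapply(mort$tables, function(tb)
    c(fisher_exact_2x2(tb), list(table = tb)))

  excluded_short <- incl$excluded
  ledger <- data.frame(
    stage = c("captured", "died_pre_inclusion", "short_track", "included"),
    n = c(n_captured,
          sum(mort$meta$died & mort$meta$animal_id %in% excluded_short$animal_id),
          nrow(excluded_short), nrow(meta)))

  manifest <- list(seed = config$seed,
                   n_captured = n_captured, n_included = nrow(meta),
                   window = c(size = config$window_size,
                              slide = config$window_slide),
                   hr_cap = config$hr_cap,
                   speed_available_pct =
                     100 * mean(!is.na(estimates$daily_distance[estimates$valid])),
                   hr_removed = filt$report)

  res <- list(estimates = estimates, hr_report = filt$report,
              excursivity = excursivity, activity = activity,
              trends = trends, mortality = mortality, ledger = ledger,
              meta = meta, manifest = manifest)
  if (!is.null(config$out_dir)) .write_artifacts(res, config)
  res
}

.write_artifacts <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) if (!is.null(df))
    write.csv(df, file.path(config$out_dir, name), row.names = FALSE)
  w(res$estimates, "window_estimates.csv")
  w(res$excursivity, "daily_excursivity.csv")
  w(res$activity, "daily_activity.csv")
  w(res$ledger, "exclusion_ledger.csv")
  for (nm in names(res$trends)) if (!is.null(res$trends[[nm]]))
    w(res$trends[[nm]]$curves, paste0("trend_", nm, ".csv"))
  mt <- do.call(rbind, lapply(names(res$mortality), function(nm)
    data.frame(stratum = nm,
               odds_ratio = res$mortality[[nm]]$odds_ratio,
               p_value = res$mortality[[nm]]$p_value)))
  w(mt, "mortality.csv")
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
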