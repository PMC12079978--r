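# Accelerometry: VeDBA over 2-s intervals, per-collar activity-state
# thresholds from local minima of the log mean VeDBA distribution, state
# labelling and daily activity budgets/transitions.

#' Log mean VeDBA over non-overlapping 2-s intervals
#'
#' For each interval the static acceleration is the per-axis mean over the
#' interval; the dynamic acceleration is the sample minus the static; VeDBA
#' is the Euclidean norm of the dynamic triaxial acceleration, and the
#' interval summary is the natural log of the interval-mean VeDBA. An
#' interval whose dynamic acceleration is identically zero has VeDBA = 0
#' and log mean VeDBA `-Inf` (the no-activity marker). A trailing partial
#' interval is dropped.
#'
#' @param acc n x 3 numeric matrix of triaxial samples.
#' @param rate sampling rate in samples/s; must match the stream (32 Hz in
#'   the study's collars, 64 samples per interval).
#' @param t0 timestamp of the first sample (numeric seconds or POSIXct).
#' @return data.frame(start, log_mean_vedba, n_samples).
#' @export
vedba_intervals <- function(acc, rate = 32, t0 = 0) {
  if (rate <= 0 || abs(rate - round(rate)) > 1e-9)
    stop("rate must be a positive integer sample rate")
  spi <- as.integer(2 * rate)
  acc <- as.matrix(acc)
  if (ncol(acc) != 3L) stop("acc must have three axes")
  n_int <- nrow(acc) %/% spi
  if (n_int == 0L) stop("stream shorter than one 2-s interval")
  acc <- acc[seq_len(n_int * spi), , drop = FALSE]
  grp <- rep(seq_len(n_int), each = spi)
  dyn2 <- 0
  for (ax in 1:3) {
    v <- acc[, ax]
    mu <- rep(tapply(v, grp, mean), each = spi)
    dyn2 <- dyn2 + (v - mu)^2
  }
  vedba <- sqrt(dyn2)
  mean_vedba <- as.numeric(tapply(vedba, grp, mean))
  lmv <- ifelse(mean_vedba == 0, -Inf, log(mean_vedba))
  data.frame(start = as.numeric(t0) + (seq_len(n_int) - 1L) * 2,
             log_mean_vedba = lmv, n_samples = spi)
}

# interior local minima/maxima of a KDE evaluated on a fixed grid
.kde_extrema <- function(values, n_grid = 512) {
  d <- density(values, bw = "nrd0", n = n_grid,
               from = min(values), to = max(values))
  y <- d$y
  i <- 2:(length(y) - 1L)
  minima <- i[y[i] < y[i - 1L] & y[i] <= y[i + 1L]]
  maxima <- i[y[i] > y[i - 1L] & y[i] >= y[i + 1L]]
  list(x = d$x, y = y, minima = minima, maxima = maxima)
}

#' Detect per-collar activity-state thresholds
#'
#' Smooths the distribution of finite log mean VeDBA values with a Gaussian
#' kernel (Silverman bandwidth, 512-point grid over the data range) and
#' locates interior local minima. The log-VeDBA distribution of a collar is
#' expected to be trimodal; the two deepest valleys become the low/medium
#' and medium/high cutpoints. Zero-VeDBA (`-Inf`) intervals are a point
#' mass, not part of the continuous density, and must be excluded upstream.
#'
#' @param values finite log mean VeDBA values of one collar.
#' @param min_n minimum sample size (default 1e4).
#' @return object of class `rm_thresholds`: `cut_low_med`, `cut_med_high`,
#'   and valley diagnostics.
#' @export
find_state_thresholds <- function(values, min_n = 1e4) {
  values <- values[is.finite(values)]
  if (length(values) < min_n)
    stop("need at least ", min_n, " finite log mean VeDBA values")
  ke <- .kde_extrema(values)
  if (length(ke$minima) < 2L)
    stop("non-trimodal collar: found ", length(ke$minima),
         " interior local minima in the log mean VeDBA density")
  # valley depth: the lower flanking peak minus the valley floor
  depth <- vapply(ke$minima, function(j) {
    left <- ke$maxima[ke$maxima < j]
    right <- ke$maxima[ke$maxima > j]
    pk <- min(if (length(left)) max(ke$y[left]) else Inf,
              if (length(right)) max(ke$y[right]) else Inf)
    pk - ke$y[j]
  }, numeric(1))
  keep <- ke$minima[order(depth, decreasing = TRUE)][1:2]
  cuts <- sort(ke$x[keep])
  structure(list(cut_low_med = cuts[1], cut_med_high = cuts[2],
                 valley_depths = sort(depth, decreasing = TRUE)[1:2],
                 n = length(values)),
            class = "rm_thresholds")
}

#' Monthly stability check of activity thresholds
#'
#' Recomputes the valley locations per calendar month and reports the
#' maximum absolute deviation from the annual cutpoints; deviations above
#' `flag_tol` flag the collar. This makes the visual month-by-month
#' histogram inspection of the study design programmatic.
#'
#' @param values finite log mean VeDBA values.
#' @param month month label per value (any grouping vector, >= 2 levels).
#' @param thresholds an `rm_thresholds` from the full record.
#' @param flag_tol deviation (log units) above which the collar is flagged.
#' @return data.frame(month, cut_low_med, cut_med_high, max_dev, flagged).
#' @export
check_threshold_stability <- function(values, month, thresholds,
                                      flag_tol = 0.5) {
  keep <- is.finite(values)
  values <- values[keep]; month <- month[keep]
  mo <- unique(month)
  if (length(mo) < 2L) stop("need at least 2 months of data")
  rows <- lapply(mo, function(m) {
    v <- values[month == m]
    th <- tryCatch(find_state_thresholds(v, min_n = min(1000, length(v))),
                   error = function(e) NULL)
    if (is.null(th))
      return(data.frame(month = m, cut_low_med = NA, cut_med_high = NA,
                        max_dev = Inf, flagged = TRUE))
    dev <- max(abs(th$cut_low_med - thresholds$cut_low_med),
               abs(th$cut_med_high - thresholds$cut_med_high))
    data.frame(month = m, cut_low_med = th$cut_low_med,
               cut_med_high = th$cut_med_high, max_dev = dev,
               flagged = dev > flag_tol)
  })
  do.call(rbind, rows)
}

.rm_states <- c("no", "low", "medium", "high")

#' Label 2-s intervals with activity states
#'
#' `-Inf` (zero VeDBA) is the no-activity state; finite values below the
#' low/medium cutpoint are low, below the medium/high cutpoint medium, else
#' high. A value exactly at a cutpoint takes the lower state.
#'
#' @param log_mean_vedba numeric vector (may contain `-Inf`).
#' @param thresholds an `rm_thresholds` (or list with the two cutpoints).
#' @return factor with levels no < low < medium < high.
#' @export
label_states <- function(log_mean_vedba, thresholds) {
  v <- log_mean_vedba
  out <- ifelse(!is.finite(v), "no",
         ifelse(v <= thresholds$cut_low_med, "low",
         ifelse(v <= thresholds$cut_med_high, "medium", "high")))
  factor(out, levels = .rm_states, ordered = TRUE)
}

#' Daily activity budget and transition counts
#'
#' Per local day: the proportion of 2-s intervals in the no- or low-activity
#' states, the number of transitions between different states among
#' consecutive within-day interval pairs (pairs spanning midnight are not
#' counted), and per-state proportions.
#'
#' @param states factor from [label_states()].
#' @param day local day label per interval (e.g. floored study-day index).
#' @return data.frame(day, prop_no_low, n_transitions, n_intervals,
#'   prop_no, prop_low, prop_medium, prop_high).
#' @export
daily_activity <- function(states, day) {
  stopifnot(length(states) == length(day))
  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    s <- states[day == d]
    n <- length(s)
    if (n == 0L) return(NULL)
    tab <- table(factor(s, levels = .rm_states)) / n
    data.frame(day = d,
               prop_no_low = unname(tab["no"] + tab["low"]),
               n_transitions = sum(s[-1] != s[-n]),
               n_intervals = n,
               prop_no = unname(tab["no"]), prop_low = unname(tab["low"]),
               prop_medium = unname(tab["medium"]),
               prop_high = unname(tab["high"]))
  })
  do.call(rbind, rows)
}
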