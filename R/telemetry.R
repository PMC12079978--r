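# Telemetry core: Movebank-style I/O, local planar projection, track
# cleaning, the days-after-1-August study time axis, moving windows, and
# cohort inclusion filters.

.movebank_cols <- c("individual-local-identifier", "timestamp",
                    "location-long", "location-lat")

#' Write tracks as Movebank-style CSV
#'
#' Columns: `individual-local-identifier`, `timestamp`
#' ("YYYY-MM-DD HH:MM:SS.000", UTC), `location-long`, `location-lat`.
#'
#' @param tracks named list of data.frames with `t`, `lon`, `lat`.
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(names(tracks), function(id) {
    tr <- tracks[[id]]
    data.frame(
      `individual-local-identifier` = id,
      timestamp = paste0(format(as.POSIXct(tr$t, tz = "UTC"),
                                "%Y-%m-%d %H:%M:%S", tz = "UTC"), ".000"),
      `location-long` = sprintf("%.7f", tr$lon),
      `location-lat` = sprintf("%.7f", tr$lat),
      check.names = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read animal metadata CSV
#' @param meta metadata data.frame; @param path CSV path.
#' @export
write_meta <- function(meta, path) {
  out <- meta
  for (col in c("deploy_date", "end_date"))
    out[[col]] <- format(as.POSIXct(out[[col]], tz = "UTC"),
                         "%Y-%m-%d %H:%M:%S", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meta
#' @export
read_meta <- function(path) {
  meta <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("deploy_date", "end_date"))
    meta[[col]] <- as.POSIXct(meta[[col]], tz = "UTC")
  meta
}

#' Read Movebank-style GPS tracks
#'
#' Groups fixes by animal and sorts them in time. Malformed rows (bad
#' timestamp or non-numeric coordinates) and exact duplicates are removed
#' and counted in the attached report, never silently dropped.
#'
#' @param path CSV path.
#' @return named list of track data.frames (`t` POSIXct UTC, `lon`, `lat`)
#'   with a `report` attribute: `c(malformed = , duplicates = )`.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(.movebank_cols, names(raw))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  t <- as.POSIXct(raw$timestamp, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  lon <- suppressWarnings(as.numeric(raw$`location-long`))
  lat <- suppressWarnings(as.numeric(raw$`location-lat`))
  ok <- !is.na(t) & !is.na(lon) & !is.na(lat) & abs(lat) <= 90 & abs(lon) <= 180
  n_malformed <- sum(!ok)
  df <- data.frame(id = raw$`individual-local-identifier`[ok],
                   t = t[ok], lon = lon[ok], lat = lat[ok])
  dup <- duplicated(df)
  n_dup <- sum(dup)
  df <- df[!dup, ]
  tracks <- lapply(split(df, df$id), function(d) {
    d <- d[order(d$t), c("t", "lon", "lat")]
    rownames(d) <- NULL
    d
  })
  attr(tracks, "report") <- c(malformed = n_malformed, duplicates = n_dup)
  tracks
}

# mean Earth radius (m); matches the spherical distance oracle used in tests
.R_earth <- 6371008.8

#' Project a track onto a local plane
#'
#' Spherical azimuthal equidistant projection centred on the track's median
#' coordinate: distances from the centre are preserved exactly on the
#' sphere, and distortion elsewhere is negligible over the <= 20 km extents
#' of deer home ranges. Adds `x`, `y` columns (metres).
#'
#' @param track data.frame with `lon`, `lat` (degrees WGS84).
#' @param center optional `c(lon, lat)`; default the track's median fix.
#' @return the track with `x`, `y` filled and a `center` attribute.
#' @export
project_to_plane <- function(track, center = NULL) {
  if (nrow(track) == 0L) stop("empty track")
  if (is.null(center)) center <- c(median(track$lon), median(track$lat))
  d2r <- pi / 180
  lam0 <- center[1] * d2r; phi0 <- center[2] * d2r
  lam <- track$lon * d2r;  phi <- track$lat * d2r
  dl <- lam - lam0
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  cosc <- pmin(1, pmax(-1, cosc))
  cc <- acos(cosc)
  k <- ifelse(cc < 1e-12, 1, cc / sin(cc))
  track$x <- .R_earth * k * cos(phi) * sin(dl)
  track$y <- .R_earth * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  attr(track, "center") <- center
  track
}

#' Clean a projected track
#'
#' Applies, in order: removal of fixes outside the deployment interval,
#' removal of exact-duplicate timestamps (first kept), and an iterated
#' speed filter that removes fixes requiring straight-line speeds above
#' `max_speed` from *both* neighbours (deer do not sustain > 5 m/s across
#' 1-h gaps). The speed rule is re-applied until no fix is removed, which
#' makes cleaning idempotent.
#'
#' @param track projected track (`t`, `x`, `y`).
#' @param max_speed m/s threshold (default 5).
#' @param deploy_date,end_date optional deployment bounds (POSIXct/numeric).
#' @return list(track, report) with per-rule removal counts.
#' @export
clean_track <- function(track, max_speed = 5, deploy_date = NULL,
                        end_date = NULL) {
  report <- c(pre_deployment = 0L, post_end = 0L, duplicate_time = 0L,
              speed = 0L)
  tt <- as.numeric(track$t)
  keep <- rep(TRUE, nrow(track))
  if (!is.null(deploy_date)) {
    bad <- tt < as.numeric(deploy_date)
    report["pre_deployment"] <- sum(bad); keep <- keep & !bad
  }
  if (!is.null(end_date)) {
    bad <- tt > as.numeric(end_date)
    report["post_end"] <- sum(bad); keep <- keep & !bad
  }
  track <- track[keep, , drop = FALSE]
  dup <- duplicated(as.numeric(track$t))
  report["duplicate_time"] <- sum(dup)
  track <- track[!dup, , drop = FALSE]
  repeat {
    n <- nrow(track)
    if (n < 3L) break
    tt <- as.numeric(track$t)
    dx <- diff(track$x); dy <- diff(track$y); dt <- diff(tt)
    sp <- sqrt(dx^2 + dy^2) / dt           # speed over each gap
    bad <- c(FALSE, sp[-(n - 1L)] > max_speed, FALSE) &
           c(FALSE, sp[-1L] > max_speed, FALSE)
    if (!any(bad)) break
    report["speed"] <- report["speed"] + sum(bad)
    track <- track[!bad, , drop = FALSE]
  }
  rownames(track) <- NULL
  if (nrow(track) == 0L) attr(track, "empty") <- TRUE
  list(track = track, report = report)
}

#' Days after 1 August
#'
#' Continuous study time axis: calendar days since 1 August of the study
#' year plus the fraction of the local clock day (America/New_York), so
#' that local midnights fall on integers across the December-January
#' boundary and the autumn DST change (1 Jan maps to 153, 10 Nov to 101).
#'
#' @param t POSIXct timestamps.
#' @param year_start POSIXct or date-like giving 1 August of the study year
#'   (any time on that date).
#' @param tz local timezone for day boundaries.
#' @return numeric fractional days; 1 Aug 00:00 local is 0.
#' @export
day_index <- function(t, year_start, tz = .rutmove_tz) {
  lt <- as.POSIXlt(t, tz = tz)
  d0 <- as.Date(as.POSIXlt(year_start, tz = tz))
  days <- as.numeric(as.Date(lt) - d0)
  frac <- (lt$hour * 3600 + lt$min * 60 + lt$sec) / 86400
  out <- days + frac
  if (any(out < 0 | out > 365))
    stop("timestamp outside the study year span")
  out
}

#' Invert the study time axis to a local timestamp
#' @param day fractional days after 1 August; @inheritParams day_index
#' @export
day_index_to_time <- function(day, year_start, tz = .rutmove_tz) {
  d0 <- as.Date(as.POSIXlt(year_start, tz = tz))
  as.POSIXct(paste(d0 + floor(day), "00:00:00"), tz = tz) +
    (day - floor(day)) * 86400
}

#' Split a track into overlapping moving windows
#'
#' Windows start at multiples of `slide` days on the days-after-1-August
#' axis and are half-open, `[start, start + size)`; the defaults give the
#' 7-day / 3-day moving-window scheme. Windows with fewer than `min_fixes`
#' fixes are flagged invalid but retained.
#'
#' @param track track with a `day` column (see [day_index()]).
#' @param size,slide window size and slide (days); `size >= slide > 0`.
#' @param min_fixes minimum fixes for a model-fit attempt (default 24).
#' @return list of windows: list(start_day, fixes, n, valid).
#' @export
make_windows <- function(track, size = 7, slide = 3, min_fixes = 24) {
  stopifnot(size >= slide, slide > 0)
  d <- track$day
  lo <- slide * floor(min(d) / slide)
  hi <- ceiling(max(d))
  starts <- seq(lo, by = slide,
                length.out = max(0, floor((hi - size - lo) / slide) + 1))
  starts <- starts[starts + size <= hi]
  degenerate <- length(starts) == 0L
  if (degenerate) starts <- lo    # track shorter than one window: flag it
  lapply(starts, function(s) {
    sel <- d >= s & d < s + size
    w <- track[sel, , drop = FALSE]
    rownames(w) <- NULL
    list(start_day = s, fixes = w, n = nrow(w),
         valid = !degenerate && nrow(w) >= min_fixes)
  })
}

#' Apply cohort inclusion filters
#'
#' Excludes animals whose tracked span is below `min_days` (28 days in the
#' study design; the threshold is closed, a 28.0-day track is included).
#'
#' @param tracks named list of tracks; @param meta metadata data.frame.
#' @param min_days minimum tracked span (days).
#' @return list(tracks, meta, excluded) where `excluded` lists animal ids
#'   and reasons.
#' @export
apply_inclusion_filters <- function(tracks, meta, min_days = 28) {
  span <- vapply(tracks, function(tr) {
    if (nrow(tr) < 2L) return(0)
    diff(range(as.numeric(tr$t))) / 86400
  }, numeric(1))
  short <- names(tracks)[span < min_days]
  excluded <- data.frame(animal_id = short,
                         reason = rep("tracking period < 28 days",
                                      length(short)))
  keep <- setdiff(names(tracks), short)
  list(tracks = tracks[keep],
       meta = meta[meta$animal_id %in% keep, , drop = FALSE],
       excluded = excluded)
}
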