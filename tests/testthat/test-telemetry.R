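# Telemetry core: Movebank I/O, projection, cleaning, the study day axis,
# moving windows and inclusion filters.

make_tracks <- function() {
  t0 <- as.POSIXct("2021-09-01 00:00:00", tz = "UTC")
  list(
    deer1 = data.frame(t = t0 + 3600 * 0:9,
                       lon = -73.84 + 1e-4 * 0:9, lat = 41.10 + 1e-4 * 0:9),
    deer2 = data.frame(t = t0 + 3600 * 0:4,
                       lon = rep(-74.15, 5), lat = 40.58 + 1e-4 * 0:4))
}

test_that("Movebank round trip preserves fixes to the second and 1e-7 deg", {
  trk <- make_tracks()
  path <- tempfile(fileext = ".csv")
  write_tracks(trk, path)
  back <- read_tracks(path)
  expect_equal(names(back), names(trk))
  for (id in names(trk)) {
    expect_equal(as.numeric(back[[id]]$t), as.numeric(trk[[id]]$t))
    expect_equal(back[[id]]$lon, trk[[id]]$lon, tolerance = 1e-7)
    expect_equal(back[[id]]$lat, trk[[id]]$lat, tolerance = 1e-7)
  }
  expect_equal(unname(attr(back, "report")), c(0L, 0L))
})

test_that("duplicated and malformed rows are removed and counted", {
  trk <- make_tracks()
  path <- tempfile(fileext = ".csv")
  write_tracks(trk, path)
  raw <- readLines(path)
  writeLines(c(raw, raw[2], "deer3,not-a-time,-73.8,41.1"), path)
  back <- read_tracks(path)
  expect_equal(attr(back, "report")[["duplicates"]], 1L)
  expect_equal(attr(back, "report")[["malformed"]], 1L)
})

test_that("missing required columns produce a hard error naming them", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(timestamp = "2021-09-01 00:00:00"), path,
            row.names = FALSE)
  expect_error(read_tracks(path), "location-long")
})

test_that("projection preserves spherical distances from the centre", {
  # 0.01 deg of latitude at lat 41 is ~1111.9 m on the mean-radius sphere
  tr <- data.frame(lon = c(-73.84, -73.84), lat = c(41.00, 41.01))
  pr <- project_to_plane(tr, center = c(-73.84, 41.00))
  d <- sqrt(diff(pr$x)^2 + diff(pr$y)^2)
  expect_equal(d, 1111.9, tolerance = 0.5 / 1111.9)
  d_geo <- geosphere::distCosine(c(-73.84, 41.00), c(-73.84, 41.01),
                                 r = 6371008.8)
  expect_equal(d, d_geo, tolerance = 1e-6)
})

test_that("projection centre maps to the origin and reflections are
           antisymmetric", {
  ctr <- c(-73.84, 41.1)
  pr <- project_to_plane(data.frame(lon = ctr[1], lat = ctr[2]), center = ctr)
  expect_equal(c(pr$x, pr$y), c(0, 0), tolerance = 1e-9)
  pts <- data.frame(lon = ctr[1] + c(0.01, -0.01), lat = rep(ctr[2], 2))
  pr2 <- project_to_plane(pts, center = ctr)
  expect_equal(pr2$x[1], -pr2$x[2], tolerance = 1e-9)
  expect_equal(pr2$y[1], pr2$y[2], tolerance = 1e-9)
  expect_error(project_to_plane(data.frame(lon = numeric(0), lat = numeric(0))),
               "empty")
})

test_that("cleaning removes teleporting fixes, out-of-deployment fixes and
           duplicate timestamps, and is idempotent", {
  t0 <- as.POSIXct("2021-09-01", tz = "UTC")
  n <- 20
  tr <- data.frame(t = t0 + 3600 * (0:(n - 1)),
                   x = rnorm(n, 0, 30), y = rnorm(n, 0, 30))
  clean0 <- clean_track(tr)
  expect_identical(clean0$track, tr)
  expect_true(all(clean0$report == 0))

  # teleport: 50 km off-path between 1-h neighbours = 13.9 m/s from both
  tele <- tr; tele$x[10] <- tele$x[10] + 50000
  cl <- clean_track(tele)
  expect_equal(cl$report[["speed"]], 1L)
  expect_equal(nrow(cl$track), n - 1L)

  pre <- rbind(data.frame(t = t0 - 86400, x = 0, y = 0), tr)
  cl2 <- clean_track(pre, deploy_date = t0)
  expect_equal(cl2$report[["pre_deployment"]], 1L)

  dup <- rbind(tr, tr[5, ])
  dup <- dup[order(dup$t), ]
  cl3 <- clean_track(dup)
  expect_equal(cl3$report[["duplicate_time"]], 1L)

  again <- clean_track(cl$track)
  expect_identical(again$track, cl$track)
  expect_true(all(again$report == 0))
})

test_that("day_index maps the study calendar correctly and inverts", {
  y0 <- as.POSIXct("2021-08-01", tz = "America/New_York")
  t_aug1 <- as.POSIXct("2021-08-01 00:00:00", tz = "America/New_York")
  expect_equal(day_index(t_aug1, y0), 0)
  t_aug2 <- as.POSIXct("2021-08-02 12:00:00", tz = "America/New_York")
  expect_equal(day_index(t_aug2, y0), 1.5)
  # 10 Nov 00:00 local is exactly day 101 despite the DST change
  t_nov10 <- as.POSIXct("2021-11-10 00:00:00", tz = "America/New_York")
  expect_equal(day_index(t_nov10, y0), 101)
  # 1 Jan of the following year is day 153
  t_jan1 <- as.POSIXct("2022-01-01 00:00:00", tz = "America/New_York")
  expect_equal(day_index(t_jan1, y0), 153)
  # invertibility
  for (d in c(0, 1.5, 101.25, 153)) {
    expect_equal(day_index(day_index_to_time(d, y0), y0), d, tolerance = 1e-9)
  }
  expect_error(day_index(t_aug1 - 86400, y0), "outside")
})

test_that("moving windows follow the 7/3 scheme with half-open membership", {
  y0 <- as.POSIXct("2021-08-01", tz = "America/New_York")
  t0 <- as.POSIXct("2021-08-01 00:00:00", tz = "America/New_York")
  tt <- seq(t0, by = 3600, length.out = 28 * 24)
  tr <- data.frame(t = tt, x = 0, y = 0, day = day_index(tt, y0))
  w <- make_windows(tr, size = 7, slide = 3)
  expect_equal(length(w), 8L)
  expect_equal(vapply(w, `[[`, 0, "start_day"), seq(0, 21, by = 3))
  expect_equal(w[[1]]$n, 168L)
  expect_true(all(vapply(w, `[[`, TRUE, "valid")))

  # short track: single flagged-invalid window
  short <- tr[tr$day < 2, ]
  ws <- make_windows(short, 7, 3)
  expect_equal(length(ws), 1L)
  expect_false(ws[[1]]$valid)

  # slide = size gives a non-overlapping partition (half-open convention)
  wp <- make_windows(tr, 7, 7)
  counts <- rowSums(vapply(wp, function(wi)
    tr$day >= wi$start_day & tr$day < wi$start_day + 7, logical(nrow(tr))))
  expect_true(all(counts <= 1))
  expect_equal(sum(vapply(wp, `[[`, 0L, "n")), sum(counts == 1))

  # interior fixes fall in floor(size/slide) or ceiling(size/slide) windows
  w73 <- make_windows(tr, 7, 3)
  interior <- tr$day >= 7 & tr$day < 21
  cov <- rowSums(vapply(w73, function(wi)
    tr$day >= wi$start_day & tr$day < wi$start_day + 7, logical(nrow(tr))))
  expect_true(all(cov[interior] %in% c(2L, 3L)))
})

test_that("inclusion filter uses a closed 28-day threshold", {
  t0 <- as.POSIXct("2021-09-01", tz = "UTC")
  mk <- function(days) data.frame(t = t0 + seq(0, days * 86400, by = 3600),
                                  lon = 0, lat = 0)
  tracks <- list(a = mk(27.9), b = mk(28.0), c = mk(40), d = mk(5))
  meta <- data.frame(animal_id = c("a", "b", "c", "d"))
  out <- apply_inclusion_filters(tracks, meta)
  expect_setequal(out$excluded$animal_id, c("a", "d"))
  expect_setequal(names(out$tracks), c("b", "c"))
  expect_equal(nrow(out$meta), 2L)
})
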