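# fix parsing, filtering, grid regularization, monthly segmentation

write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("bird_id,species,age_class,timestamp,lon,lat,utc_offset_h", rows),
             path)
  path
}

test_that("read_fixes parses, drops bad rows and duplicates, handles empty files", {
  p <- write_toy_csv(c("b1,SNI,adult,2021-01-01T00:00:00,145.0,-35.0,10",
                       "b1,SNI,adult,2021-01-01T06:00:00,145.1,-35.1,10",
                       "b1,SNI,adult,2021-01-01T12:00:00,145.2,-35.2,10"))
  trks <- read_fixes(p)
  expect_length(trks, 1)
  expect_equal(nrow(trks$b1), 3)
  expect_s3_class(trks$b1$timestamp, "POSIXct")

  pdup <- write_toy_csv(c("b1,SNI,adult,2021-01-01T00:00:00,145.0,-35.0,10",
                          "b1,SNI,adult,2021-01-01T00:00:00,145.3,-35.3,10"))
  expect_warning(trks2 <- read_fixes(pdup), "duplicate")
  expect_equal(nrow(trks2$b1), 1)
  expect_equal(trks2$b1$lon, 145.0)   # first kept

  pbad <- write_toy_csv(c("b1,SNI,adult,2021-01-01T00:00:00,145.0,-35.0,10",
                          "b1,SNI,adult,not-a-time,145.0,-35.0,10",
                          "b1,SNI,adult,2021-01-01T12:00:00,999,-35.0,10"))
  expect_message(trks3 <- read_fixes(pbad), "2 row")
  expect_equal(nrow(trks3$b1), 1)

  pempty <- write_toy_csv(character())
  expect_identical(read_fixes(pempty), list())

  pnolat <- tempfile(fileext = ".csv")
  writeLines(c("bird_id,timestamp,lon", "b1,2021-01-01T00:00:00,145"), pnolat)
  expect_error(read_fixes(pnolat), "mandatory column")
})

test_that("read_fixes understands the Movebank dialect", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("individual-local-identifier,timestamp,location-long,location-lat",
               "m1,2021-01-01 00:00:00,145.0,-35.0",
               "m1,2021-01-01 06:00:00,145.1,-35.1"), p)
  trks <- read_fixes(p, dialect = "movebank", default_utc_offset_h = 10)
  expect_equal(nrow(trks$m1), 2)
  expect_equal(trks$m1$utc_offset_h, c(10, 10))
})

test_that("filter_tracks enforces the 30-day rule and exclusion windows", {
  mk <- function(days, id) make_track(seq(0, days * 24, by = 6), bird_id = id)
  trks <- list(short = mk(29, "short"), ok = mk(31, "ok"))
  kept <- filter_tracks(trks)
  expect_named(kept, "ok")
  expect_equal(nrow(kept$ok), nrow(trks$ok))      # retained unchanged

  # 60-day track with a 40-day middle exclusion: span of what remains decides
  t60 <- mk(60, "b60")
  win <- list(b60 = data.frame(start = as.Date("2021-01-11"),
                               end = as.Date("2021-02-19")))
  kept2 <- filter_tracks(list(b60 = t60), exclusion_windows = win)
  # remaining fixes: Jan 1-10 and Feb 20-Mar 2 -> span ~60 d >= 30, retained
  expect_named(kept2, "b60")
  expect_lt(nrow(kept2$b60), nrow(t60))
  # but a track whose remaining span collapses below 30 d is dropped
  t35 <- mk(35, "b35")
  win2 <- list(b35 = data.frame(start = as.Date("2021-01-02"),
                                end = as.Date("2021-02-10")))
  expect_length(filter_tracks(list(b35 = t35), exclusion_windows = win2), 0)
  # fix count never increases
  expect_lte(nrow(kept2$b60), nrow(t60))
})

test_that("regularize assigns nearest fixes within tolerance on a UTC-anchored grid", {
  hourly <- make_track(0:47)
  r <- regularize(hourly)
  expect_true(all(r$observed))
  expect_equal(as.numeric(diff(r$timestamp), units = "hours"),
               rep(6, nrow(r) - 1))

  twelve <- make_track(seq(0, 48, by = 12))
  r12 <- regularize(twelve)
  expect_equal(r12$observed, rep(c(TRUE, FALSE), length.out = nrow(r12)))

  near <- make_track(c(5 + 50 / 60, 12))     # 05:50 fix -> 06:00 slot
  rn <- regularize(near)
  slot6 <- which(format(rn$timestamp, "%H") == "06" &
                   as.Date(rn$timestamp) == as.Date("2021-01-01"))
  expect_true(rn$observed[slot6])
  far <- make_track(c(3, 12))                # 03:00 is 180 min from both slots
  rf <- regularize(far)
  expect_equal(sum(rf$observed), 1)
  expect_error(regularize(hourly, grid_interval_h = 0), "grid_interval_h")
})

test_that("regularization is idempotent and never double-assigns a fix", {
  set.seed(3)
  jitter_h <- sort(stats::runif(40, 0, 10 * 24))
  trk <- make_track(jitter_h, x_km = stats::rnorm(40), y_km = stats::rnorm(40))
  r1 <- regularize(trk)
  r2 <- regularize(r1)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  # each observed slot's position matches exactly one raw fix
  obs <- r1[r1$observed, ]
  expect_lte(nrow(obs), nrow(trk))
  expect_false(any(duplicated(paste(obs$lon, obs$lat, obs$timestamp))))
})

test_that("split_months yields one segment per local calendar month", {
  trk <- make_track(seq(0, 90 * 24, by = 6))   # 90 days from Jan 1
  segs <- split_months(regularize(trk))
  expect_equal(unname(vapply(segs, function(s) attr(s, "month"), 0L)),
               c(1L, 2L, 3L, 4L))
  expect_equal(attr(segs[[1]], "window_h"), 31 * 24)
  expect_equal(attr(segs[[2]], "window_h"), 28 * 24)

  # single-fix month flagged by its n_fixes
  one <- make_track(c(0, 6, 40 * 24))
  segs1 <- split_months(regularize(one))
  expect_equal(attr(segs1[[2]], "n_fixes"), 1L)

  empty <- regularize(make_track(c(0, 6)))
  empty$lon <- NA_real_; empty$lat <- NA_real_; empty$observed <- FALSE
  expect_identical(split_months(empty), list())

  # local-time month membership: a 23:00 UTC fix on Jan 31 is February at +10h
  lt <- make_track(31 * 24 - 1, utc_offset_h = 10)
  lt2 <- rbind(make_track(0, utc_offset_h = 10), lt)
  segs2 <- split_months(regularize(lt2, tolerance_min = 90))
  expect_equal(unname(vapply(segs2, function(s) attr(s, "month"), 0L)), c(1L, 2L))
})

test_that("regular tracks and GeoJSON lines round-trip", {
  trk <- make_track(seq(0, 10 * 24, by = 6), x_km = sin(1:41), y_km = cos(1:41))
  r <- regularize(trk)
  p <- tempfile(fileext = ".csv")
  write_regular_csv(r, p)
  r2 <- read_regular_csv(p)
  expect_equal(r2$lon, r$lon)
  expect_equal(attr(r2, "grid_interval_h"), attr(r, "grid_interval_h"))

  gj <- tempfile(fileext = ".geojson")
  write_track_geojson(trk, gj)
  parsed <- jsonlite::fromJSON(gj, simplifyVector = FALSE)
  expect_equal(parsed$features[[1]]$geometry$type, "LineString")
  expect_length(parsed$features[[1]]$geometry$coordinates, nrow(trk))
})
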