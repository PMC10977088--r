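# GPX reading, trip segmentation, logbook parsing, sighting association.

t0 <- as.POSIXct("2018-07-02 09:00:00", tz = "UTC")

test_that("read_gpx returns fixes in order and rejects untimed points", {
  p <- gpx_file(lat = c(-7.1, -7.11, -7.12), lon = c(-34.8, -34.81, -34.82),
                times = t0 + c(0, 300, 600))
  fx <- read_gpx(p, fisher_id = "F1")
  expect_equal(nrow(fx), 3)
  expect_equal(fx$lat, c(-7.1, -7.11, -7.12))
  expect_equal(as.numeric(diff(fx$timestamp)), c(5, 5))  # minutes
  expect_identical(fx$fisher_id, rep("F1", 3))

  p_bad <- gpx_file(lat = c(-7.1, -7.11), lon = c(-34.8, -34.81),
                    times = t0 + c(0, 300), drop_time_at = 2)
  expect_error(read_gpx(p_bad), "point 2.*no <time>")
})

test_that("an 8-hour trip at 5-min cadence reads back as 97 fixes", {
  n <- 8 * 12 + 1
  p <- gpx_file(lat = rep(-7.1, n), lon = -34.8 + (1:n) * 1e-4,
                times = t0 + (0:(n - 1)) * 300)
  expect_equal(nrow(read_gpx(p)), 97)
})

test_that("segment_trips splits on gaps and preserves every fix", {
  fx <- data.frame(timestamp = t0 + (0:20) * 300, lat = -7.1, lon = -34.8,
                   fisher_id = "F1", source_file = "x.gpx")
  one <- segment_trips(fx)
  expect_equal(length(unique(one$trip_id)), 1)

  # a single 6-h gap with a 4-h threshold forces exactly two trips
  fx2 <- fx
  fx2$timestamp[12:21] <- fx2$timestamp[12:21] + 6 * 3600
  two <- segment_trips(fx2, gap_threshold = 4 * 3600)
  expect_equal(length(unique(two$trip_id)), 2)

  # concatenating trips in order reproduces the input sequence exactly
  expect_identical(two$timestamp, fx2$timestamp)
  expect_false(anyNA(two$trip_id))

  expect_error(segment_trips(fx[c(2, 1, 3), ]), "not time-sorted")
})

test_that("trip count equals 1 + number of gaps above threshold (random gap patterns)", {
  set.seed(99)
  for (i in 1:20) {
    # runs of small gaps separated by overnight-scale gaps, so every trip
    # keeps at least 2 fixes
    n_trips <- sample(1:6, 1)
    gaps <- numeric(0)
    for (k in seq_len(n_trips)) {
      gaps <- c(gaps, rep(300, sample(3:10, 1)))
      if (k < n_trips) gaps <- c(gaps, runif(1, 5, 12) * 3600)
    }
    fx <- data.frame(timestamp = t0 + cumsum(c(0, gaps)), lat = -7.1,
                     lon = -34.8, fisher_id = "F1", source_file = "x.gpx")
    segd <- segment_trips(fx, gap_threshold = 4 * 3600)
    expect_equal(length(unique(segd$trip_id)), 1 + sum(gaps > 4 * 3600))
  }
})

test_that("single-fix trips are discarded with a warning", {
  fx <- data.frame(
    timestamp = t0 + c(0, 300, 600, 10 * 3600, 20 * 3600, 20 * 3600 + 300),
    lat = -7.1, lon = -34.8, fisher_id = "F1", source_file = "x.gpx")
  expect_warning(segd <- segment_trips(fx), "single-fix")
  expect_true(is.na(segd$trip_id[4]))
  expect_equal(length(unique(na.omit(segd$trip_id))), 2)
})

make_records <- function(times, fisher = "F1", date = "2018-07-02") {
  data.frame(date = as.Date(date), time = times, fisher_id = fisher,
             community = "Penha", folk_name = "turtle",
             species = NA_character_, n_individuals = 1L,
             life_stage = "unknown", sex = "unknown", stringsAsFactors = FALSE)
}

test_that("match_sightings picks the nearest same-day fix of the same fisher", {
  # logbook clocks are local (UTC-3); fixes at 10:00 and 10:05 local
  fixes <- data.frame(timestamp = as.POSIXct("2018-07-02 13:00:00", tz = "UTC") + c(0, 300),
                      lat = c(-7.10, -7.20), lon = c(-34.8, -34.9),
                      fisher_id = "F1", source_file = "x.gpx")
  # exact hit
  m0 <- match_sightings(make_records("10:00:00"), fixes)
  expect_true(m0$matched)
  expect_equal(m0$time_offset, 0)
  expect_equal(m0$lat, -7.10)
  # 10:02 -> the 10:00 fix, offset 120 s
  m1 <- match_sightings(make_records("10:02:00"), fixes)
  expect_true(m1$matched)
  expect_equal(abs(m1$time_offset), 120)
  expect_equal(m1$lat, -7.10)
  # beyond tolerance -> unmatched but retained
  m2 <- match_sightings(make_records("10:25:00"), fixes, tolerance = 150)
  expect_false(m2$matched)
  expect_equal(nrow(m2), 1)
  # fisher with no fixes that date -> unmatched, not dropped
  m3 <- match_sightings(make_records("10:00:00", fisher = "F9"), fixes)
  expect_false(m3$matched)
  # equidistant tie goes to the earlier fix
  m4 <- match_sightings(make_records("10:02:30"), fixes)
  expect_equal(m4$lat, -7.10)
})

test_that("match_sightings is stable under record permutation", {
  fixes <- data.frame(timestamp = as.POSIXct("2018-07-02 12:00:00", tz = "UTC") + (0:30) * 300,
                      lat = -7.1 - (0:30) * 1e-3, lon = -34.8,
                      fisher_id = "F1", source_file = "x.gpx")
  recs <- make_records(sprintf("09:%02d:00", seq(1, 51, by = 5)))
  m <- match_sightings(recs, fixes)
  perm <- sample(nrow(recs))
  mp <- match_sightings(recs[perm, ], fixes)
  expect_equal(mp$lat, m$lat[perm])
  expect_equal(mp$time_offset, m$time_offset[perm])
})

test_that("read_logbook validates schema, counts and species registry", {
  lb <- study_effort_logbook()[1:3, ]
  p <- tempfile(fileext = ".csv")
  write_logbook(lb, p)
  r <- read_logbook(p)
  expect_equal(nrow(r), 3)
  expect_identical(r$folk_name, lb$folk_name)

  bad <- lb; bad$n_individuals[2] <- 0L
  write_logbook(bad, p)
  expect_error(read_logbook(p), "n_individuals")

  bad2 <- lb; bad2$species[1] <- "Testudo graeca"
  write_logbook(bad2, p)
  expect_error(read_logbook(p), "registry")

  writeLines("date,time,fisher_id\n2018-07-02,10:00,F1", p)
  expect_error(read_logbook(p), "missing column")
})

test_that("the study-effort fixture reproduces the published per-fisher totals", {
  path <- system.file("extdata", "logbook_effort_synthetic.csv",
                      package = "turtlerisk")
  r <- read_logbook(path)
  counts <- table(r$fisher_id)
  expect_equal(as.integer(counts[paste0("F", 1:9)]),
               c(65, 7, 61, 5, 22, 7, 30, 19, 2))
  expect_equal(nrow(r), 218)
})
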