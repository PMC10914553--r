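test_that("field_series validates and records metadata", {
  fs <- make_field(rep(6, 120))
  expect_s3_class(fs, "field_series")
  expect_true(attr(fs, "cadence_ok"))
  expect_error(make_field(c(25, 6)), "\\[0, 20\\]")
  expect_error(field_series(Sys.time() + c(0, -60), c(6, 6),
                            position = "interior"), "not increasing")
  # a 10-min hole is recorded as a gap
  t0 <- as.POSIXct("2022-02-08", tz = "UTC")
  tt <- c(t0 + 60 * (0:59), t0 + 600 + 60 * (60:119))
  g <- field_series(tt, rep(6, 120), position = "exterior")
  expect_length(attr(g, "gaps"), 1L)
})

test_that("read_logger_csv round-trips and flags cadence", {
  f <- withr::local_tempfile(fileext = ".csv")
  t0 <- as.POSIXct("2022-02-08 00:00:00", tz = "UTC")
  write.csv(data.frame(datetime = format(t0 + 60 * (0:149)),
                       do_mgL = 6 + 0.01 * (0:149)), f, row.names = FALSE)
  fs <- read_logger_csv(f, "interior", "c1")
  expect_equal(length(fs$do_mgL), 150L)
  expect_equal(fs$position, "interior")

  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(datetime = format(t0 + 600 * (0:119)),
                       do_mgL = rep(6, 120)), f2, row.names = FALSE)
  expect_warning(read_logger_csv(f2, "interior", "c1"), "cadence")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("datetime,do_mgL", f3)
  expect_error(read_logger_csv(f3, "interior", "c1"), "empty")
})

test_that("summarize_series computes time-weighted statistics", {
  expect_error(summarize_series(make_field(rep(6, 50))), ">= 100")
  s <- summarize_series(make_field(rep(6, 200)), thresholds = 5)
  expect_equal(unname(s$fraction_below["5"]), 0)
  expect_equal(s$mean, 6)
  s2 <- summarize_series(make_field(rep(c(4, 4, 6, 6), 50)), thresholds = 5)
  expect_equal(unname(s2$fraction_below["5"]), 0.5, tolerance = 0.01)
  # fraction below monotone in threshold
  s3 <- summarize_series(make_field(4 + 4 * (0:199) / 199),
                         thresholds = c(3, 5, 6, 9))
  expect_true(all(diff(s3$fraction_below) >= 0))
  expect_true(s3$min <= s3$mean && s3$mean <= s3$max)
})

test_that("sinusoid time-below matches the arcsine closed form", {
  # DO = 6 + 2 sin(2 pi t / T), 10 full cycles: below 5 one third of time
  tt <- 0:5999
  do <- 6 + 2 * sin(2 * pi * tt / 600)
  s <- summarize_series(make_field(do), thresholds = 5)
  expect_equal(unname(s$fraction_below["5"]), 1 / 3, tolerance = 0.01)
})

test_that("cumulative histogram partitions time", {
  h <- cumulative_time_histogram(make_field(rep(6, 200)), bin_width = 1,
                                 origin = 5.5)
  expect_equal(nrow(h), 1L)
  expect_equal(h$lo, 5.5)
  expect_equal(h$fraction, 1)
  # sinusoid fractions match a direct equal-weight tally
  do <- 6 + 2 * sin(2 * pi * (0:5999) / 600)
  h2 <- cumulative_time_histogram(make_field(do), bin_width = 0.5)
  expect_equal(sum(h2$fraction), 1, tolerance = 1e-9)
  tally <- table(floor((do - min(h2$lo)) / 0.5)) / length(do)
  expect_equal(h2$fraction, as.numeric(tally), tolerance = 0.01)
})

test_that("interior/exterior deltas behave on constructed pairs", {
  int <- make_field(rep(6, 200), "interior")
  ext_same <- make_field(rep(6, 200), "exterior")
  d0 <- interior_exterior_delta(int, ext_same)
  expect_equal(d0$delta_mean, 0)
  expect_equal(d0$pct_diff, 0)
  v <- 6 + sin(2 * pi * (0:199) / 50)
  d <- interior_exterior_delta(make_field(v, "interior"),
                               make_field(v + 0.5, "exterior"))
  expect_equal(d$delta_mean, 0.5, tolerance = 1e-9)
  expect_equal(d$delta_range, 0, tolerance = 1e-9)
  # antisymmetric under swapping the series
  dsw <- interior_exterior_delta(make_field(v + 0.5, "interior"),
                                 make_field(v, "exterior"))
  expect_equal(dsw$delta_mean, -d$delta_mean)
  expect_equal(dsw$delta_range, -d$delta_range)
})

test_that("delta contracts: colony identity and overlap", {
  int <- make_field(rep(6, 200), "interior", colony_id = "a")
  ext <- make_field(rep(6, 200), "exterior", colony_id = "b")
  expect_error(interior_exterior_delta(int, ext), "different colonies")
  late <- make_field(rep(6, 200), "exterior", colony_id = "a",
                     start = "2022-03-01 00:00:00")
  expect_error(interior_exterior_delta(int, late), "overlap")
})

test_that("tide/sun alignment joins and classifies day/night", {
  fs <- make_field(rep(6, 1440), start = "2022-02-08 00:00:00")
  t0 <- as.POSIXct("2022-02-08 00:00:00", tz = "UTC")
  tides <- data.frame(datetime = format(t0 + 3600 * (0:24)),
                      height = sin(2 * pi * (0:24) / 12.42))
  sun <- data.frame(date = "2022-02-08", sunrise = "06:00:00",
                    sunset = "18:00:00")
  j <- align_with_tides(fs, tides, sun)
  expect_true(all(j$tide_offset_min <= 30))
  expect_false(j$is_day[1])
  # flag flips exactly at sunset
  at <- format(j$timestamp, "%H:%M:%S")
  expect_true(j$is_day[match("17:59:00", at)])
  expect_false(j$is_day[match("18:00:00", at)])
  # coverage failures are reported
  expect_error(align_with_tides(fs, tides[1:3, ], sun), "cover")
  sun_wrong <- data.frame(date = "2022-02-09", sunrise = "06:00:00",
                          sunset = "18:00:00")
  expect_error(align_with_tides(fs, tides, sun_wrong), "missing date")
})
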