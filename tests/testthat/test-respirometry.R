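test_that("drawdown_trace enforces its invariants", {
  expect_s3_class(linear_trace(), "drawdown_trace")
  expect_error(drawdown_trace("x", c(0, 60, 60), c(100, 99, 98)),
               "not strictly increasing at row 3")
  expect_error(drawdown_trace("x", c(0, 60), c(100, 130)), "tolerated range")
  expect_error(drawdown_trace("x", c(0, 60), c(100, 99),
                              chamber_volume = 400,
                              displacement_volume = 400),
               "displacement_volume")
  expect_error(drawdown_trace("x", c(0, 60), c(100, 99),
                              displacement_volume = 10, is_blank = TRUE),
               "blank")
})

test_that("read_firesting_csv parses, cleans and validates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,airsat_pct,temp_C",
               "0,100,27", "60,99.5,27", "120,99.0,27"), f)
  tr <- read_firesting_csv(f, meta = list(chamber_id = "ch1"))
  expect_length(tr$timestamps, 3L)
  expect_equal(tr$airsat, c(100, 99.5, 99))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,temp_C", "0,27"), f2)
  expect_error(read_firesting_csv(f2), "airsat_pct")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,airsat_pct", "0,100", "0,99"), f3)
  expect_error(read_firesting_csv(f3), "row 2")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,airsat_pct", "0,100", "60,NA", "120,99"), f4)
  expect_message(tr4 <- read_firesting_csv(f4), "dropped 1 row")
  expect_length(tr4$airsat, 2L)

  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,airsat_pct", "0,NA", "60,NA"), f5)
  expect_error(suppressMessages(read_firesting_csv(f5)), "no usable rows")
})

test_that("vo2 of a linear decline matches the closed form", {
  # 100 -> 0 % over 4 h: volumetric rate = C_sat/4 per hour, times v_net
  tr <- linear_trace(hours = 4, chamber_volume = 400,
                     displacement_volume = 50)
  rates <- compute_vo2_curve(tr, blank = NULL)
  csat <- o2_solubility(27, 35)
  expect_equal(rates$vo2, rep(csat / 4 * 0.35, nrow(rates)),
               tolerance = 1e-9)
})

test_that("a blank identical to the trace self-subtracts to zero", {
  tr <- linear_trace(displacement_volume = 0)
  bl <- linear_trace(displacement_volume = 0, id = "blank",
                     is_blank = TRUE)
  rates <- compute_vo2_curve(tr, bl)
  expect_equal(max(abs(rates$vo2)), 0, tolerance = 1e-12)
})

test_that("vo2 contracts: window size, blank displacement", {
  tr <- linear_trace()
  expect_error(compute_vo2_curve(tr, window = 120), ">= 5 samples")
  short <- linear_trace(hours = 0.1)
  expect_error(compute_vo2_curve(short, window = 600),
               "window longer than trace")
  bad_blank <- linear_trace(displacement_volume = 10, id = "bb")
  expect_error(compute_vo2_curve(tr, bad_blank), "nonzero displacement")
})

test_that("vo2 is invariant to uniform time translation", {
  tr <- linear_trace()
  shifted <- tr
  shifted$timestamps <- tr$timestamps + 7200
  expect_equal(compute_vo2_curve(shifted)$vo2, compute_vo2_curve(tr)$vo2)
})

test_that("doubling v_net doubles every vo2 at zero blank", {
  tr1 <- linear_trace(chamber_volume = 400, displacement_volume = 0)
  tr2 <- linear_trace(chamber_volume = 800, displacement_volume = 0)
  expect_equal(compute_vo2_curve(tr2)$vo2, 2 * compute_vo2_curve(tr1)$vo2)
})

test_that("conformer trace yields vo2 proportional to pO2 (R^2 > 0.99)", {
  sim <- simulate_drawdown(regulator_model("conformer"),
                           simulation_config(noise_sd = 0, blank_rate = 0))
  rates <- compute_vo2_curve(sim$trace, sim$blank)
  fit <- lm(vo2 ~ pO2_mid, data = rates)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("drawdown_duration interpolates crossings linearly", {
  tr6 <- linear_trace(hours = 6)
  d1 <- drawdown_duration(tr6, 100, 0)
  expect_equal(d1$hours, 6, tolerance = 1e-9)
  expect_false(d1$censored)
  d2 <- drawdown_duration(tr6, 100, 2)
  expect_equal(d2$hours, 5.88, tolerance = 1e-9)
})

test_that("drawdown_duration censors traces that never reach `end`", {
  tr <- linear_trace(from = 100, to = 5, hours = 6)
  d <- drawdown_duration(tr, 100, 0)
  expect_true(d$censored)
  expect_equal(d$min_airsat, 5)
  expect_equal(d$hours, 6, tolerance = 1e-9)
})

test_that("normalize_curve normalizes to the top-decile reference", {
  # constant rates: y identically 1
  p <- seq(2, 98, length.out = 30)
  hc <- normalize_curve(raw_rates(p, rep(0.5, 30)))
  expect_equal(hc$y, rep(1, 30))
  expect_equal(hc$y_ref, 0.5)
  # proportional rates: y = x / mean(top-decile x)
  hc2 <- normalize_curve(raw_rates(p, 0.004 * p))
  xtop <- mean(p[p >= quantile(p, 0.9)]) / 100
  expect_equal(hc2$y, (p / 100) / xtop, tolerance = 1e-12)
})

test_that("normalize_curve contracts", {
  expect_error(normalize_curve(raw_rates(seq(10, 90, 20), rep(1, 5))),
               ">= 10 rate points")
  expect_error(normalize_curve(raw_rates(seq(50, 90, length.out = 12),
                                         rep(1, 12))), "span")
  expect_error(normalize_curve(raw_rates(seq(2, 98, length.out = 12),
                                         rep(-1, 12))), "non-respiring")
})
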