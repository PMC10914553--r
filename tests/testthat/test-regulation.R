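mm_fit <- function(vmax, k) {
  suppressWarnings(  # exact recovery can hit rss = 0 -> AIC -Inf warning
    fit_model(curve_from_fn(function(x) vmax * x / (k + x), n = 60),
              model_spec("michaelis_menten")))
}

test_that("rho identities hold analytically", {
  lin <- suppressWarnings(fit_model(curve_from_fn(identity),
                                    model_spec("linear")))
  expect_equal(rho(lin, c(0, 0.3, 1)), c(0, 0, 0))
  # MM closed form Vmax x / (K + x)^2
  expect_equal(rho(mm_fit(1, 0.25), 0.25), 1.0, tolerance = 1e-6)
  # f = x^2: rho = x - 2x = -x
  sq <- suppressWarnings(fit_model(curve_from_fn(function(x) x^2),
                                   model_spec("constrained_poly", 2)))
  expect_equal(rho(sq, 0.5), -0.5, tolerance = 1e-8)
  expect_error(rho(sq, 1.5), "outside")
})

test_that("rho on custom fits handles the origin correctly", {
  const <- hrc_fit_custom(function(x) rep(1, length(x)),
                          function(x) rep(0, length(x)))
  expect_equal(rho(const, 0.5), 2)
  expect_error(rho(const, 0), "singular")
  ident <- hrc_fit_custom(identity, function(x) rep(1, length(x)))
  expect_equal(rho(ident, c(0, 0.5)), c(0, 0))
})

test_that("finite-difference rho matches analytic rho to 1e-6", {
  fits <- list(mm_fit(1.1, 0.12),
               suppressWarnings(
                 fit_model(curve_from_fn(function(x) 2 * x - 1.2 * x^2 +
                                           0.3 * x^4),
                           model_spec("constrained_poly", 4))))
  g <- seq(0.02, 0.98, length.out = 300)
  h <- 1e-6
  for (fit in fits) {
    fd <- predict(fit, g) / g -
      (predict(fit, g + h) - predict(fit, g - h)) / (2 * h)
    expect_equal(rho(fit, g), fd, tolerance = 1e-6)
  }
})

test_that("profile extracts the MM arg-maximum at x = K", {
  prof <- regulation_profile(mm_fit(1, 0.2), x_window = c(0.02, 0.98))
  expect_equal(prof$p_cmax, 20, tolerance = 1e-4)
  expect_gt(prof$t_pos, 0)
})

test_that("P_cmax sits at 100K across random K (one grid step)", {
  set.seed(7)
  for (k in runif(6, 0.05, 0.8)) {
    prof <- regulation_profile(mm_fit(1, k), x_window = c(0.02, 0.98),
                               grid_n = 1000)
    expect_equal(prof$p_cmax, 100 * k, tolerance = 0.1 / (100 * k))
  }
})

test_that("strict conformity gives zero regulation and undefined extrema", {
  lin <- suppressWarnings(fit_model(curve_from_fn(identity),
                                    model_spec("linear")))
  prof <- regulation_profile(lin)
  expect_equal(prof$t_pos, 0)
  expect_equal(prof$t_neg, 0)
  expect_true(is.na(prof$p_cmax) && is.na(prof$p_cmin))
})

test_that("constant regulator integrates to log(x_hi/x_lo)", {
  const <- hrc_fit_custom(function(x) rep(1, length(x)),
                          function(x) rep(0, length(x)))
  prof <- regulation_profile(const, x_window = c(0.02, 0.98), grid_n = 4000)
  expect_equal(prof$t_pos, log(0.98 / 0.02), tolerance = 1e-3)
})

test_that("profile contracts and numerical properties", {
  fit <- mm_fit(1, 0.15)
  expect_error(regulation_profile(fit, x_window = c(0.5, 0.4)), "x_lo")
  expect_error(regulation_profile(fit, grid_n = 50), "grid_n")
  # rho -> 0 as x -> 0 for origin-constrained fits
  expect_lt(abs(rho(fit, 1e-6)), 1e-4)
  # t_pos stable under grid refinement
  t1 <- regulation_profile(fit, grid_n = 1000)$t_pos
  t2 <- regulation_profile(fit, grid_n = 2000)$t_pos
  expect_lt(abs(t1 - t2), 1e-4)
  # range_mean mode divides by the window width
  pr <- regulation_profile(fit, x_window = c(0.02, 0.98))
  pm <- regulation_profile(fit, x_window = c(0.02, 0.98),
                           tpos_mode = "range_mean")
  expect_equal(pm$t_pos, pr$t_pos / 0.96)
})

test_that("scaling y scales rho and t_pos, leaves P_cmax fixed", {
  f1 <- mm_fit(1, 0.2)
  f3 <- mm_fit(3, 0.2)
  p1 <- regulation_profile(f1, x_window = c(0.02, 0.98))
  p3 <- regulation_profile(f3, x_window = c(0.02, 0.98))
  expect_equal(p3$t_pos, 3 * p1$t_pos, tolerance = 1e-6)
  expect_equal(p3$rho, 3 * p1$rho, tolerance = 1e-6)
  expect_equal(p3$p_cmax, p1$p_cmax, tolerance = 1e-6)
  expect_equal(p3$p_cmin, p1$p_cmin, tolerance = 1e-6)
})

test_that("replicate_summary aggregates with SE and NA handling", {
  prof <- regulation_profile(mm_fit(1, 0.2))
  expect_error(replicate_summary(list(prof)), ">= 2")
  s3 <- replicate_summary(list(prof, prof, prof))
  expect_equal(s3$se[s3$statistic == "t_pos"], 0)
  # hand-computed: {0.5, 1.0, 1.5} -> mean 1, SE 0.2887
  ps <- lapply(c(0.5, 1.0, 1.5), function(v) {
    p <- prof; p$t_pos <- v; p
  })
  s <- replicate_summary(ps)
  expect_equal(s$mean[s$statistic == "t_pos"], 1.0)
  expect_equal(s$se[s$statistic == "t_pos"], 0.288675, tolerance = 1e-5)
  # undefined entries excluded with a recorded count
  pna <- prof; pna$p_cmax <- NA_real_
  s2 <- replicate_summary(list(prof, prof, pna))
  expect_equal(s2$n_undefined[s2$statistic == "p_cmax"], 1L)
  expect_equal(s2$n[s2$statistic == "p_cmax"], 2L)
  lin <- suppressWarnings(fit_model(curve_from_fn(identity),
                                    model_spec("linear")))
  lp <- regulation_profile(lin)
  expect_warning(replicate_summary(list(lp, lp)), "undefined in every")
})
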