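#' Ground-truth respiration kinetics for simulation
#'
#' Oxygen consumption as a function of ambient pO2, VO2(pO2) =
#' basal_rate * g(pO2/100), with g one of: `conformer` g(x) = x (strict
#' oxyconformity); `mm` the endpoint-normalised Michaelis-Menten
#' g(x) = (1 + K) x / (K + x), so basal_rate is the rate at full
#' saturation regardless of K; or `poly` with supplied origin-constrained
#' coefficients.
#'
#' @param kind "conformer", "mm" or "poly".
#' @param basal_rate mg O2 h^-1 at 100% air saturation (> 0). Default 0.3,
#'   which drains a 400-mL chamber (50 mL displacement) from saturation in
#'   roughly 8 h at 27 degC — the middle of the typical 6-12 h run.
#' @param K Michaelis constant, dimensionless pO2 in (0, 1) (mm only).
#' @param coefficients polynomial coefficients a1..ad (poly only).
#' @return a `regulator_model`.
#' @export
regulator_model <- function(kind = c("conformer", "mm", "poly"),
                            basal_rate = 0.3, K = NULL,
                            coefficients = NULL) {
  kind <- match.arg(kind)
  stopifnot(basal_rate > 0)
  if (kind == "mm") {
    if (is.null(K) || K <= 0 || K >= 1) {
      stop("regulator_model: mm needs K in (0, 1)", call. = FALSE)
    }
  }
  if (kind == "poly" && is.null(coefficients)) {
    stop("regulator_model: poly needs coefficients", call. = FALSE)
  }
  m <- structure(list(kind = kind, basal_rate = basal_rate, K = K,
                      coefficients = coefficients),
                 class = "regulator_model")
  g <- model_g(m)
  if (any(g(seq(0.01, 1, by = 0.01)) < 0)) {
    stop("regulator_model: VO2 negative within (0, 1]", call. = FALSE)
  }
  m
}

model_g <- function(model) {
  switch(model$kind,
    conformer = function(x) x,
    mm = function(x) (1 + model$K) * x / (model$K + x),
    poly = function(x) horner0(model$coefficients, x))
}

#' Simulation settings for a sealed-chamber drawdown
#'
#' Defaults mirror a standard coral respirometry set-up: 400-mL glass
#' chambers, ~50 mL fragment displacement, 27 degC seawater, 60-s optode
#' logging, start near 100% air saturation, Gaussian sensor noise of
#' 0.5% air saturation, and a small microbial background drawdown.
#'
#' @param chamber_volume mL. @param displacement mL.
#' @param temperature degC. @param salinity ppt.
#' @param start_airsat initial percent air saturation.
#' @param dt logging interval, s. @param noise_sd sensor noise sd,
#'   percent air saturation (noise lives in the sensor domain, not
#'   concentration). @param blank_rate microbial volumetric consumption,
#'   mg L^-1 h^-1. @param seed RNG seed; mandatory whenever noise_sd > 0.
#' @param max_hours hard stop (default 12).
#' @return a `simulation_config`.
#' @export
simulation_config <- function(chamber_volume = 400, displacement = 50,
                              temperature = 27, salinity = 35,
                              start_airsat = 100, dt = 60, noise_sd = 0.5,
                              blank_rate = 0.01, seed = NULL,
                              max_hours = 12) {
  stopifnot(dt > 0, noise_sd >= 0, displacement < chamber_volume,
            max_hours > 0)
  if (noise_sd > 0 && is.null(seed)) {
    stop("simulation_config: seed is mandatory for stochastic simulation",
         call. = FALSE)
  }
  structure(list(chamber_volume = chamber_volume, displacement = displacement,
                 temperature = temperature, salinity = salinity,
                 start_airsat = start_airsat, dt = dt, noise_sd = noise_sd,
                 blank_rate = blank_rate, seed = seed,
                 max_hours = max_hours),
            class = "simulation_config")
}

#' Simulate a sealed-chamber drawdown and its paired blank
#'
#' Integrates dC/dt = -[VO2(pO2)/v_net + blank_rate] by classical RK4 at
#' the logging cadence (Euler drifts measurably for fast conformers),
#' converts to percent air saturation via [o2_solubility()], and adds
#' i.i.d. Gaussian sensor noise. Integration terminates the way the assay
#' does: on crossing below 2% air saturation (effective anoxia) or at
#' `max_hours`. The paired blank integrates `blank_rate` alone.
#'
#' @param model a `regulator_model`.
#' @param config a `simulation_config`.
#' @param chamber_id id prefix for the two traces.
#' @return list with `trace` and `blank` (both `drawdown_trace`), plus
#'   `truth` (the inputs and v_net) for parameter-recovery tests.
#' @export
simulate_drawdown <- function(model, config = simulation_config(seed = 1),
                              chamber_id = "sim") {
  stopifnot(inherits(model, "regulator_model"),
            inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  csat <- o2_solubility(config$temperature, config$salinity)
  v_net <- (config$chamber_volume - config$displacement) / 1000
  g <- model_g(model)
  dC <- function(C) {
    x <- max(C, 0) / csat
    -(model$basal_rate * g(x) / v_net + config$blank_rate)
  }
  dt_h <- config$dt / 3600
  n_max <- ceiling(config$max_hours / dt_h) + 1L
  C <- numeric(n_max)
  C[1] <- config$start_airsat / 100 * csat
  # terminate like the assay: at effective anoxia (< 2% air sat) or the cap
  c_stop <- 0.02 * csat
  n <- 1L
  while (n < n_max && C[n] > c_stop) {
    k1 <- dC(C[n])
    k2 <- dC(C[n] + dt_h / 2 * k1)
    k3 <- dC(C[n] + dt_h / 2 * k2)
    k4 <- dC(C[n] + dt_h * k3)
    C[n + 1L] <- max(C[n] + dt_h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    n <- n + 1L
  }
  C <- C[seq_len(n)]
  tt <- (seq_len(n) - 1L) * config$dt
  noisy <- function(conc) {
    a <- 100 * conc / csat
    if (config$noise_sd > 0) {
      a <- a + stats::rnorm(length(a), 0, config$noise_sd)
    }
    pmin(pmax(a, -2), 120)
  }
  trace <- drawdown_trace(paste0(chamber_id, "_coral"), tt, noisy(C),
                          temperature = config$temperature,
                          chamber_volume = config$chamber_volume,
                          displacement_volume = config$displacement)
  Cb <- pmax(C[1] - config$blank_rate * tt / 3600, 0)
  blank <- drawdown_trace(paste0(chamber_id, "_blank"), tt, noisy(Cb),
                          temperature = config$temperature,
                          chamber_volume = config$chamber_volume,
                          displacement_volume = 0, is_blank = TRUE)
  list(trace = trace, blank = blank,
       truth = list(model = model, config = config, v_net = v_net,
                    csat = csat))
}

#' Simulate a replicated two-group respirometry experiment
#'
#' Emulates an interior-versus-exterior (or clipped-versus-fresh) design:
#' `n_per_group` fragments per group, each drawn down under group-specific
#' Michaelis-Menten kinetics, with the ground-truth parameters recorded in
#' the sample sheet.
#'
#' @param n_per_group fragments per group (>= 2; default 6).
#' @param group_effects list with numeric `K` and `basal_rate`, one value
#'   per group; group labels come from `names(K)` (default interior /
#'   exterior).
#' @param noise_sd sensor noise, percent air saturation.
#' @param seed RNG seed (mandatory).
#' @param ... further arguments to [simulation_config()].
#' @return list: `sheet` (data frame: chamber_id, group, K_true,
#'   basal_true), `traces`, `blanks` (named lists of `drawdown_trace`).
#' @export
make_experiment_fixture <- function(n_per_group = 6,
                                    group_effects = list(
                                      K = c(interior = 0.05,
                                            exterior = 0.20),
                                      basal_rate = c(0.3, 0.3)),
                                    noise_sd = 0.5, seed, ...) {
  stopifnot(n_per_group >= 2)
  groups <- names(group_effects$K)
  if (is.null(groups)) groups <- paste0("group_", seq_along(group_effects$K))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L,
                      n_per_group * length(groups))
  sheet <- list()
  traces <- list()
  blanks <- list()
  k <- 0L
  for (gi in seq_along(groups)) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", groups[gi], i)
      model <- regulator_model("mm", basal_rate = group_effects$basal_rate[gi],
                               K = group_effects$K[[gi]])
      cfg <- simulation_config(noise_sd = noise_sd,
                               seed = if (noise_sd > 0) seeds[k] else NULL,
                               ...)
      sim <- simulate_drawdown(model, cfg, chamber_id = id)
      traces[[id]] <- sim$trace
      blanks[[id]] <- sim$blank
      sheet[[k]] <- data.frame(chamber_id = id, group = groups[gi],
                               K_true = group_effects$K[[gi]],
                               basal_true = group_effects$basal_rate[gi])
    }
  }
  list(sheet = do.call(rbind, sheet), traces = traces, blanks = blanks)
}

#' Simulate paired interior/exterior field DO logger series
#'
#' Exterior DO = mean + a diel sinusoid (24-h period, peaking
#' mid-afternoon) + a tidal sinusoid (12.42-h principal lunar period) +
#' Gaussian noise. The interior series is the clean exterior signal scaled
#' down by `interior_pct_offset` percent with independent noise. 60-s
#' cadence.
#'
#' @param mean_do exterior mean DO, mg L^-1 (default 6.5).
#' @param diel_amplitude mg L^-1 (default 1.5).
#' @param tidal_amplitude mg L^-1 (default 0.3).
#' @param interior_pct_offset percent by which the interior is lower on
#'   average (default 10).
#' @param noise_sd sensor noise, mg L^-1 (default 0.1).
#' @param days deployment length, days (>= 1; default 3).
#' @param seed RNG seed (mandatory when noise_sd > 0).
#' @param colony_id label for both series.
#' @param start start time (default 2022-02-08 00:00 UTC).
#' @return list with `interior` and `exterior` (`field_series`).
#' @export
simulate_field_series <- function(mean_do = 6.5, diel_amplitude = 1.5,
                                  tidal_amplitude = 0.3,
                                  interior_pct_offset = 10,
                                  noise_sd = 0.1, days = 3, seed = NULL,
                                  colony_id = "colony",
                                  start = "2022-02-08 00:00:00") {
  stopifnot(days >= 1)
  if (noise_sd > 0 && is.null(seed)) {
    stop("simulate_field_series: seed mandatory when noise_sd > 0",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  t0 <- as.POSIXct(start, tz = "UTC")
  n <- days * 24 * 60
  tt <- t0 + 60 * (seq_len(n) - 1L)
  hours <- (seq_len(n) - 1L) / 60
  clean_ext <- mean_do +
    diel_amplitude * cos(2 * pi * (hours - 15) / 24) +
    tidal_amplitude * cos(2 * pi * hours / 12.42)
  noise <- function() if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  ext <- pmin(pmax(clean_ext + noise(), 0), 20)
  int <- pmin(pmax(clean_ext * (1 - interior_pct_offset / 100) + noise(),
                   0), 20)
  list(interior = field_series(tt, int, position = "interior",
                               colony_id = colony_id),
       exterior = field_series(tt, ext, position = "exterior",
                               colony_id = colony_id))
}
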