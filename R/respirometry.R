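#' Construct a sealed-chamber oxygen drawdown trace
#'
#' The raw unit of closed-system respirometry: one chamber's optode time
#' series together with the chamber geometry needed to turn volumetric
#' rates into whole-fragment rates.
#'
#' @param chamber_id character scalar identifying the chamber.
#' @param timestamps seconds since start of incubation, strictly increasing
#'   (nominal 60 s cadence).
#' @param airsat percent air saturation at each time point. Small sensor
#'   excursions outside [0, 100] are tolerated within [-2, 120]; values are
#'   clamped to [0, 120] before rate estimation.
#' @param temperature incubation temperature, degC; a scalar or one value
#'   per time point. Default 27.
#' @param chamber_volume chamber volume, mL. Default 400.
#' @param displacement_volume seawater volume displaced by the fragment, mL
#'   (0 for blanks).
#' @param is_blank logical; TRUE for a coral-free seawater control.
#' @param meta named list of labels (species, colony, position, treatment).
#' @return an object of class `drawdown_trace`.
#' @export
drawdown_trace <- function(chamber_id, timestamps, airsat, temperature = 27,
                           chamber_volume = 400, displacement_volume = 0,
                           is_blank = FALSE, meta = list()) {
  timestamps <- as.numeric(timestamps)
  airsat <- as.numeric(airsat)
  n <- length(timestamps)
  if (n < 2L || length(airsat) != n) {
    stop("drawdown_trace: need >= 2 points with matching airsat", call. = FALSE)
  }
  d <- diff(timestamps)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1L
    stop(sprintf("drawdown_trace: timestamps not strictly increasing at row %d",
                 bad), call. = FALSE)
  }
  if (any(!is.finite(airsat)) || any(airsat < -2 | airsat > 120)) {
    stop("drawdown_trace: airsat outside tolerated range [-2, 120]",
         call. = FALSE)
  }
  if (!length(temperature) %in% c(1L, n)) {
    stop("drawdown_trace: temperature must be scalar or per-point",
         call. = FALSE)
  }
  if (displacement_volume >= chamber_volume) {
    stop("drawdown_trace: displacement_volume must be < chamber_volume",
         call. = FALSE)
  }
  if (isTRUE(is_blank) && displacement_volume != 0) {
    stop("drawdown_trace: blank traces must have displacement_volume = 0",
         call. = FALSE)
  }
  structure(list(
    chamber_id = as.character(chamber_id),
    timestamps = timestamps,
    airsat = airsat,
    temperature = as.numeric(temperature),
    chamber_volume = chamber_volume,
    displacement_volume = displacement_volume,
    is_blank = isTRUE(is_blank),
    meta = meta
  ), class = "drawdown_trace")
}

#' @export
print.drawdown_trace <- function(x, ...) {
  cat(sprintf(
    "<drawdown_trace> %s: %d pts over %.2f h, airsat %.1f -> %.1f%%%s\n",
    x$chamber_id, length(x$timestamps),
    diff(range(x$timestamps)) / 3600,
    x$airsat[1], x$airsat[length(x$airsat)],
    if (x$is_blank) " [blank]" else ""))
  invisible(x)
}

#' Read a chamber logger CSV into a drawdown trace
#'
#' Column names vary across firmware versions, so the mapping from file
#' columns to (time, O2, temperature) is configurable. Rows with missing
#' O2 are dropped with a message.
#'
#' @param path CSV file path.
#' @param meta chamber metadata: a named list with at least `chamber_id`;
#'   optionally `chamber_volume`, `displacement_volume`, `is_blank`,
#'   plus any labels.
#' @param dialect named list mapping roles to column names; default
#'   `list(time = "time_s", o2 = "airsat_pct", temperature = "temp_C")`.
#'   The temperature column is optional in the file.
#' @return a `drawdown_trace`.
#' @export
read_firesting_csv <- function(path, meta = list(),
                               dialect = list(time = "time_s",
                                              o2 = "airsat_pct",
                                              temperature = "temp_C")) {
  if (!file.exists(path)) stop("read_firesting_csv: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (role in c("time", "o2")) {
    if (!dialect[[role]] %in% names(df)) {
      stop(sprintf("read_firesting_csv: required column '%s' (%s) missing in %s",
                   dialect[[role]], role, basename(path)), call. = FALSE)
    }
  }
  o2 <- suppressWarnings(as.numeric(df[[dialect$o2]]))
  keep <- is.finite(o2)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("read_firesting_csv: dropped %d row(s) with missing O2",
                    n_drop))
  }
  df <- df[keep, , drop = FALSE]
  o2 <- o2[keep]
  if (nrow(df) == 0L) {
    stop("read_firesting_csv: no usable rows after cleaning", call. = FALSE)
  }
  tt <- as.numeric(df[[dialect$time]])
  temp <- if (!is.null(dialect$temperature) &&
              dialect$temperature %in% names(df)) {
    as.numeric(df[[dialect$temperature]])
  } else {
    meta$temperature %||% 27
  }
  drawdown_trace(
    chamber_id = meta$chamber_id %||% basename(path),
    timestamps = tt, airsat = o2, temperature = temp,
    chamber_volume = meta$chamber_volume %||% 400,
    displacement_volume = meta$displacement_volume %||% 0,
    is_blank = meta$is_blank %||% FALSE,
    meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp excursions and strip the post-anoxia flatline (no rate information)
trim_trace <- function(trace) {
  a <- pmin(pmax(trace$airsat, 0), 120)
  last_pos <- max(which(a > 0), 1L)
  keep <- seq_len(min(last_pos + 1L, length(a)))
  trace$airsat <- a[keep]
  trace$timestamps <- trace$timestamps[keep]
  if (length(trace$temperature) > 1L) {
    trace$temperature <- trace$temperature[keep]
  }
  trace
}

# volumetric O2 consumption rates (mg L^-1 h^-1) per sliding window
window_rates <- function(trace, window, step, salinity, pressure) {
  tt <- trace$timestamps - trace$timestamps[1]
  a <- trace$airsat
  temp <- if (length(trace$temperature) == 1L) {
    rep(trace$temperature, length(a))
  } else trace$temperature
  n <- length(tt)
  dt <- stats::median(diff(tt))
  if (window / dt < 5 - 1e-9) {
    stop("compute_vo2_curve: window must span >= 5 samples", call. = FALSE)
  }
  if (window > tt[n]) {
    stop("compute_vo2_curve: window longer than trace", call. = FALSE)
  }
  starts <- seq(0, tt[n] - window, by = step)
  out <- lapply(starts, function(t0) {
    idx <- which(tt >= t0 - 1e-9 & tt <= t0 + window + 1e-9)
    if (length(idx) < 5L) return(NULL)
    csat <- o2_solubility(mean(temp[idx]), salinity, pressure)
    conc <- a[idx] / 100 * csat
    slope <- stats::cov(tt[idx], conc) / stats::var(tt[idx]) # mg L^-1 s^-1
    data.frame(pO2_mid = mean(a[idx]),
               rate_vol = -slope * 3600,                     # mg L^-1 h^-1
               t_start = t0, t_end = t0 + window)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Oxygen consumption curve from a drawdown trace
#'
#' Converts a sealed-chamber drawdown into per-window oxygen consumption
#' rates against ambient O2. Each sliding window is converted from percent
#' air saturation to mg/L at the window's temperature, a least-squares
#' slope taken, the blank's volumetric rate (interpolated at the same
#' ambient pO2, since control and coral chambers traverse pO2 at different
#' speeds) subtracted, and the net rate scaled by the effective water
#' volume `v_net = (chamber_volume - displacement_volume)/1000` litres.
#'
#' @param trace a `drawdown_trace` for the organism chamber.
#' @param blank optional coral-free control `drawdown_trace`; NULL for no
#'   blank correction.
#' @param window sliding-window length, seconds (default 600; must span at
#'   least 5 samples).
#' @param step window step, seconds (default 300).
#' @inheritParams o2_solubility
#' @return a `rate_series`: data frame of (pO2_mid, vo2, t_start, t_end)
#'   with attributes `v_net` (L) and `source_id`. `vo2` is mg O2 h^-1 per
#'   fragment.
#' @export
compute_vo2_curve <- function(trace, blank = NULL, window = 600, step = 300,
                              salinity = 35, pressure = 1013.25) {
  stopifnot(inherits(trace, "drawdown_trace"))
  trace <- trim_trace(trace)
  rw <- window_rates(trace, window, step, salinity, pressure)
  if (is.null(rw) || nrow(rw) == 0L) {
    stop("compute_vo2_curve: no usable windows", call. = FALSE)
  }
  blank_at <- function(p) 0
  if (!is.null(blank)) {
    stopifnot(inherits(blank, "drawdown_trace"))
    if (blank$displacement_volume != 0) {
      stop("compute_vo2_curve: blank has nonzero displacement volume",
           call. = FALSE)
    }
    bw <- window_rates(trim_trace(blank), window, step, salinity, pressure)
    if (diff(range(bw$pO2_mid)) >= 5) {
      o <- order(bw$pO2_mid)
      blank_at <- stats::approxfun(bw$pO2_mid[o], bw$rate_vol[o], rule = 2,
                                   ties = mean)
    } else {
      # blank that barely moves in pO2: matching by pO2 window would just
      # extrapolate one noisy window estimate; pool the rate instead
      blank_at <- function(p) rep(mean(bw$rate_vol), length(p))
    }
  }
  v_net <- (trace$chamber_volume - trace$displacement_volume) / 1000
  rw$vo2 <- (rw$rate_vol - blank_at(rw$pO2_mid)) * v_net
  out <- rw[, c("pO2_mid", "vo2", "t_start", "t_end")]
  structure(out, v_net = v_net, source_id = trace$chamber_id,
            class = c("rate_series", "data.frame"))
}

#' Time for chamber oxygen to fall between two saturation thresholds
#'
#' Crossing times are linearly interpolated between samples. When the trace
#' never falls below `end`, the result is censored at the trace's minimum.
#'
#' @param trace a `drawdown_trace`.
#' @param start,end percent air saturation thresholds (default 100 and 0).
#' @return list with `hours` (elapsed time between first crossings),
#'   `censored` (TRUE if `end` was never reached; `hours` then measures to
#'   the minimum) and `min_airsat`.
#' @export
drawdown_duration <- function(trace, start = 100, end = 0) {
  stopifnot(inherits(trace, "drawdown_trace"), start > end)
  tt <- trace$timestamps
  a <- pmin(pmax(trace$airsat, 0), 120)
  cross_below <- function(thr) {
    i <- which(a <= thr)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L || a[i] == thr) return(tt[i])
    # interpolate within [i-1, i]
    tt[i - 1] + (a[i - 1] - thr) / (a[i - 1] - a[i]) * (tt[i] - tt[i - 1])
  }
  t_start <- cross_below(start)
  if (is.na(t_start)) {
    stop("drawdown_duration: trace never falls below `start`", call. = FALSE)
  }
  t_end <- cross_below(end)
  if (is.na(t_end)) {
    i_min <- which.min(a)
    return(list(hours = (tt[i_min] - t_start) / 3600, censored = TRUE,
                min_airsat = a[i_min]))
  }
  list(hours = (t_end - t_start) / 3600, censored = FALSE, min_airsat = min(a))
}

#' Normalize a rate series into a dimensionless hypoxia response curve
#'
#' The fitting substrate: x = pO2/100 (fraction of air saturation) and
#' y = VO2 relative to the full-saturation reference rate `y_ref`, taken
#' as the mean VO2 over the highest decile of observed x (a single-point
#' reference is too noisy).
#'
#' @param rates a `rate_series` with >= 10 points spanning >= 50
#'   percentage points of air saturation.
#' @return an `hr_curve`: list with `x`, `y`, `y_ref` (mg O2 h^-1) and
#'   `x_range`.
#' @export
normalize_curve <- function(rates) {
  stopifnot(inherits(rates, "rate_series"))
  ok <- is.finite(rates$pO2_mid) & is.finite(rates$vo2)
  p <- rates$pO2_mid[ok]
  v <- rates$vo2[ok]
  if (length(p) < 10L) {
    stop("normalize_curve: need >= 10 rate points", call. = FALSE)
  }
  if (diff(range(p)) < 50) {
    stop("normalize_curve: points must span >= 50 %-air-sat", call. = FALSE)
  }
  top <- p >= stats::quantile(p, 0.9)
  y_ref <- mean(v[top])
  if (!is.finite(y_ref) || y_ref <= 0) {
    stop("normalize_curve: non-respiring trace (y_ref <= 0)", call. = FALSE)
  }
  x <- p / 100
  structure(list(x = x, y = v / y_ref, y_ref = y_ref, x_range = range(x)),
            class = "hr_curve")
}

#' @export
print.hr_curve <- function(x, ...) {
  cat(sprintf("<hr_curve> %d pts, x in [%.3f, %.3f], y_ref = %.4g mg O2/h\n",
              length(x$x), x$x_range[1], x$x_range[2], x$y_ref))
  invisible(x)
}
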