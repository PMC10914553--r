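#' Construct an in-situ dissolved oxygen logger series
#'
#' @param timestamps POSIXct (or coercible) sample times, increasing,
#'   nominal 60 s cadence.
#' @param do_mgL dissolved oxygen, mg O2 L^-1, within [0, 20].
#' @param temperature optional water temperature, degC.
#' @param position "interior" (inner thicket) or "exterior" (open outer
#'   branches).
#' @param colony_id colony label.
#' @return a `field_series`; gaps > 5 min and off-nominal cadence are
#'   recorded in the `gaps` / `cadence_ok` attributes.
#' @export
field_series <- function(timestamps, do_mgL, temperature = NULL,
                         position = c("interior", "exterior"),
                         colony_id = "colony") {
  position <- match.arg(position)
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  do_mgL <- as.numeric(do_mgL)
  n <- length(timestamps)
  if (n < 2L || length(do_mgL) != n) {
    stop("field_series: need >= 2 points with matching DO", call. = FALSE)
  }
  d <- as.numeric(diff(timestamps), units = "secs")
  if (any(d <= 0)) stop("field_series: timestamps not increasing",
                        call. = FALSE)
  if (any(!is.finite(do_mgL)) || any(do_mgL < 0 | do_mgL > 20)) {
    stop("field_series: do_mgL outside [0, 20]", call. = FALSE)
  }
  gaps <- which(d > 300)
  cadence_ok <- abs(stats::median(d) - 60) <= 6
  structure(list(timestamps = timestamps, do_mgL = do_mgL,
                 temperature = temperature, position = position,
                 colony_id = as.character(colony_id)),
            gaps = gaps, cadence_ok = cadence_ok, class = "field_series")
}

#' @export
print.field_series <- function(x, ...) {
  cat(sprintf("<field_series> %s/%s: %d pts, DO %.2f-%.2f mg/L\n",
              x$colony_id, x$position, length(x$do_mgL),
              min(x$do_mgL), max(x$do_mgL)))
  invisible(x)
}

#' Read an in-situ O2 logger CSV
#'
#' @param path CSV with ISO-8601 datetime, DO (mg/L) and optional
#'   temperature columns.
#' @param position,colony_id deployment labels (see [field_series()]).
#' @param dialect column mapping; default
#'   `list(time = "datetime", do = "do_mgL", temperature = "temp_C")`.
#' @return a `field_series`. Cadence more than 10% off the nominal 60 s
#'   raises a warning (recorded in the `cadence_ok` attribute).
#' @export
read_logger_csv <- function(path, position, colony_id,
                            dialect = list(time = "datetime", do = "do_mgL",
                                           temperature = "temp_C")) {
  if (!file.exists(path)) stop("read_logger_csv: no such file: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("read_logger_csv: empty file", call. = FALSE)
  for (role in c("time", "do")) {
    if (!dialect[[role]] %in% names(df)) {
      stop(sprintf("read_logger_csv: required column '%s' missing",
                   dialect[[role]]), call. = FALSE)
    }
  }
  temp <- if (!is.null(dialect$temperature) &&
              dialect$temperature %in% names(df)) {
    as.numeric(df[[dialect$temperature]])
  } else NULL
  fs <- field_series(df[[dialect$time]], as.numeric(df[[dialect$do]]),
                     temperature = temp, position = position,
                     colony_id = colony_id)
  if (!attr(fs, "cadence_ok")) {
    warning("read_logger_csv: cadence deviates > 10% from nominal 60 s")
  }
  fs
}

# per-sample duration weights (half-interval to each neighbour)
sample_weights <- function(timestamps) {
  d <- as.numeric(diff(timestamps), units = "secs")
  n <- length(timestamps)
  w <- numeric(n)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

#' Summary statistics of a DO logger deployment
#'
#' Extremes, mean, range and time fractions below each threshold, with
#' every sample weighted by its inter-sample interval (so irregular
#' cadence does not bias the fractions).
#'
#' @param series a `field_series` with >= 100 samples.
#' @param thresholds DO thresholds, mg L^-1 (default `c(2, 5)`).
#' @return a `field_summary`: min, max, mean, range, fraction_below
#'   (named numeric), n, span_hours.
#' @export
summarize_series <- function(series, thresholds = c(2, 5)) {
  stopifnot(inherits(series, "field_series"))
  v <- series$do_mgL
  if (length(v) < 100L) {
    stop("summarize_series: need >= 100 samples", call. = FALSE)
  }
  w <- sample_weights(series$timestamps)
  fb <- vapply(sort(thresholds),
               function(thr) sum(w[v < thr]) / sum(w), 0)
  names(fb) <- sort(thresholds)
  structure(list(min = min(v), max = max(v),
                 mean = sum(w * v) / sum(w), range = max(v) - min(v),
                 fraction_below = fb, n = length(v),
                 span_hours = as.numeric(diff(range(series$timestamps)),
                                         units = "hours")),
            class = "field_summary")
}

#' Cumulative time-at-DO histogram
#'
#' Time fraction spent in each half-open DO bin `[lo, lo + width)`.
#'
#' @param series a `field_series`.
#' @param bin_width bin width, mg L^-1 (default 0.5).
#' @param origin left edge of the bin lattice; default snaps to
#'   `floor(min/width) * width`. Use `origin = -0.5` with `bin_width = 1`
#'   for integer-centred 1-mg/L bins.
#' @return data frame (lo, hi, fraction); fractions sum to 1.
#' @export
cumulative_time_histogram <- function(series, bin_width = 0.5,
                                      origin = NULL) {
  stopifnot(inherits(series, "field_series"), bin_width > 0)
  v <- series$do_mgL
  w <- sample_weights(series$timestamps)
  if (is.null(origin)) origin <- floor(min(v) / bin_width) * bin_width
  idx <- floor((v - origin) / bin_width)
  agg <- tapply(w, idx, sum)
  lo <- origin + as.numeric(names(agg)) * bin_width
  data.frame(lo = lo, hi = lo + bin_width,
             fraction = as.numeric(agg) / sum(w), row.names = NULL)
}

#' Interior-versus-exterior dissolved oxygen deltas
#'
#' Computed on the intersection of the two deployment windows (staggered
#' deployments make the restriction mandatory). `pct_diff` of +10 means
#' the interior mean is 10% below the exterior mean.
#'
#' @param interior,exterior `field_series` from the same colony.
#' @return list: delta_mean (mg/L, exterior - interior), delta_range
#'   (range(ext) - range(int)), pct_diff (%), overlap_hours, n_int, n_ext.
#' @export
interior_exterior_delta <- function(interior, exterior) {
  stopifnot(inherits(interior, "field_series"),
            inherits(exterior, "field_series"))
  if (interior$colony_id != exterior$colony_id) {
    stop("interior_exterior_delta: series from different colonies",
         call. = FALSE)
  }
  lo <- max(min(interior$timestamps), min(exterior$timestamps))
  hi <- min(max(interior$timestamps), max(exterior$timestamps))
  if (lo >= hi) {
    stop("interior_exterior_delta: deployments do not overlap", call. = FALSE)
  }
  clip <- function(s) s$do_mgL[s$timestamps >= lo & s$timestamps <= hi]
  vi <- clip(interior)
  ve <- clip(exterior)
  delta_mean <- mean(ve) - mean(vi)
  list(delta_mean = delta_mean,
       delta_range = diff(range(ve)) - diff(range(vi)),
       pct_diff = 100 * delta_mean / mean(ve),
       overlap_hours = as.numeric(hi - lo, units = "hours"),
       n_int = length(vi), n_ext = length(ve))
}

#' Join a DO series with tide heights and a day/night flag
#'
#' Nearest-neighbour join against the tide table (30 min tolerance) plus
#' a day flag from sunrise/sunset times (no twilight allowance).
#'
#' @param series a `field_series`.
#' @param tides data frame with `datetime` (POSIXct/ISO-8601) and `height`
#'   (m), covering the deployment span.
#' @param sun data frame with `date` (Date/ISO), `sunrise`, `sunset`
#'   ("HH:MM" or "HH:MM:SS" local = series timezone).
#' @return data frame: timestamp, do_mgL, tide_height, tide_offset_min,
#'   is_day.
#' @export
align_with_tides <- function(series, tides, sun) {
  stopifnot(inherits(series, "field_series"))
  tt <- as.numeric(series$timestamps)
  td <- as.numeric(as.POSIXct(tides$datetime, tz = "UTC"))
  o <- order(td)
  td <- td[o]
  th <- tides$height[o]
  # nearest neighbour via findInterval
  i <- findInterval(tt, td)
  i_lo <- pmax(i, 1L)
  i_hi <- pmin(i + 1L, length(td))
  use_hi <- abs(td[i_hi] - tt) < abs(td[i_lo] - tt)
  nn <- ifelse(use_hi, i_hi, i_lo)
  off <- abs(td[nn] - tt)
  if (any(off > 1800)) {
    bad <- range(series$timestamps[off > 1800])
    stop(sprintf("align_with_tides: tide table does not cover %s .. %s",
                 format(bad[1]), format(bad[2])), call. = FALSE)
  }
  dates <- as.Date(series$timestamps, tz = "UTC")
  sun$date <- as.Date(sun$date)
  m <- match(dates, sun$date)
  if (anyNA(m)) {
    stop(sprintf("align_with_tides: sun table missing date(s) %s",
                 paste(unique(dates[is.na(m)]), collapse = ", ")),
         call. = FALSE)
  }
  parse_tod <- function(date, tod) {
    as.POSIXct(paste(date, tod), tz = "UTC")
  }
  rise <- parse_tod(sun$date[m], sun$sunrise[m])
  set <- parse_tod(sun$date[m], sun$sunset[m])
  data.frame(timestamp = series$timestamps,
             do_mgL = series$do_mgL,
             tide_height = th[nn],
             tide_offset_min = off / 60,
             is_day = series$timestamps >= rise & series$timestamps < set)
}
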