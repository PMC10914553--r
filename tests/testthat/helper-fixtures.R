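# shared fixture builders (all generated in code; nothing on disk)

# linear airsat decline from `from` to `to` over `hours`, 60-s cadence
linear_trace <- function(from = 100, to = 0, hours = 4, dt = 60,
                         chamber_volume = 400, displacement_volume = 50,
                         id = "lin", temperature = 27, ...) {
  tt <- seq(0, hours * 3600, by = dt)
  a <- from + (to - from) * tt / (hours * 3600)
  drawdown_trace(id, tt, a, temperature = temperature,
                 chamber_volume = chamber_volume,
                 displacement_volume = displacement_volume, ...)
}

# rate series straight from (pO2, vo2) vectors
raw_rates <- function(pO2, vo2, v_net = 0.35, id = "raw") {
  structure(data.frame(pO2_mid = pO2, vo2 = vo2,
                       t_start = seq_along(pO2), t_end = seq_along(pO2) + 1),
            v_net = v_net, source_id = id,
            class = c("rate_series", "data.frame"))
}

# noiseless hr_curve sampled from a function on a grid
curve_from_fn <- function(f, n = 50, x_lo = 0.02, x_hi = 1) {
  x <- seq(x_lo, x_hi, length.out = n)
  structure(list(x = x, y = f(x), y_ref = 1, x_range = range(x)),
            class = "hr_curve")
}

# constant-cadence field series from a DO vector
make_field <- function(do, position = "interior", colony_id = "c1",
                       dt = 60, start = "2022-02-08 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  field_series(t0 + dt * (seq_along(do) - 1L), do, position = position,
               colony_id = colony_id)
}
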