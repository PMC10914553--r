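#' The regulation function rho
#'
#' Local oxyregulation index of a fitted hypoxia response curve f:
#' `rho(x) = f(x)/x - f'(x)`, evaluated analytically. Strict conformity
#' (f(x) = m x) gives rho identically 0; for the Michaelis-Menten fit the
#' closed form is `rho(x) = Vmax x / (K + x)^2`, maximal at x = K. For the
#' origin-constrained model family the x -> 0 limit is 0 and rho(0) is
#' defined by that limit.
#'
#' @param fit an `hrc_fit`.
#' @param x dimensionless pO2 in [0, 1.2].
#' @return rho(x), relative units.
#' @export
rho <- function(fit, x) {
  stopifnot(inherits(fit, "hrc_fit"))
  if (any(x < 0 | x > 1.2)) {
    stop("rho: x outside [0, 1.2]", call. = FALSE)
  }
  p <- fit$params
  switch(fit$spec$kind,
    linear = rep(0, length(x)),
    # f/x - f' = sum_j (1 - j) a_j x^(j-1); the j = 1 term vanishes
    constrained_poly = horner0(p * (1 - seq_along(p)), x, shift = -1L),
    michaelis_menten = p[["Vmax"]] * x / (p[["K"]] + x)^2,
    custom = {
      out <- numeric(length(x))
      at0 <- x == 0
      if (any(at0)) {
        f0 <- fit$f(0)
        if (!is.finite(f0) || abs(f0) > 1e-12) {
          stop("rho: singular at x = 0 (f(0) != 0)", call. = FALSE)
        }
        # limit via a small step
        h <- 1e-8
        out[at0] <- fit$f(h) / h - fit$fprime(h)
      }
      xs <- x[!at0]
      out[!at0] <- fit$f(xs) / xs - fit$fprime(xs)
      out
    })
}

#' Regulation profile and oxyregulation statistics
#'
#' Evaluates rho on a uniform grid over the pO2 window and extracts:
#' T_pos, the trapezoidal integral of the positive part of rho (the total
#' positive regulation beyond strict conformity); T_neg, likewise for the
#' negative part (a diagnostic); and P_cmax / P_cmin, the percent air
#' saturation of maximum / minimum regulation effort, refined from the
#' grid arg-extremum by bounded scalar optimisation of the analytic rho.
#'
#' The default window floor of 0.02 (2% air saturation) reflects the usual
#' drawdown termination criterion, avoids the f/x singularity for
#' unconstrained shapes, and keeps P_cmin at the high-pO2 end where the
#' regulation deficit of saturating fits actually lies.
#'
#' @param fit an `hrc_fit`.
#' @param x_window evaluation window `[x_lo, x_hi]`; default
#'   `[max(floor, min observed x), min(1, max observed x)]`.
#' @param grid_n grid size (>= 200; default 1000).
#' @param floor lower evaluation bound (default 0.02).
#' @param tpos_mode "integral" (plain integral over the window, default) or
#'   "range_mean" (integral divided by window width).
#' @return a `regulation_profile`: grid_x, rho, t_pos, t_neg, p_cmax,
#'   p_cmin, x_window. When rho is constant across the grid (within 1e-12),
#'   p_cmax and p_cmin are `NA` (undefined).
#' @export
regulation_profile <- function(fit, x_window = NULL, grid_n = 1000,
                               floor = 0.02,
                               tpos_mode = c("integral", "range_mean")) {
  stopifnot(inherits(fit, "hrc_fit"), grid_n >= 200)
  tpos_mode <- match.arg(tpos_mode)
  if (is.null(x_window)) {
    x_window <- c(max(floor, fit$x_range[1]), min(1.0, fit$x_range[2]))
  }
  x_lo <- x_window[1]; x_hi <- x_window[2]
  if (x_lo >= x_hi) stop("regulation_profile: x_lo >= x_hi", call. = FALSE)
  gx <- seq(x_lo, x_hi, length.out = grid_n)
  r <- rho(fit, gx)
  if (any(!is.finite(r))) {
    stop("regulation_profile: rho not finite on the grid", call. = FALSE)
  }
  h <- gx[2] - gx[1]
  trapz <- function(v) sum((v[-1] + v[-length(v)]) / 2) * h
  t_pos <- trapz(pmax(r, 0))
  t_neg <- trapz(pmin(r, 0))
  if (tpos_mode == "range_mean") {
    t_pos <- t_pos / (x_hi - x_lo)
    t_neg <- t_neg / (x_hi - x_lo)
  }
  if (diff(range(r)) < 1e-12) {
    p_cmax <- NA_real_
    p_cmin <- NA_real_
  } else {
    refine <- function(i, maximum) {
      lo <- gx[max(i - 1L, 1L)]
      hi <- gx[min(i + 1L, grid_n)]
      opt <- stats::optimize(function(z) rho(fit, z), c(lo, hi),
                             maximum = maximum, tol = 1e-10)
      if (maximum) opt$maximum else opt$minimum
    }
    p_cmax <- 100 * refine(which.max(r), TRUE)
    # ties at the minimum break toward larger x
    p_cmin <- 100 * refine(max(which(r == min(r))), FALSE)
  }
  structure(list(grid_x = gx, rho = r, t_pos = t_pos, t_neg = t_neg,
                 p_cmax = p_cmax, p_cmin = p_cmin,
                 x_window = c(x_lo, x_hi), tpos_mode = tpos_mode),
            class = "regulation_profile")
}

#' @export
print.regulation_profile <- function(x, ...) {
  cat(sprintf(
    "<regulation_profile> T_pos = %.4g, P_cmax = %s%%, P_cmin = %s%% on [%.2f, %.2f]\n",
    x$t_pos,
    if (is.na(x$p_cmax)) "NA" else sprintf("%.2f", x$p_cmax),
    if (is.na(x$p_cmin)) "NA" else sprintf("%.2f", x$p_cmin),
    x$x_window[1], x$x_window[2]))
  invisible(x)
}

#' Mean and standard error of regulation statistics across replicates
#'
#' @param profiles list of >= 2 `regulation_profile`s.
#' @return data frame with one row per statistic (t_pos, t_neg, p_cmax,
#'   p_cmin): mean, se (sd/sqrt(n)), n used, n_undefined excluded. A
#'   statistic undefined in every profile yields NA with a warning.
#' @export
replicate_summary <- function(profiles) {
  if (length(profiles) < 2L) {
    stop("replicate_summary: need >= 2 profiles", call. = FALSE)
  }
  stats_ <- c("t_pos", "t_neg", "p_cmax", "p_cmin")
  rows <- lapply(stats_, function(s) {
    v <- vapply(profiles, `[[`, 0, s)
    ok <- is.finite(v)
    if (!any(ok)) {
      warning("replicate_summary: '", s, "' undefined in every profile")
      return(data.frame(statistic = s, mean = NA_real_, se = NA_real_,
                        n = 0L, n_undefined = sum(!ok)))
    }
    v <- v[ok]
    data.frame(statistic = s, mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), n_undefined = sum(!ok))
  })
  do.call(rbind, rows)
}
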