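#' Specify a hypoxia response curve model
#'
#' The candidate family: slope-only linear conformity `y = m x` (one free
#' parameter — strict oxyconformity scaled), origin-constrained polynomials
#' `y = a1 x + ... + ad x^d` (d free parameters; the intercept is omitted so
#' f(0) = 0), and the two-parameter Michaelis-Menten kinetics form
#' `y = Vmax x / (K + x)`.
#'
#' @param kind one of "linear", "constrained_poly", "michaelis_menten".
#' @param degree polynomial degree, 2-12; required iff
#'   `kind = "constrained_poly"`.
#' @return a `model_spec`.
#' @export
model_spec <- function(kind = c("linear", "constrained_poly",
                                "michaelis_menten"),
                       degree = NULL) {
  kind <- match.arg(kind)
  if (kind == "constrained_poly") {
    if (is.null(degree) || degree < 2 || degree > 12 || degree != round(degree)) {
      stop("model_spec: constrained_poly needs integer degree in 2..12",
           call. = FALSE)
    }
    degree <- as.integer(degree)
  } else if (!is.null(degree)) {
    stop("model_spec: degree is only meaningful for constrained_poly",
         call. = FALSE)
  }
  structure(list(kind = kind, degree = degree), class = "model_spec")
}

#' Default candidate model set
#'
#' Linear, Michaelis-Menten, and even-degree constrained polynomials
#' 2, 4, ..., 12 (the degrees conventionally tabulated; odd degrees are
#' accepted by [model_spec()] but not included by default).
#'
#' @return list of `model_spec`s.
#' @export
default_model_set <- function() {
  c(list(model_spec("linear"), model_spec("michaelis_menten")),
    lapply(seq(2, 12, by = 2), function(d) model_spec("constrained_poly", d)))
}

#' @export
format.model_spec <- function(x, ...) {
  if (x$kind == "constrained_poly") paste0("constrained_poly_", x$degree)
  else x$kind
}

#' Gaussian-likelihood AIC for a least-squares fit
#'
#' `AIC = n log(2 pi rss / n) + n + 2 (p_free + 1)` under
#' `convention = "gaussian_plus_sigma"` — the residual variance is counted
#' as an estimated parameter, matching `stats::AIC` on an `lm`. The
#' `"gaussian_fixed_sigma"` convention drops the +1. Absolute AIC values
#' (though never AIC differences between models fitted to the same data)
#' depend on this choice.
#'
#' @param n number of points fitted.
#' @param rss residual sum of squares.
#' @param p_free free parameter count of the mean function.
#' @param convention see Details.
#' @return AIC value; `-Inf` with a warning when `rss` is exactly 0
#'   (perfect interpolation).
#' @export
hrc_aic <- function(n, rss, p_free,
                    convention = c("gaussian_plus_sigma",
                                   "gaussian_fixed_sigma")) {
  convention <- match.arg(convention)
  stopifnot(n > 0, rss >= 0)
  if (rss == 0) {
    warning("hrc_aic: rss = 0 (perfect interpolation); returning -Inf")
    return(-Inf)
  }
  k <- if (convention == "gaussian_plus_sigma") p_free + 1 else p_free
  n * log(2 * pi * rss / n) + n + 2 * k
}

#' Fit one model to a hypoxia response curve
#'
#' Linear and polynomial fits are linear least squares through the origin
#' (the polynomial design uses a scaled basis `(x/max(x))^j` solved by QR
#' for conditioning at high degree; coefficients are reported on the raw
#' power basis). The Michaelis-Menten fit is nonlinear least squares
#' (`nls`, port algorithm) with bounds Vmax in (0, 10], K in (1e-4, 10],
#' started from Vmax0 = max(y) and K0 = x at the first y >= Vmax0/2, with
#' fallback starts K0 x {0.1, 1, 10} on failure.
#'
#' @param curve an `hr_curve` from [normalize_curve()] (or any list with
#'   numeric `x`, `y`).
#' @param spec a `model_spec`.
#' @param aic_convention passed to [hrc_aic()].
#' @return an `hrc_fit`: spec, params (named numeric), rss, aic, n,
#'   p_free, x_range. Evaluate with [predict()] and [hrc_deriv()].
#' @export
fit_model <- function(curve, spec, aic_convention = "gaussian_plus_sigma") {
  stopifnot(inherits(spec, "model_spec"))
  x <- curve$x
  y <- curve$y
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("fit_model: too few points", call. = FALSE)

  if (spec$kind == "linear") {
    m <- sum(x * y) / sum(x * x)
    r <- y - m * x
    params <- c(m = m)
    p_free <- 1L
  } else if (spec$kind == "constrained_poly") {
    d <- spec$degree
    if (n <= d + 2L) {
      stop("fit_model: need n > degree + 2 for constrained_poly",
           call. = FALSE)
    }
    s <- max(x)
    X <- outer(x / s, seq_len(d), `^`)
    qr_x <- qr(X)
    if (qr_x$rank < d) {
      stop("fit_model: rank-deficient polynomial system", call. = FALSE)
    }
    b <- qr.coef(qr_x, y)
    r <- y - X %*% b
    params <- stats::setNames(b / s^seq_len(d), paste0("a", seq_len(d)))
    p_free <- d
  } else { # michaelis_menten
    fitted <- fit_mm(x, y)
    params <- fitted$params
    r <- y - params[["Vmax"]] * x / (params[["K"]] + x)
    p_free <- 2L
  }
  rss <- sum(r^2)
  structure(list(
    spec = spec,
    params = params,
    rss = rss,
    aic = hrc_aic(n, rss, p_free, aic_convention),
    n = n,
    p_free = p_free,
    x_range = range(x)
  ), class = "hrc_fit")
}

fit_mm <- function(x, y) {
  vmax0 <- max(y)
  half <- which(y >= vmax0 / 2)
  k0 <- if (length(half)) max(min(x[half]), 1e-3) else stats::median(x)
  df <- data.frame(x = x, y = y)
  errs <- character(0)
  for (mult in c(1, 0.1, 10, 1)) {
    st <- list(Vmax = min(vmax0, 10), K = min(max(k0 * mult, 2e-4), 9))
    fit <- tryCatch(
      stats::nls(y ~ Vmax * x / (K + x), data = df, start = st,
                 algorithm = "port",
                 lower = c(Vmax = 1e-8, K = 1e-4),
                 upper = c(Vmax = 10, K = 10),
                 control = stats::nls.control(maxiter = 200,
                                              warnOnly = FALSE)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      return(list(params = c(Vmax = unname(cf["Vmax"]), K = unname(cf["K"]))))
    }
    errs <- c(errs, conditionMessage(fit))
  }
  stop("fit_model: Michaelis-Menten fit failed from all starts: ",
       paste(unique(errs), collapse = "; "), call. = FALSE)
}

#' @export
print.hrc_fit <- function(x, ...) {
  cat(sprintf("<hrc_fit> %s: rss = %.4g, AIC = %.2f, n = %d\n",
              format(x$spec), x$rss, x$aic, x$n))
  cat("  params:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a fitted HRC model
#'
#' @param object an `hrc_fit`.
#' @param x dimensionless pO2 values.
#' @param ... unused.
#' @return f(x).
#' @export
predict.hrc_fit <- function(object, x, ...) {
  p <- object$params
  switch(object$spec$kind,
    linear = p[["m"]] * x,
    constrained_poly = horner0(p, x),
    michaelis_menten = p[["Vmax"]] * x / (p[["K"]] + x),
    custom = object$f(x))
}

#' Analytic derivative f'(x) of a fitted HRC model
#'
#' @inheritParams predict.hrc_fit
#' @param fit an `hrc_fit`.
#' @return f'(x).
#' @export
hrc_deriv <- function(fit, x) {
  p <- fit$params
  switch(fit$spec$kind,
    linear = rep(p[["m"]], length(x)),
    constrained_poly = horner0(p * seq_along(p), x, shift = -1L),
    michaelis_menten = p[["Vmax"]] * p[["K"]] / (p[["K"]] + x)^2,
    custom = fit$fprime(x))
}

# evaluate sum_j a_j x^(j+shift) for a = (a1..ad), origin-constrained
horner0 <- function(a, x, shift = 0L) {
  acc <- rep(0, length(x))
  for (j in rev(seq_along(a))) acc <- acc * x + a[[j]]
  acc * x^(1L + shift)
}

#' Wrap arbitrary f, f' as a fit object
#'
#' Mainly for evaluating the regulation function on analytically known
#' response shapes (e.g. a constant regulator f(x) = 1) without going
#' through a least-squares fit.
#'
#' @param f,fprime functions of dimensionless pO2.
#' @param x_range evaluation range.
#' @return an `hrc_fit` of kind "custom" (no rss/aic).
#' @export
hrc_fit_custom <- function(f, fprime, x_range = c(0, 1)) {
  structure(list(spec = structure(list(kind = "custom", degree = NULL),
                                  class = "model_spec"),
                 params = numeric(0), f = f, fprime = fprime,
                 rss = NA_real_, aic = NA_real_, n = NA_integer_,
                 p_free = NA_integer_, x_range = x_range),
            class = "hrc_fit")
}

#' Fit and rank candidate models by AIC
#'
#' Results are sorted ascending by AIC; exact ties are broken by fewer
#' free parameters, then by kind order (linear < Michaelis-Menten <
#' polynomial). Candidates that fail to fit are reported with their error
#' message and never ranked.
#'
#' @param curve an `hr_curve`.
#' @param candidates list of `model_spec`s (default [default_model_set()]).
#' @param aic_convention passed to [fit_model()].
#' @return list with `fits` (ranked list of `hrc_fit`), `best` (the top
#'   fit), `table` (data frame: model, p_free, rss, aic), and `failures`
#'   (named character vector of error messages).
#' @export
select_best <- function(curve, candidates = default_model_set(),
                        aic_convention = "gaussian_plus_sigma") {
  if (length(candidates) == 0L) {
    stop("select_best: empty candidate list", call. = FALSE)
  }
  names(candidates) <- vapply(candidates, format, "")
  fits <- list()
  failures <- character(0)
  for (nm in names(candidates)) {
    f <- tryCatch(
      suppressWarnings(fit_model(curve, candidates[[nm]], aic_convention)),
      error = function(e) e)
    if (inherits(f, "error")) failures[nm] <- conditionMessage(f)
    else fits[[nm]] <- f
  }
  if (length(fits) == 0L) {
    stop("select_best: all candidates failed: ",
         paste(failures, collapse = "; "), call. = FALSE)
  }
  kind_rank <- vapply(fits, function(f) {
    match(f$spec$kind, c("linear", "michaelis_menten", "constrained_poly"))
  }, 0L)
  ord <- order(vapply(fits, `[[`, 0, "aic"),
               vapply(fits, `[[`, 0L, "p_free"),
               kind_rank)
  fits <- fits[ord]
  tab <- data.frame(
    model = names(fits),
    p_free = vapply(fits, `[[`, 0L, "p_free"),
    rss = vapply(fits, `[[`, 0, "rss"),
    aic = vapply(fits, `[[`, 0, "aic"),
    row.names = NULL)
  list(fits = fits, best = fits[[1]], table = tab, failures = failures)
}
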