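#' Independent two-sample t-test
#'
#' Pooled-variance by default (the method that yields df = n_a + n_b - 2,
#' e.g. df = 10 for 6 vs 6); Welch available by flag; a paired option is
#' provided for by-colony pairing designs.
#'
#' @param a,b numeric samples (n >= 2 each, finite).
#' @param method "pooled" or "welch".
#' @param paired logical; if TRUE, a paired t-test on a - b (equal lengths
#'   required, df = n - 1).
#' @return a `group_comparison`: statistic (t), df, p (two-sided),
#'   estimate_a / estimate_b (mean, se), n_a, n_b, method. Degenerate
#'   zero-variance inputs give t = 0 (equal means) or +/-Inf with p = 0.
#' @export
two_sample_t <- function(a, b, method = c("pooled", "welch"),
                         paired = FALSE) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L || any(!is.finite(c(a, b)))) {
    stop("two_sample_t: need >= 2 finite values per group", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (paired) {
    if (na != nb) stop("two_sample_t: paired test needs equal n",
                       call. = FALSE)
    d <- a - b
    df <- na - 1
    sed <- stats::sd(d) / sqrt(na)
    t <- if (sed == 0) { if (mean(d) == 0) 0 else sign(mean(d)) * Inf }
         else mean(d) / sed
    method <- "paired"
  } else if (method == "pooled") {
    df <- na + nb - 2
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t <- if (se == 0) { if (ma == mb) 0 else sign(ma - mb) * Inf }
         else (ma - mb) / se
  } else {
    sea2 <- va / na; seb2 <- vb / nb
    se <- sqrt(sea2 + seb2)
    df <- se^4 / (sea2^2 / (na - 1) + seb2^2 / (nb - 1))
    t <- if (se == 0) { if (ma == mb) 0 else sign(ma - mb) * Inf }
         else (ma - mb) / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df)
  structure(list(statistic = t, df = df, p = p,
                 estimate_a = c(mean = ma, se = sqrt(va / na)),
                 estimate_b = c(mean = mb, se = sqrt(vb / nb)),
                 n_a = na, n_b = nb, method = method,
                 type = "t"),
            class = "group_comparison")
}

#' Pearson correlation with R-squared
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a `group_comparison` with statistic = r, r_squared, df = n - 2
#'   and a two-sided p-value from the t distribution.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3L || length(y) != n) {
    stop("pearson: need >= 3 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson: undefined correlation (zero variance)", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  structure(list(statistic = r, r_squared = r^2, df = df, p = p,
                 n = n, type = "pearson"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$type == "t") {
    cat(sprintf("t(%.4g) = %.3f, p = %.4g [%s]\n", x$df, x$statistic, x$p,
                x$method))
  } else {
    cat(sprintf("r(%d) = %.3f, R^2 = %.3f, p = %.4g\n", x$df, x$statistic,
                x$r_squared, x$p))
  }
  invisible(x)
}

#' Normality and homogeneity-of-variance checks
#'
#' Shapiro-Wilk per group plus a Brown-Forsythe (median-centred) Levene
#' test across the two groups. Advisory only: results never gate the
#' t-test.
#'
#' @param a,b numeric samples.
#' @return list: shapiro_a / shapiro_b (w, p, or a flag when n < 3 or the
#'   group is constant) and levene (f, df1, df2, p).
#' @export
assumption_checks <- function(a, b) {
  sw <- function(v) {
    if (length(v) < 3L) return(list(skipped = TRUE, reason = "n < 3"))
    if (stats::sd(v) == 0) return(list(skipped = TRUE, reason = "constant"))
    s <- stats::shapiro.test(v)
    list(skipped = FALSE, w = unname(s$statistic), p = s$p.value)
  }
  # Brown-Forsythe: one-way ANOVA on |x - median(group)|
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  n <- length(za) + length(zb)
  zbar <- mean(c(za, zb))
  ssb <- length(za) * (mean(za) - zbar)^2 + length(zb) * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  df1 <- 1; df2 <- n - 2
  f <- if (ssw == 0) { if (ssb == 0) 0 else Inf }
       else (ssb / df1) / (ssw / df2)
  p <- if (is.infinite(f)) 0 else stats::pf(f, df1, df2, lower.tail = FALSE)
  list(shapiro_a = sw(a), shapiro_b = sw(b),
       levene = list(f = f, df1 = df1, df2 = df2, p = p))
}
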