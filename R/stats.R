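#' Mean and standard error of the mean
#'
#' @param values numeric vector, length >= 2, finite.
#' @return List with `mean`, `sem` (sample SD over sqrt(n)) and `n`.
#' @export
mean_sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values for a SEM")
  if (!all(is.finite(values))) stop("values must be finite")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

check_paired <- function(x, y, min_n = 3L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < min_n) stop("need at least ", min_n, " paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  list(x = x, y = y)
}

#' Pearson product-moment correlation with p-value
#'
#' Two-sided p from the t transform with n - 2 degrees of freedom
#' (delegating to [stats::cor.test()]).
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant).
#' @return List with `rho`, `p` and `n`.
#' @export
pearson_cor <- function(x, y) {
  s <- check_paired(x, y)
  if (stats::sd(s$x) == 0 || stats::sd(s$y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(s$x, s$y, method = "pearson")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(s$x))
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of mid-ranks (average ranks on ties) with the same
#' t-transform p-value as [pearson_cor()] — the large-sample convention,
#' applied at every n for consistency.
#'
#' @param x,y equal-length numeric vectors (n >= 3, non-constant ranks).
#' @return List with `rho`, `p` and `n`.
#' @export
spearman_cor <- function(x, y) {
  s <- check_paired(x, y)
  rx <- rank(s$x)
  ry <- rank(s$y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero variance in ranks of x or y")
  }
  rho <- stats::cor(rx, ry)
  n <- length(rx)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Ordinary least-squares line with coefficient standard errors
#'
#' `y = intercept + slope * x` fitted by [stats::lm()]; standard errors and
#' two-sided p-values come from the residual variance with n - 2 degrees of
#' freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3; x non-constant).
#' @return List with `slope`, `slope_se`, `slope_p`, `intercept`,
#'   `intercept_se`, `intercept_p`, `n`.
#' @export
linear_fit <- function(x, y) {
  s <- check_paired(x, y)
  if (stats::sd(s$x) == 0) stop("x is constant; cannot fit a line")
  fit <- stats::lm(y ~ x, data = s)
  # noiseless inputs trigger the "essentially perfect fit" note; the
  # coefficients and (zero) SEs are exactly what callers want then
  cf <- suppressWarnings(summary(fit))$coefficients
  list(slope = cf["x", 1], slope_se = cf["x", 2], slope_p = cf["x", 4],
       intercept = cf["(Intercept)", 1], intercept_se = cf["(Intercept)", 2],
       intercept_p = cf["(Intercept)", 4],
       n = length(s$x))
}
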