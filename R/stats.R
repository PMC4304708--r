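# Group-comparison statistics: Pearson correlation with zero-slope test and
# Welch's unequal-variance t-test (including a summary-statistic form, since
# published group means/SDs/ns are often all that is available).

#' Pearson correlation with two-sided zero-slope test
#'
#' Product-moment correlation between two count vectors (e.g. per-image
#' lesion counts by two raters), with significance assessed as the
#' probability that the regression slope differs from zero:
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom,
#' two-sided.
#'
#' @param x,y numeric vectors of equal length `>= 3` with non-zero variance.
#' @return list (class `correlation_result`) with `r`, `n`, `p_value`.
#' @export
pearson <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop("`x` and `y` must be numeric vectors of equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in at least one variable: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin # exactly collinear
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  structure(list(r = r, n = n, p_value = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f (n = %d, two-sided p = %.4g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Welch's two-sample t-test from summary statistics
#'
#' Unequal-variance t-test:
#' `t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2)`, with
#' Welch--Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param mean1,sd1,n1 first group's mean, standard deviation (`> 0`) and
#'   size (`>= 2`).
#' @param mean2,sd2,n2 second group likewise.
#' @return list (class `welch_result`) with `t`, `df`, `p_value`.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  vals <- c(mean1, sd1, n1, mean2, sd2, n2)
  if (!is.numeric(vals) || length(vals) != 6L || !all(is.finite(vals)))
    stop("all six summary statistics must be finite numbers")
  if (sd1 <= 0 || sd2 <= 0)
    stop("standard deviations must be positive (degenerate constant group)")
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- min(max(2 * pt(-abs(t), df = df), .Machine$double.xmin), 1)
  structure(list(t = t, df = df, p_value = p), class = "welch_result")
}

#' Welch's t-test from raw samples
#'
#' Convenience wrapper: computes each group's mean and standard deviation and
#' delegates to [welch_t()].
#'
#' @param a,b numeric vectors, each of length `>= 2`.
#' @return list (class `welch_result`) with `t`, `df`, `p_value`.
#' @export
welch_t_from_samples <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) < 2 || length(b) < 2)
    stop("`a` and `b` must be numeric vectors of length >= 2")
  if (anyNA(a) || anyNA(b)) stop("missing values are not supported")
  welch_t(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch> t(%.2f) = %.3f, two-sided p = %.4g\n",
              x$df, x$t, x$p_value))
  invisible(x)
}
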