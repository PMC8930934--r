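# Rounding at the presentation layer is half-away-from-zero (the convention
# of the printed tables), not banker's rounding.
round_half_away <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Cohen's D with pooled standard deviation
#'
#' Two-group standardized mean difference
#' `d = (mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)`. When working from a
#' published summary table the difference of the printed (rounded) group
#' means can disagree with the separately printed mean-difference cell; the
#' optional `mean_diff` argument lets that cell be used as the numerator.
#'
#' @param mean1,sd1 Mean and SD of group 1 (cases).
#' @param mean2,sd2 Mean and SD of group 2 (controls).
#' @param mean_diff Numerator; defaults to `mean1 - mean2`.
#' @return Effect size d (unitless).
#' @export
cohens_d_pooled <- function(mean1, sd1, mean2, sd2,
                            mean_diff = mean1 - mean2) {
  if (sd1 < 0 || sd2 < 0)
    abort_menisq("standard deviations must be non-negative", "menisq_invalid_input")
  if (sd1 == 0 && sd2 == 0)
    abort_menisq("both group SDs are zero; d undefined", "menisq_degenerate")
  mean_diff / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired t-test on within-pair differences
#'
#' One-sample t-test of the paired differences against zero:
#' `t = mean(d) / (sd(d) / sqrt(n))`, `df = n - 1`, two-sided p.
#'
#' @param diffs Numeric vector of within-pair differences, length >= 2.
#' @return List with `t`, `df`, `p_value`.
#' @export
paired_t_test <- function(diffs) {
  d <- as.numeric(diffs)
  if (length(d) < 2L)
    abort_menisq("need at least 2 paired differences", "menisq_invalid_input")
  if (stats::sd(d) == 0)
    abort_menisq("paired differences have zero variance", "menisq_degenerate")
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Mean difference with 95% confidence interval
#'
#' `mean(d) +/- t_{0.975, n-1} * sd(d) / sqrt(n)`. A zero-variance vector
#' yields a degenerate interval of zero width.
#'
#' @param diffs Numeric vector of within-pair differences, length >= 2.
#' @return Named numeric: `mean`, `ci95_low`, `ci95_high`.
#' @export
mean_diff_ci95 <- function(diffs) {
  d <- as.numeric(diffs)
  n <- length(d)
  if (n < 2L)
    abort_menisq("need at least 2 differences for a CI", "menisq_invalid_input")
  m <- mean(d)
  half <- stats::qt(0.975, df = n - 1) * stats::sd(d) / sqrt(n)
  c(mean = m, ci95_low = m - half, ci95_high = m + half)
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation; requires at least 3 complete observations
#' and non-constant inputs.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y))
    abort_menisq("x and y must have equal length", "menisq_invalid_input")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    abort_menisq("need at least 3 complete observations", "menisq_invalid_input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_menisq("correlation undefined for constant input", "menisq_degenerate")
  stats::cor(x, y)
}

#' Variance explained, integer percent
#'
#' `round(100 * r^2)` (half away from zero), the `r^2 %` of a simple linear
#' regression.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @return Integer percent.
#' @export
variance_explained_pct <- function(r) {
  if (any(abs(r) > 1))
    abort_menisq("|r| must not exceed 1", "menisq_invalid_input")
  as.integer(round_half_away(100 * r^2))
}
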