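#' Lilliefors test of residual normality
#'
#' Kolmogorov–Smirnov test against a normal law with mean and standard
#' deviation estimated from the sample (the Lilliefors correction).
#' Small p-values reject normality of the residuals, one of the two
#' assumptions behind the t-based prediction intervals.
#'
#' @param residuals numeric vector, length >= 5, with positive variance.
#' @return The p-value.
#' @export
lilliefors_normality <- function(residuals) {
  residuals <- as.numeric(residuals)
  if (length(residuals) < 5)
    stop("need at least 5 residuals", call. = FALSE)
  if (sd(residuals) == 0)
    stop("residuals have zero variance: normality test is degenerate",
         call. = FALSE)
  nortest::lillie.test(residuals)$p.value
}

#' Wald-Wolfowitz runs test of residual independence
#'
#' Two-sided test that successive residuals are mutually independent,
#' based on the number of runs of values above/below the median and the
#' normal approximation to its null distribution, with the usual
#' continuity correction of 1/2 on the run count (without it the test is
#' anticonservative at moderate sample sizes). Too few runs indicate
#' positive serial dependence; too many indicate alternation.
#'
#' Values exactly equal to the median are dropped before counting runs.
#'
#' @param residuals numeric vector; at least 10 values with both signs
#'   present after median-centering.
#' @return The two-sided p-value.
#' @export
runs_test_independence <- function(residuals) {
  x <- as.numeric(residuals)
  if (length(x) < 10) stop("need at least 10 residuals", call. = FALSE)
  s <- sign(x - median(x))
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0)
    stop("all values on one side of the median: runs test undefined",
         call. = FALSE)
  runs <- 1L + sum(diff(s) != 0)
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sigma2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  dev <- max(0, abs(runs - mu) - 0.5)
  2 * pnorm(-dev / sqrt(sigma2))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3, each with positive
#'   variance.
#' @return r in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  cor(x, y)
}
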