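#' Probability that the cumulative kidney dose exceeds a threshold
#'
#' Implements the predicted-Y t-statistic method: given a fitted model for
#' the remaining dose, a new patient's predictor values `x0`, the dose
#' already accumulated, and a safety threshold, the probability that
#' (known cumulative + future response) exceeds the threshold is the upper
#' tail of a Student t distribution,
#' \deqn{t = \frac{\mathrm{threshold} - \mathrm{known} - \hat y(x_0)}
#'            {s\sqrt{1 + x_0'(X'X)^{-1}x_0}},\qquad
#'       P = \Pr(T_{df} > t).}
#' The probability is one-sided by construction: the clinical question is
#' directional (does the dose exceed the limit), and the paired 10%/95%
#' decision contours are one-sided tail levels.
#'
#' When the model is noiseless (`residual_scale == 0`) the predictive law
#' degenerates and the probability is a step: 0 below the threshold
#' margin, 1 above, 0.5 at exact equality.
#'
#' @param fit a [dose_model] for the remaining (future) dose.
#' @param x0 named numeric vector or one-row data frame of predictor
#'   values (Gy).
#' @param known_cumulative kidney dose already received (Gy, >= 0).
#' @param threshold safety threshold (Gy, > 0); default 25.
#' @return Object of class `exceedance_result`: `point_prediction`,
#'   `prediction_se`, `t_statistic`, `probability_exceed`, `threshold`,
#'   `known_cumulative`, `df`.
#' @examples
#' eq1 <- dose_model_fixed(c("(Intercept)" = 1.39, d1 = 0.56, d2 = 1.19),
#'                         residual_scale = 1.7, df = 87)
#' exceedance_probability(eq1, c(d1 = 6, d2 = 6),
#'                        known_cumulative = 12, threshold = 25)
#' @export
exceedance_probability <- function(fit, x0, known_cumulative, threshold = 25) {
  stopifnot(inherits(fit, "dose_model"))
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  if (known_cumulative < 0) stop("known_cumulative must be >= 0", call. = FALSE)
  nd <- if (is.data.frame(x0)) x0 else as.data.frame(as.list(x0))
  pr <- predict(fit, nd)
  if (nrow(pr) != 1L) stop("x0 must describe a single new patient", call. = FALSE)
  margin <- threshold - known_cumulative - pr$fit
  if (pr$se_pred == 0) {
    p <- if (margin < 0) 1 else if (margin > 0) 0 else 0.5
    t <- if (margin == 0) 0 else sign(margin) * Inf
  } else {
    t <- margin / pr$se_pred
    p <- pt(t, df = fit$df, lower.tail = FALSE)
  }
  structure(list(
    point_prediction = pr$fit,
    prediction_se = pr$se_pred,
    t_statistic = t,
    probability_exceed = p,
    threshold = threshold,
    known_cumulative = known_cumulative,
    df = fit$df
  ), class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Predicted remaining dose %.*f Gy (prediction SE %.*f Gy)\n",
    digits, x$point_prediction, digits, x$prediction_se))
  cat(sprintf(
    "P(cumulative dose > %g Gy | %g Gy already received) = %.*f  (t = %.3g, df = %s)\n",
    x$threshold, x$known_cumulative, digits, x$probability_exceed,
    x$t_statistic, format(x$df)))
  invisible(x)
}

#' Exceedance probability across alternative safety thresholds
#'
#' Recomputes the exceedance probability for a list of candidate safety
#' thresholds (e.g. 25 Gy vs the more permissive 29 Gy), holding the
#' model, patient and accumulated dose fixed. Probabilities are strictly
#' decreasing along an increasing threshold list.
#'
#' @inheritParams exceedance_probability
#' @param thresholds increasing vector of positive thresholds (Gy).
#' @return Data frame with columns `threshold` and `probability_exceed`.
#' @export
threshold_sensitivity <- function(fit, x0, known_cumulative, thresholds) {
  if (any(thresholds <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  p <- vapply(thresholds, function(th)
    exceedance_probability(fit, x0, known_cumulative, th)$probability_exceed,
    numeric(1))
  data.frame(threshold = thresholds, probability_exceed = p)
}

#' Exceedance-probability grid over the (D1, D2) plane
#'
#' Evaluates the exceedance probability on a rectangular grid of first-
#' and second-cycle doses, for replotting the decision-zone contour maps
#' (the 10% and 95% contours bound zones A/C for the four-cycle model and
#' D/F for the three-cycle model). D1 and D2 enter both the predictor row
#' and the known cumulative dose.
#'
#' @param fit a [dose_model] with predictors `d1` and `d2` for the
#'   remaining dose (either the 3rd+4th-cycle or the 3rd-cycle model).
#' @param d1,d2 grid axis values in Gy (defaults 0 to 12 by 0.1).
#' @param threshold safety threshold in Gy.
#' @return Data frame in long form: `d1`, `d2`, `probability_exceed`.
#' @export
exceedance_grid <- function(fit, d1 = seq(0, 12, by = 0.1),
                            d2 = seq(0, 12, by = 0.1), threshold = 25) {
  stopifnot(length(d1) >= 1, length(d2) >= 1)
  if (!setequal(fit$predictor_labels, c("d1", "d2")))
    stop("fit must have predictors d1 and d2", call. = FALSE)
  g <- expand.grid(d1 = d1, d2 = d2, KEEP.OUT.ATTRS = FALSE)
  pr <- predict(fit, g)
  margin <- threshold - g$d1 - g$d2 - pr$fit
  p <- numeric(nrow(g))
  zero <- pr$se_pred == 0
  p[zero] <- ifelse(margin[zero] < 0, 1, ifelse(margin[zero] > 0, 0, 0.5))
  p[!zero] <- pt(margin[!zero] / pr$se_pred[!zero], df = fit$df,
                 lower.tail = FALSE)
  g$probability_exceed <- p
  g
}
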