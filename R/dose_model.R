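#' Fit a kidney dose-prediction regression
#'
#' Ordinary least-squares fit of a late-cycle kidney absorbed dose (or sum
#' of doses) on earlier-cycle doses, keeping exactly the pieces the
#' predicted-Y method needs: coefficients, the residual standard error
#' \eqn{s = \sqrt{RSS/df}}, the unscaled coefficient covariance
#' \eqn{(X'X)^{-1}}, and the residual degrees of freedom \eqn{n - p - 1}.
#'
#' The design is checked for rank deficiency with a singular-value
#' decomposition: the fit aborts, naming the offending column, when the
#' smallest relative singular value falls below `tol`.
#'
#' @param formula model formula, e.g. `d3 ~ d1 + d2` or
#'   `I(d2 + d3 + d4) ~ d1`. An intercept is always included.
#' @param data data frame with one row per patient; all doses in Gy.
#' @param tol relative singular-value tolerance below which the design is
#'   declared rank deficient.
#' @return An object of class `dose_model` with components
#'   `coefficients`, `residual_scale` (Gy), `xtx_inv`, `df`, `n`,
#'   `predictor_labels`, `pearson_r` (simple regression only, otherwise
#'   `NA`), `fitted`, `residuals` and `model` (the model frame).
#' @seealso [predict.dose_model()], [exceedance_probability()],
#'   [dose_model_fixed()] for building a model from known coefficients.
#' @examples
#' d <- data.frame(d1 = c(3, 4, 5, 6, 7), y = c(7.1, 9.0, 10.9, 13.2, 15.0))
#' fit <- dose_model(y ~ d1, d)
#' coef(fit)
#' predict(fit, data.frame(d1 = 5.5))
#' @export
dose_model <- function(formula, data, tol = 1e-10) {
  mf <- model.frame(formula, data, na.action = NULL)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  if (anyNA(y) || anyNA(X))
    stop("missing values in response or predictors", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 2L)
    stop(sprintf("too few rows: %d observations for %d coefficients (need at least %d)",
                 n, p, p + 2L), call. = FALSE)

  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < tol * max(sv)) {
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, p)]]
    stop(sprintf("rank-deficient design: column(s) %s linearly dependent on the others",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }

  qx <- qr(X)
  beta <- drop(qr.coef(qx, y))
  fitted <- drop(X %*% beta)
  res <- y - fitted
  df <- n - p
  rss <- sum(res^2)
  s <- sqrt(rss / df)
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))

  labels <- colnames(X)[-1L]
  r <- if (length(labels) == 1L) cor(X[, 2L], y) else NA_real_

  structure(list(
    coefficients = beta,
    residual_scale = s,
    xtx_inv = xtx_inv,
    df = df,
    n = n,
    predictor_labels = labels,
    pearson_r = r,
    fitted = fitted,
    residuals = res,
    model = mf,
    call = match.call()
  ), class = "dose_model")
}

#' Build a dose-prediction model from known coefficients
#'
#' Constructs a `dose_model` without data, e.g. from published regression
#' coefficients, for planning and for noiseless worked examples. With
#' `residual_scale = 0` the predictive law degenerates to a step function
#' and every planning operation reduces to a deterministic threshold
#' comparison.
#'
#' @param coefficients named numeric vector, intercept first; predictor
#'   names are taken from the remaining elements.
#' @param residual_scale residual standard error s in Gy (default 0).
#' @param xtx_inv optional unscaled coefficient covariance; when `NULL`
#'   the prediction leverage is taken as 0, so the new-observation
#'   standard error equals `residual_scale`.
#' @param df residual degrees of freedom (default `Inf`, i.e. a normal
#'   predictive law).
#' @param n number of observations behind the fit, if known.
#' @return A `dose_model` object.
#' @examples
#' # published model for D3 + D4 given D1 and D2
#' eq1 <- dose_model_fixed(c("(Intercept)" = 1.39, d1 = 0.56, d2 = 1.19),
#'                         residual_scale = 1.7, df = 87)
#' predict(eq1, data.frame(d1 = 6, d2 = 6))
#' @export
dose_model_fixed <- function(coefficients, residual_scale = 0,
                             xtx_inv = NULL, df = Inf, n = NA_integer_) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("coefficients must be named, intercept first", call. = FALSE)
  if (residual_scale < 0) stop("residual_scale must be >= 0", call. = FALSE)
  if (df < 1) stop("degrees of freedom must be >= 1", call. = FALSE)
  p <- length(coefficients)
  if (!is.null(xtx_inv)) {
    xtx_inv <- as.matrix(xtx_inv)
    if (!all(dim(xtx_inv) == p))
      stop("xtx_inv must be a ", p, "x", p, " matrix", call. = FALSE)
    if (max(abs(xtx_inv - t(xtx_inv))) > 1e-8 * max(1, max(abs(xtx_inv))))
      stop("xtx_inv must be symmetric", call. = FALSE)
  }
  structure(list(
    coefficients = coefficients,
    residual_scale = residual_scale,
    xtx_inv = xtx_inv,
    df = df,
    n = n,
    predictor_labels = names(coefficients)[-1L],
    pearson_r = NA_real_,
    fitted = NULL,
    residuals = NULL,
    model = NULL,
    call = match.call()
  ), class = "dose_model")
}

#' Predict a new observation from a dose-prediction model
#'
#' Point prediction and the \emph{new-observation} standard error
#' \eqn{s\sqrt{1 + x_0'(X'X)^{-1}x_0}} — the spread of a single future
#' response, not of the mean response. This is the quantity the
#' exceedance-probability calculation is built on.
#'
#' @param object a [dose_model] fit.
#' @param newdata data frame containing the model's predictor columns.
#' @param ... unused.
#' @return Data frame with columns `fit` (Gy) and `se_pred` (Gy), one row
#'   per row of `newdata`.
#' @export
predict.dose_model <- function(object, newdata, ...) {
  labels <- object$predictor_labels
  if (missing(newdata)) {
    if (is.null(object$model))
      stop("newdata required for a coefficient-only model", call. = FALSE)
    newdata <- object$model
  }
  newdata <- as.data.frame(newdata)
  miss <- setdiff(labels, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  X0 <- cbind(`(Intercept)` = 1,
              as.matrix(newdata[, labels, drop = FALSE]))
  if (anyNA(X0)) stop("missing values in newdata", call. = FALSE)
  fit <- drop(X0 %*% object$coefficients)
  lev <- if (is.null(object$xtx_inv)) rep(0, nrow(X0))
         else rowSums((X0 %*% object$xtx_inv) * X0)
  se <- object$residual_scale * sqrt(1 + lev)
  data.frame(fit = fit, se_pred = se)
}

#' @export
coef.dose_model <- function(object, ...) object$coefficients

#' @export
residuals.dose_model <- function(object, ...) object$residuals

#' @importFrom stats sigma
#' @export
sigma.dose_model <- function(object, ...) object$residual_scale

#' @export
print.dose_model <- function(x, digits = 4, ...) {
  cat("Kidney dose-prediction model:",
      paste(x$predictor_labels, collapse = " + "), "\n")
  print(round(x$coefficients, digits))
  cat(sprintf("residual scale s = %.*f Gy on %s degrees of freedom (n = %s)\n",
              digits, x$residual_scale,
              format(x$df), format(x$n)))
  invisible(x)
}

#' Summarise a dose-prediction model
#'
#' Adds the residual diagnostics used to validate the modelling
#' assumptions: a Lilliefors test of residual normality, a
#' Wald–Wolfowitz runs test of residual independence, and (for a simple
#' regression) Pearson's r.
#'
#' @param object a fitted [dose_model] (with data; coefficient-only models
#'   have no residuals to diagnose).
#' @param ... unused.
#' @return An object of class `summary.dose_model`.
#' @export
summary.dose_model <- function(object, ...) {
  out <- object[c("coefficients", "residual_scale", "df", "n",
                  "predictor_labels", "pearson_r")]
  if (!is.null(object$residuals) && length(object$residuals) >= 10 &&
      sd(object$residuals) > 0) {
    out$lilliefors_p <- lilliefors_normality(object$residuals)
    out$runs_p <- tryCatch(runs_test_independence(object$residuals),
                           error = function(e) NA_real_)
  } else {
    out$lilliefors_p <- NA_real_
    out$runs_p <- NA_real_
  }
  class(out) <- "summary.dose_model"
  out
}

#' @export
print.summary.dose_model <- function(x, digits = 4, ...) {
  cat("Kidney dose-prediction model:",
      paste(x$predictor_labels, collapse = " + "), "\n\nCoefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("\nresidual scale s = %.*f Gy, df = %s, n = %s\n",
              digits, x$residual_scale, format(x$df), format(x$n)))
  if (!is.na(x$pearson_r))
    cat(sprintf("Pearson r = %.*f\n", digits, x$pearson_r))
  if (!is.na(x$lilliefors_p))
    cat(sprintf("Lilliefors normality p = %.3g; runs independence p = %.3g\n",
                x$lilliefors_p, x$runs_p))
  invisible(x)
}

#' @export
plot.dose_model <- function(x, ...) {
  if (is.null(x$fitted))
    stop("coefficient-only model: nothing to plot", call. = FALSE)
  y <- x$fitted + x$residuals
  plot(x$fitted, y, xlab = "fitted dose (Gy)", ylab = "observed dose (Gy)",
       main = "Observed vs fitted", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate new responses from the predictive law of a fitted model
#'
#' Draws future single observations as
#' \eqn{\hat y(x_0) + s\sqrt{1+h_0}\,T_{df}}: the same law the exceedance
#' probability integrates.
#'
#' @param object a [dose_model].
#' @param nsim number of draws per row of `newdata`.
#' @param seed optional integer seed.
#' @param newdata data frame of predictor values.
#' @param ... unused.
#' @return Matrix with `nrow(newdata)` rows and `nsim` columns.
#' @export
simulate.dose_model <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  pr <- predict(object, newdata)
  m <- nrow(pr)
  draws <- if (is.finite(object$df)) rt(m * nsim, df = object$df)
           else rnorm(m * nsim)
  matrix(pr$fit + pr$se_pred * draws, nrow = m, ncol = nsim)
}

#' Fit the four planning regressions from a cohort
#'
#' Convenience wrapper producing, from a per-cycle cohort:
#' \describe{
#'   \item{simple}{`D2 + D3 + D4 ~ D1` on patients with 4 cycles}
#'   \item{eq1}{`D3 + D4 ~ D1 + D2` on patients with 4 cycles}
#'   \item{eq2}{`D3 ~ D1 + D2` on patients with at least 3 cycles}
#'   \item{eq3}{`D4 ~ D1 + D2 + D3` on patients with 4 cycles}
#' }
#'
#' @param cohort cohort data frame (long form, see [read_cohort()]) or the
#'   wide per-patient form from [cohort_wide()].
#' @param tol rank tolerance passed to [dose_model()].
#' @return Named list of `dose_model` objects: `simple`, `eq1`, `eq2`,
#'   `eq3`.
#' @export
fit_dose_models <- function(cohort, tol = 1e-10) {
  w <- if (all(c("d1", "cycles_completed") %in% names(cohort))) cohort
       else cohort_wide(cohort)
  four <- w[w$cycles_completed >= 4L, , drop = FALSE]
  three <- w[w$cycles_completed >= 3L, , drop = FALSE]
  four$d234 <- four$d2 + four$d3 + four$d4
  four$d34 <- four$d3 + four$d4
  list(
    simple = dose_model(d234 ~ d1, four, tol = tol),
    eq1 = dose_model(d34 ~ d1 + d2, four, tol = tol),
    eq2 = dose_model(d3 ~ d1 + d2, three, tol = tol),
    eq3 = dose_model(d4 ~ d1 + d2 + d3, four, tol = tol)
  )
}
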