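# published dose-chain coefficients used as generating ground truth
EQ1 <- c(`(Intercept)` = 1.39, d1 = 0.56, d2 = 1.19)   # D3 + D4 | D1, D2
EQ2 <- c(`(Intercept)` = 0.37, d1 = 0.14, d2 = 0.83)   # D3 | D1, D2
EQ3 <- c(`(Intercept)` = 0.99, d1 = 0.12, d2 = 0.19, d3 = 0.50)  # D4 | ...

# noiseless planning models: every probability is a 0/1 step
noiseless_fits <- function(simple = c(`(Intercept)` = 2.5, d1 = 3)) {
  list(simple = dose_model_fixed(simple),
       eq1 = dose_model_fixed(EQ1),
       eq2 = dose_model_fixed(EQ2),
       eq3 = dose_model_fixed(EQ3))
}

# smooth planning models with a normal predictive law of scale s
noisy_fits <- function(s = 1.7, df = 60) {
  list(simple = dose_model_fixed(c(`(Intercept)` = 4.4, d1 = 2.2),
                                 residual_scale = s, df = df),
       eq1 = dose_model_fixed(EQ1, residual_scale = s, df = df),
       eq2 = dose_model_fixed(EQ2, residual_scale = 0.7 * s, df = df),
       eq3 = dose_model_fixed(EQ3, residual_scale = 0.5 * s, df = df))
}

# generator with stopping switched off, for calibration checks
no_dropout_config <- function(...) {
  generator_config(dropout = c(cycle1 = 0, cycle2 = 0, cycle3 = 0,
                               completed = 1),
                   kidney_rule = list(enabled = FALSE), ...)
}

# tiny hand-written cohort: one completer, one 2-cycle stop
toy_cohort <- function() {
  as_cohort(data.frame(
    patient_id = c(rep("A", 4), rep("B", 2)),
    cycle = c(1:4, 1:2),
    dose_gy = c(2, 2.1, 2.2, 2.3, 7, 7.5),
    activity_gbq = 7.4,
    stop_reason = c(rep("completed", 4), rep("clinical_deterioration", 2)),
    stringsAsFactors = FALSE))
}

# upper-tail t probability computed directly, as an independent check
tail_prob <- function(coefs, x0, s, df, known, threshold, lev = 0) {
  point <- coefs[1] + sum(coefs[-1] * x0)
  se <- s * sqrt(1 + lev)
  unname(pt((threshold - known - point) / se, df = df, lower.tail = FALSE))
}
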