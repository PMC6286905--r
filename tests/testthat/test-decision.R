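test_that("legacy extrapolation rule: cum (p+1)/p, boundary at 18.75 Gy", {
  # three cycles summing to exactly 18.75 Gy sit on the 25 Gy boundary
  expect_identical(legacy_expected_cumulative(rep(6.25, 3)), 25)
  expect_false(legacy_withhold(rep(6.25, 3)))
  expect_equal(legacy_expected_cumulative(10), 20)
  expect_equal(legacy_expected_cumulative(c(7, 7, 7)), 28)
  expect_true(legacy_withhold(c(7, 7, 7)))
  expect_error(legacy_expected_cumulative(numeric()), "no doses")
  # identity cum * (p+1)/p over random inputs
  set.seed(13)
  for (k in 1:50) {
    d <- runif(sample(1:4, 1), 0.5, 10)
    p <- length(d)
    expect_equal(legacy_expected_cumulative(d), sum(d) * (p + 1) / p)
  }
})

test_that("first-cycle threshold has the noiseless closed form (25-a)/(1+b)", {
  fit <- dose_model_fixed(c(`(Intercept)` = 2.5, d1 = 3))
  t1 <- first_cycle_threshold(fit)
  expect_equal(t1, (25 - 2.5) / (1 + 3), tolerance = 1e-3)
  # a higher safety threshold strictly raises T1
  t1_29 <- first_cycle_threshold(fit, risk_policy(dose_threshold = 29))
  expect_equal(t1_29, (29 - 2.5) / 4, tolerance = 1e-3)
  expect_gt(t1_29, t1)
})

test_that("bisection lands within 0.002 of the clearance risk", {
  fit <- dose_model_fixed(c(`(Intercept)` = 4.4, d1 = 2.2),
                          residual_scale = 1.9, df = 88)
  pol <- risk_policy()
  t1 <- first_cycle_threshold(fit, pol)
  p_at <- exceedance_probability(fit, c(d1 = t1), t1, 25)$probability_exceed
  expect_lt(p_at, pol$continue_risk)
  expect_gt(p_at, pol$continue_risk - 0.002)
  # raising the threshold to 29 Gy increases T1 for this noisy fit too
  expect_gt(first_cycle_threshold(fit, risk_policy(dose_threshold = 29)), t1)
})

test_that("threshold search rejects degenerate fits", {
  down <- dose_model_fixed(c(`(Intercept)` = 10, d1 = -2),
                           residual_scale = 1, df = 30)
  expect_error(first_cycle_threshold(down), "non-monotone")
  hot <- dose_model_fixed(c(`(Intercept)` = 40, d1 = 2),
                          residual_scale = 1, df = 30)
  expect_error(first_cycle_threshold(hot), "never attained")
})

test_that("zone classification matches direct tail arithmetic", {
  f1 <- dose_model_fixed(EQ1, residual_scale = 1.8, df = 87)
  f2 <- dose_model_fixed(EQ2, residual_scale = 0.75, df = 125)
  pol <- risk_policy()
  cases <- list(c(3, 3), c(5.5, 5.5), c(6.5, 6.5), c(8, 8), c(10, 10))
  for (d in cases) {
    z <- classify_zones(f1, f2, d[1], d[2], pol)
    p4 <- tail_prob(EQ1, d, 1.8, 87, sum(d), 25)
    p3 <- tail_prob(EQ2, d, 0.75, 125, sum(d), 25)
    expect_equal(z$p4, p4, tolerance = 1e-10)
    expect_equal(z$p3, p3, tolerance = 1e-10)
    expect_equal(z$four_cycle_zone,
                 if (p4 < 0.10) "A" else if (p4 > 0.95) "C" else "B")
    expect_equal(z$three_cycle_zone,
                 if (p3 < 0.10) "D" else if (p3 > 0.95) "F" else "E")
  }
  # each probability pair maps to exactly one zone pair
  zs <- classify_zones(f1, f2, 6.5, 6.5, pol)
  expect_length(zs$four_cycle_zone, 1)
  expect_error(classify_zones(f1, f2, -1, 5), "positive")
})

test_that("boundary probabilities fall in the intermediate zones B/E", {
  # noiseless models put the probability exactly at 0.5; with the
  # clearance level also at 0.5 the tie must classify as B/E, not A/D
  f1 <- dose_model_fixed(EQ1)
  f2 <- dose_model_fixed(EQ2)
  pol <- risk_policy(continue_risk = 0.5, preclusion_risk = 0.05)
  pred <- 1.39 + 0.56 * 5 + 1.19 * 5   # remaining dose at d1 = d2 = 5
  pol25 <- risk_policy(dose_threshold = 10 + pred,
                       continue_risk = 0.5, preclusion_risk = 0.05)
  z <- classify_zones(f1, f2, 5, 5, pol25)
  expect_equal(z$p4, 0.5)
  expect_equal(z$four_cycle_zone, "B")
})

test_that("the follow-up algorithm reproduces hand-worked noiseless cases", {
  fits <- noiseless_fits()          # T1 = (25 - 2.5)/4 = 5.625
  pol <- risk_policy()
  # cycle 1: clearance below T1
  expect_equal(recommend(4.0, fits, pol)$action, "complete_all_four_no_pts")
  expect_equal(recommend(5.7, fits, pol)$action, "continue_with_pts")
  # cycle 2 hand oracle: P4 = [d1+d2+eq1 > 25], P3 = [d1+d2+eq2 > 25]
  hand2 <- function(d1, d2) {
    p4 <- (d1 + d2 + 1.39 + 0.56 * d1 + 1.19 * d2) > 25
    p3 <- (d1 + d2 + 0.37 + 0.14 * d1 + 0.83 * d2) > 25
    if (p3) "stop_now"
    else if (p4) "give_three_only_no_pts"
    else "complete_all_four_no_pts"
  }
  for (d in list(c(3, 3), c(5, 5), c(6, 6), c(7, 7), c(8, 8),
                 c(9, 9), c(10, 10), c(4, 8), c(8, 4), c(12, 12))) {
    expect_equal(recommend(d, fits, pol)$action, hand2(d[1], d[2]),
                 info = paste(d, collapse = ","))
  }
  # cycle 3: noiseless D4 prediction of 9 Gy on top of 27 Gy -> stop
  fits9 <- noiseless_fits()
  fits9$eq3 <- dose_model_fixed(c(`(Intercept)` = 0, d1 = 0, d2 = 0, d3 = 1))
  expect_equal(recommend(c(9, 9, 9), fits9, pol)$action, "stop_now")
  expect_equal(recommend(c(3, 3, 3), fits9, pol)$action,
               "complete_all_four_no_pts")
  expect_error(recommend(numeric(), fits, pol), "no doses")
  expect_error(recommend(rep(3, 4), fits, pol), "nothing left")
})

test_that("the give-three-only case arises at the C/D intersection", {
  f1 <- dose_model_fixed(EQ1, residual_scale = 1.0, df = 87)
  f2 <- dose_model_fixed(EQ2, residual_scale = 0.6, df = 125)
  fits <- list(simple = dose_model_fixed(c(`(Intercept)` = 4.4, d1 = 2.2),
                                         residual_scale = 1.9, df = 88),
               eq1 = f1, eq2 = f2,
               eq3 = dose_model_fixed(EQ3, residual_scale = 0.6, df = 86))
  # find a (d1, d2) with P4 > 0.95 and P3 < 0.10
  z <- classify_zones(f1, f2, 7.6, 7.6)
  expect_equal(z$four_cycle_zone, "C")
  expect_equal(z$three_cycle_zone, "D")
  expect_equal(recommend(c(7.6, 7.6), fits)$action, "give_three_only_no_pts")
})

test_that("recommendations never relax as doses increase", {
  fits <- noisy_fits()
  pol <- risk_policy()
  set.seed(404)
  for (k in 1:300) {
    stage <- sample(1:3, 1)
    d <- runif(stage, 1, 11)
    j <- sample(stage, 1)
    d2 <- d
    d2[j] <- d2[j] + runif(1, 0.1, 3)
    s1 <- action_severity(recommend(d, fits, pol)$action)
    s2 <- action_severity(recommend(d2, fits, pol)$action)
    expect_gte(s2, s1)
  }
  expect_error(action_severity("ponder"), "unknown action")
})

test_that("observer-variability helpers match the reported worst case", {
  expect_equal(worst_case_variability(-6.5, 6.8), 13.3)
  expect_equal(round(perturb_dose(5.6, 0.133), 1), 6.3)
  expect_equal(perturb_dose(5.6, 0), 5.6)
  expect_error(perturb_dose(5.6, -1), "> -1")
  expect_error(perturb_dose(-2, 0.1), "positive")
})

test_that("risk policy validates its levels", {
  expect_error(risk_policy(dose_threshold = -5), "> 0")
  expect_error(risk_policy(continue_risk = 0.97, preclusion_risk = 0.05),
               "continue_risk")
  pol <- risk_policy(29, 0.2, 0.1)
  expect_equal(pol$dose_threshold, 29)
})
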