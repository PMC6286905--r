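#' Risk policy for treatment-planning decisions
#'
#' Encodes the two asymmetric significance levels of the planning method:
#' a further cycle is \emph{cleared} when the probability of exceeding the
#' dose threshold is below `continue_risk` (default 10%), and
#' \emph{precluded} when that probability is above
#' `1 - preclusion_risk` (default above 95%). The asymmetry is
#' deliberate: wrongly giving a toxic cycle and wrongly withholding an
#' effective one carry different costs.
#'
#' @param dose_threshold cumulative kidney dose safety threshold in Gy
#'   (default 25; 29 is the common alternative).
#' @param continue_risk clearance level (default 0.10).
#' @param preclusion_risk preclusion level (default 0.05, applied as
#'   exceedance probability > 0.95).
#' @return Object of class `risk_policy`.
#' @export
risk_policy <- function(dose_threshold = 25, continue_risk = 0.10,
                        preclusion_risk = 0.05) {
  if (dose_threshold <= 0) stop("dose_threshold must be > 0", call. = FALSE)
  if (!(continue_risk > 0 && continue_risk < 1 - preclusion_risk &&
        preclusion_risk > 0))
    stop("need 0 < continue_risk < 1 - preclusion_risk < 1", call. = FALSE)
  structure(list(dose_threshold = dose_threshold,
                 continue_risk = continue_risk,
                 preclusion_risk = preclusion_risk),
            class = "risk_policy")
}

#' First-cycle clearance threshold T1
#'
#' The largest first-cycle dose D1 such that the probability of the
#' four-cycle cumulative dose D1 + (D2 + D3 + D4) exceeding the safety
#' threshold stays below the clearance level. Patients with D1 below T1
#' can receive all four cycles without further dosimetry scans. Found by
#' bisection on D1 (the exceedance probability is monotone increasing in
#' D1 for a positive-slope fit); in the noiseless limit this reduces to
#' the closed form (threshold - a) / (1 + b) for a fit y = a + b D1.
#'
#' @param fit_simple [dose_model] of the remaining three-cycle dose sum on
#'   the single predictor `d1`.
#' @param policy a [risk_policy()].
#' @param bracket search interval for D1 in Gy.
#' @param tol bisection tolerance on D1 in Gy.
#' @return T1 in Gy.
#' @export
first_cycle_threshold <- function(fit_simple, policy = risk_policy(),
                                  bracket = c(1e-3, 50), tol = 1e-4) {
  stopifnot(inherits(fit_simple, "dose_model"))
  if (length(fit_simple$predictor_labels) != 1L)
    stop("fit_simple must have a single predictor (d1)", call. = FALSE)
  lab <- fit_simple$predictor_labels
  slope <- fit_simple$coefficients[[2L]]
  if (slope <= -1)
    stop("non-monotone threshold search: exceedance is not increasing in d1",
         call. = FALSE)
  pexc <- function(d1) {
    x0 <- setNames(list(d1), lab)
    exceedance_probability(fit_simple, as.data.frame(x0),
                           known_cumulative = d1,
                           threshold = policy$dose_threshold)$probability_exceed
  }
  lo <- bracket[1]; hi <- bracket[2]
  if (pexc(lo) >= policy$continue_risk)
    stop("risk never attained in bracket: exceedance at ", lo,
         " Gy already >= ", policy$continue_risk, call. = FALSE)
  if (pexc(hi) < policy$continue_risk)
    stop("risk never reached in bracket: exceedance at ", hi,
         " Gy still below ", policy$continue_risk, call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pexc(mid) < policy$continue_risk) lo <- mid else hi <- mid
  }
  lo
}

#' Classify a patient into the four-cycle and three-cycle decision zones
#'
#' From the observed first- and second-cycle doses, computes
#' P4 = P(D1 + D2 + D3 + D4 > threshold) via the model for D3 + D4, and
#' P3 = P(D1 + D2 + D3 > threshold) via the model for D3, then maps them
#' to zones: A (P4 < clearance), C (P4 > 1 - preclusion), B between, and
#' likewise D/E/F for P3. Boundary values fall in the intermediate zones
#' B/E — more monitoring is the conservative failure mode.
#'
#' @param fit_eq1 [dose_model] for D3 + D4 on (d1, d2).
#' @param fit_eq2 [dose_model] for D3 on (d1, d2).
#' @param d1,d2 observed doses in Gy (> 0).
#' @param policy a [risk_policy()].
#' @return List with `four_cycle_zone` ("A"/"B"/"C"), `three_cycle_zone`
#'   ("D"/"E"/"F"), and the probabilities `p4`, `p3`.
#' @export
classify_zones <- function(fit_eq1, fit_eq2, d1, d2,
                           policy = risk_policy()) {
  if (d1 <= 0 || d2 <= 0) stop("doses must be positive", call. = FALSE)
  x0 <- data.frame(d1 = d1, d2 = d2)
  known <- d1 + d2
  p4 <- exceedance_probability(fit_eq1, x0, known,
                               policy$dose_threshold)$probability_exceed
  p3 <- exceedance_probability(fit_eq2, x0, known,
                               policy$dose_threshold)$probability_exceed
  hi <- 1 - policy$preclusion_risk
  z4 <- if (p4 < policy$continue_risk) "A" else if (p4 > hi) "C" else "B"
  z3 <- if (p3 < policy$continue_risk) "D" else if (p3 > hi) "F" else "E"
  list(four_cycle_zone = z4, three_cycle_zone = z3, p4 = p4, p3 = p3)
}

planning_actions <- c("complete_all_four_no_pts", "continue_with_pts",
                      "give_three_only_no_pts", "individual_review",
                      "stop_now")

#' Caution ordering of planning actions
#'
#' Severity rank of a recommendation, from clearing all four cycles
#' (rank 1) to stopping now (rank 5). Ordered by how much treatment the
#' action withholds:
#' `complete_all_four_no_pts < continue_with_pts <
#' give_three_only_no_pts < individual_review < stop_now`.
#' Under positive-slope fits, increasing any observed dose never moves
#' the recommendation to a lower rank.
#'
#' @param action character vector of action labels.
#' @return Integer severity ranks.
#' @export
action_severity <- function(action) {
  rank <- c(complete_all_four_no_pts = 1L, continue_with_pts = 2L,
            give_three_only_no_pts = 3L, individual_review = 4L,
            stop_now = 5L)
  bad <- setdiff(action, names(rank))
  if (length(bad)) stop("unknown action(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  unname(rank[action])
}

#' Follow-up recommendation after 1, 2 or 3 treatment cycles
#'
#' The renal-dosimetry follow-up algorithm:
#' \itemize{
#'   \item After cycle 1: if D1 is below the first-cycle threshold T1,
#'     complete all four cycles with no further post-treatment scans;
#'     otherwise continue with scanning.
#'   \item After cycle 2: classify into zones and apply, in precedence
#'     order, F (stop now), C with D (give three cycles only, no further
#'     scans), A (complete all four, no further scans), E (individual
#'     review), otherwise B with D (continue with scanning). Stopping
#'     conditions are checked before clearances.
#'   \item After cycle 3: the fourth cycle is decided from the model for
#'     D4 — exceedance below the clearance level completes the course
#'     (treatment ends, no further scans), above the preclusion level
#'     stops now, otherwise individual review.
#' }
#'
#' @param doses_so_far numeric vector of 1-3 observed per-cycle doses
#'   (Gy).
#' @param fits named list of [dose_model]s: `simple` (D2+D3+D4 ~ d1),
#'   `eq1` (D3+D4 ~ d1 + d2), `eq2` (D3 ~ d1 + d2), `eq3`
#'   (D4 ~ d1 + d2 + d3), e.g. from [fit_dose_models()].
#' @param policy a [risk_policy()].
#' @return Object of class `decision_state`: `action`, `stage` (cycles
#'   observed), `four_cycle_zone`/`three_cycle_zone` (stage 2 only,
#'   otherwise NA) and `probabilities`.
#' @export
recommend <- function(doses_so_far, fits, policy = risk_policy()) {
  doses <- as.numeric(doses_so_far)
  if (length(doses) < 1L) stop("no doses observed", call. = FALSE)
  if (length(doses) > 3L)
    stop("all four cycles given: nothing left to decide", call. = FALSE)
  if (any(doses <= 0)) stop("doses must be positive", call. = FALSE)
  stage <- length(doses)
  z4 <- z3 <- NA_character_
  probs <- c()

  if (stage == 1L) {
    t1 <- first_cycle_threshold(fits$simple, policy)
    action <- if (doses[1] < t1) "complete_all_four_no_pts"
              else "continue_with_pts"
    probs <- c(t1 = t1)
  } else if (stage == 2L) {
    z <- classify_zones(fits$eq1, fits$eq2, doses[1], doses[2], policy)
    z4 <- z$four_cycle_zone; z3 <- z$three_cycle_zone
    probs <- c(p4 = z$p4, p3 = z$p3)
    action <-
      if (z3 == "F") "stop_now"
      else if (z4 == "C" && z3 == "D") "give_three_only_no_pts"
      else if (z4 == "A") "complete_all_four_no_pts"
      else if (z3 == "E") "individual_review"
      else "continue_with_pts"
  } else {
    x0 <- data.frame(d1 = doses[1], d2 = doses[2], d3 = doses[3])
    p <- exceedance_probability(fits$eq3, x0, sum(doses),
                                policy$dose_threshold)$probability_exceed
    probs <- c(p4 = p)
    action <-
      if (p < policy$continue_risk) "complete_all_four_no_pts"
      else if (p > 1 - policy$preclusion_risk) "stop_now"
      else "individual_review"
  }
  structure(list(action = action, stage = stage,
                 four_cycle_zone = z4, three_cycle_zone = z3,
                 probabilities = probs),
            class = "decision_state")
}

#' @export
print.decision_state <- function(x, ...) {
  cat(sprintf("After cycle %d: %s\n", x$stage, x$action))
  if (!is.na(x$four_cycle_zone))
    cat(sprintf("zones: %s / %s  (P4 = %.3f, P3 = %.3f)\n",
                x$four_cycle_zone, x$three_cycle_zone,
                x$probabilities[["p4"]], x$probabilities[["p3"]]))
  invisible(x)
}

#' Legacy expected cumulative dose after the next cycle
#'
#' The pre-existing extrapolation rule: the expected cumulative kidney
#' dose after the next cycle is the cumulative dose over the p cycles
#' given so far plus their mean, i.e. cum (p + 1) / p. Treatment is
#' withheld when this exceeds the safety threshold — after three cycles
#' the boundary is a cumulative dose of 18.75 Gy against a 25 Gy
#' threshold.
#'
#' @param doses numeric vector of observed per-cycle doses (Gy),
#'   length >= 1.
#' @return Expected cumulative dose after the next cycle, in Gy.
#' @export
legacy_expected_cumulative <- function(doses) {
  doses <- as.numeric(doses)
  p <- length(doses)
  if (p < 1L) stop("no doses observed", call. = FALSE)
  sum(doses) * (p + 1) / p
}

#' @rdname legacy_expected_cumulative
#' @param policy a [risk_policy()]; the rule withholds when the expected
#'   cumulative dose exceeds `policy$dose_threshold`.
#' @return `legacy_withhold` returns TRUE when the next cycle would be
#'   withheld.
#' @export
legacy_withhold <- function(doses, policy = risk_policy()) {
  legacy_expected_cumulative(doses) > policy$dose_threshold
}

#' Observer-variability perturbation of a dose
#'
#' Shifts a dose by a relative fraction, for propagating intra- and
#' inter-observer variability of the dosimetry calculation through the
#' planning decisions (reported variability: intra -1.0 +/- 3.4%, inter
#' -6.5 +/- 6.8%, i.e. a worst case of 13.3%).
#'
#' @param dose dose in Gy (> 0).
#' @param relative_shift relative shift as a fraction (0.133 = +13.3%);
#'   must be > -1.
#' @return Perturbed dose in Gy (full precision; round only for display).
#' @export
perturb_dose <- function(dose, relative_shift) {
  if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
  if (any(relative_shift <= -1))
    stop("relative_shift must be > -1 (dose must stay positive)",
         call. = FALSE)
  dose * (1 + relative_shift)
}

#' @rdname perturb_dose
#' @param mean_pct,sd_pct mean and standard deviation of the observer
#'   variability, in percent.
#' @return `worst_case_variability` returns |mean| + sd, in percent.
#' @export
worst_case_variability <- function(mean_pct, sd_pct) {
  abs(mean_pct) + sd_pct
}
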