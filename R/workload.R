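#' Scan and inpatient-night counting rules
#'
#' Encodes the dosimetry imaging schedule: full dosimetry after the first
#' cycle (three SPECT/CT sessions at about 20 h, 25 h and 7 days) and a
#' single scan after each subsequent cycle; patients stay one night after
#' a scanned cycle (the scan cannot be done too soon after injection),
#' while an unscanned cycle allows same-day release after a few hours of
#' decay. Totals from the source study cannot be reconstructed exactly
#' from its printed cycle counts, so every rule is configurable and the
#' defaults are an approximation of that schedule.
#'
#' @param scans_first_cycle scans after cycle 1 (default 3).
#' @param scans_subsequent_cycle scans after each later scanned cycle
#'   (default 1).
#' @param nights_per_scanned_cycle inpatient nights per scanned cycle
#'   (default 1).
#' @param nights_per_unscanned_cycle nights per unscanned cycle
#'   (default 0, same-day release).
#' @param scan_minutes duration of a post-treatment scan (default 35).
#' @param planar_minutes duration of the optional pre-release planar
#'   whole-body exam offered on unscanned cycles (default 15; reported
#'   separately, never counted as a post-treatment scan).
#' @return Object of class `counting_rules`.
#' @export
counting_rules <- function(scans_first_cycle = 3L,
                           scans_subsequent_cycle = 1L,
                           nights_per_scanned_cycle = 1L,
                           nights_per_unscanned_cycle = 0L,
                           scan_minutes = 35,
                           planar_minutes = 15) {
  r <- list(scans_first_cycle = scans_first_cycle,
            scans_subsequent_cycle = scans_subsequent_cycle,
            nights_per_scanned_cycle = nights_per_scanned_cycle,
            nights_per_unscanned_cycle = nights_per_unscanned_cycle,
            scan_minutes = scan_minutes,
            planar_minutes = planar_minutes)
  if (any(unlist(r) < 0)) stop("counting rules must be non-negative",
                               call. = FALSE)
  structure(r, class = "counting_rules")
}

#' Scans and nights under the empiric protocol
#'
#' Every administered cycle is scanned: the first cycle gets the full
#' dosimetry series, later cycles one scan each, and each cycle costs one
#' inpatient night.
#'
#' @param cohort a cohort (long form or [cohort_wide()] output).
#' @param rules a [counting_rules()].
#' @return List with totals `scans`, `nights`, and a `per_patient` data
#'   frame.
#' @export
count_empiric <- function(cohort, rules = counting_rules()) {
  w <- if (all(c("cycles_completed", "patient_id") %in% names(cohort)))
    cohort else cohort_wide(cohort)
  cc <- w$cycles_completed
  scans <- rules$scans_first_cycle +
    rules$scans_subsequent_cycle * (cc - 1L)
  nights <- rules$nights_per_scanned_cycle * cc
  list(scans = sum(scans), nights = sum(nights),
       per_patient = data.frame(patient_id = w$patient_id,
                                cycles_completed = cc,
                                scans = scans, nights = nights,
                                stringsAsFactors = FALSE))
}

#' Plan per-patient follow-up decisions for a whole cohort
#'
#' Walks each patient through the follow-up algorithm: the first cycle is
#' always scanned (full dosimetry); each subsequent administered cycle is
#' scanned only while the latest recommendation is `continue_with_pts`.
#' Once a clearance, restriction or stop is issued, scanning ends and the
#' remaining administered cycles are release-without-dosimetry cycles.
#'
#' @param cohort a cohort in long form.
#' @param fits model list as from [fit_dose_models()].
#' @param policy a [risk_policy()].
#' @return List (one element per patient) with `patient_id`, `scanned`
#'   (logical per administered cycle), `decisions` (list of
#'   `decision_state`), `final_action`.
#' @export
plan_cohort <- function(cohort, fits, policy = risk_policy()) {
  w <- cohort_wide(cohort)
  lapply(seq_len(nrow(w)), function(i) {
    cc <- w$cycles_completed[i]
    doses <- as.numeric(w[i, c("d1", "d2", "d3", "d4")])[seq_len(cc)]
    scanned <- c(TRUE, rep(FALSE, cc - 1L))
    decisions <- list()
    action <- NA_character_
    for (k in seq_len(min(cc, 3L))) {
      if (k > 1L && !identical(action, "continue_with_pts")) break
      dec <- recommend(doses[seq_len(k)], fits, policy)
      decisions[[k]] <- dec
      action <- dec$action
      if (k + 1L <= cc && identical(action, "continue_with_pts"))
        scanned[k + 1L] <- TRUE
    }
    list(patient_id = w$patient_id[i], scanned = scanned,
         decisions = decisions, final_action = action)
  })
}

#' Scans and nights under the predictive algorithm
#'
#' @param cohort a cohort in long form.
#' @param plans output of [plan_cohort()] for the same cohort.
#' @param rules a [counting_rules()].
#' @return List with totals `scans`, `nights`, `planar_exams` (optional
#'   pre-release planar exams on unscanned cycles, reported separately),
#'   and a `per_patient` data frame.
#' @export
count_predictive <- function(cohort, plans, rules = counting_rules()) {
  w <- cohort_wide(cohort)
  ids <- vapply(plans, `[[`, character(1), "patient_id")
  if (!setequal(ids, w$patient_id) || length(ids) != nrow(w))
    stop("plans do not match the cohort patient-by-patient", call. = FALSE)
  plans <- plans[match(w$patient_id, ids)]
  per <- lapply(seq_len(nrow(w)), function(i) {
    sc <- plans[[i]]$scanned
    if (length(sc) != w$cycles_completed[i])
      stop("plan for patient ", w$patient_id[i],
           " does not cover its administered cycles", call. = FALSE)
    n_scanned_later <- sum(sc[-1L])
    n_unscanned <- sum(!sc)
    scans <- rules$scans_first_cycle +
      rules$scans_subsequent_cycle * n_scanned_later
    nights <- rules$nights_per_scanned_cycle * sum(sc) +
      rules$nights_per_unscanned_cycle * n_unscanned
    data.frame(patient_id = w$patient_id[i],
               cycles_completed = w$cycles_completed[i],
               scans = scans, nights = nights,
               planar_exams = n_unscanned, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(scans = sum(per$scans), nights = sum(per$nights),
       planar_exams = sum(per$planar_exams), per_patient = per)
}

#' Workload reduction report
#'
#' Compares scan and inpatient-night totals between the empiric and
#' predictive protocols; reductions are 100 (1 - predictive / empiric).
#'
#' @param empiric output of [count_empiric()].
#' @param predictive output of [count_predictive()].
#' @param rules a [counting_rules()] (for the scanner-time figures).
#' @param digits rounding for the displayed percentages.
#' @return Object of class `workload_summary`.
#' @export
reduction_report <- function(empiric, predictive,
                             rules = counting_rules(), digits = 1) {
  if (empiric$scans <= 0 || empiric$nights <= 0)
    stop("empiric counts must be positive", call. = FALSE)
  structure(list(
    scans_empiric = empiric$scans,
    scans_predictive = predictive$scans,
    nights_empiric = empiric$nights,
    nights_predictive = predictive$nights,
    planar_exams = predictive$planar_exams,
    scan_reduction_pct = round(100 * (1 - predictive$scans / empiric$scans),
                               digits),
    night_reduction_pct = round(100 * (1 - predictive$nights / empiric$nights),
                                digits),
    scanner_minutes_empiric = empiric$scans * rules$scan_minutes,
    scanner_minutes_predictive = predictive$scans * rules$scan_minutes +
      predictive$planar_exams * rules$planar_minutes,
    per_patient = merge(empiric$per_patient, predictive$per_patient,
                        by = c("patient_id", "cycles_completed"),
                        suffixes = c("_empiric", "_predictive"))
  ), class = "workload_summary")
}

#' @export
print.workload_summary <- function(x, ...) {
  cat("Workload: empiric vs predictive follow-up\n")
  cat(sprintf("  post-treatment scans: %d -> %d  (%.1f%% reduction)\n",
              x$scans_empiric, x$scans_predictive, x$scan_reduction_pct))
  cat(sprintf("  inpatient nights:     %d -> %d  (%.1f%% reduction)\n",
              x$nights_empiric, x$nights_predictive, x$night_reduction_pct))
  cat(sprintf("  optional pre-release planar exams: %d\n", x$planar_exams))
  cat(sprintf("  scanner time: %g -> %g min\n",
              x$scanner_minutes_empiric, x$scanner_minutes_predictive))
  invisible(x)
}
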