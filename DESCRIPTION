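Package: prrtplan
Title: Kidney Dosimetry Prediction and Treatment Planning for Lu-177 PRRT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for planning peptide receptor radionuclide therapy
    ([177Lu]-DOTA-TATE) from per-cycle kidney absorbed doses. Fits the
    linear dose-prediction models relating early- and late-cycle kidney
    doses, computes new-observation prediction intervals and one-sided
    probabilities that the cumulative kidney dose exceeds a safety
    threshold (predicted-Y t-statistic method), derives the first-cycle
    clearance threshold by bisection, classifies patients into decision
    zones on the (D1, D2) plane, runs the renal-dosimetry follow-up
    algorithm against the legacy extrapolation rule, and quantifies the
    post-treatment scans and inpatient nights saved by predictive
    planning. Includes a calibrated synthetic-cohort generator so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
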