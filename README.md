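# prrtplan

Kidney dosimetry prediction and treatment planning for
[<sup>177</sup>Lu]-DOTA-TATE peptide receptor radionuclide therapy (PRRT).

PRRT for metastatic neuroendocrine tumors is commonly given as an
*empiric protocol* of four cycles of 7.4 GBq, limited by the cumulative
absorbed dose to the kidneys (safety threshold 25 Gy). Post-treatment
dosimetry requires SPECT/CT scanning after every cycle and an inpatient
night per scanned cycle. But per-cycle kidney doses D<sub>1</sub>…D<sub>4</sub>
are strongly linearly related across cycles, so much of that scanning is
redundant: doses of later cycles can be *predicted* from earlier ones,
with quantified uncertainty.

`prrtplan` is aimed at medical physicists and nuclear-medicine
biostatisticians. It implements:

- **Dose-prediction models** — OLS fits of the form
  D<sub>3</sub>+D<sub>4</sub> = a₁ + b₁D₁ + c₁D₂,
  D₃ = a₂ + b₂D₁ + c₂D₂, D₄ = a₃ + b₃D₁ + c₃D₂ + d₃D₃ and
  D₂+D₃+D₄ = a + bD₁, as a classed `dose_model` object with
  `print`/`summary`/`coef`/`predict`/`residuals`/`simulate`/`plot`
  methods.
- **Exceedance probabilities** by the predicted-Y method: a future
  response is t-distributed around the point prediction with the
  new-observation standard error s·√(1 + x₀ᵀ(XᵀX)⁻¹x₀), so

  P(D_T > threshold) = P( T_df > (threshold − known − ŷ(x₀)) / se_pred ).

- **Planning layer** — the first-cycle clearance threshold T₁ (largest
  D₁ with exceedance risk < 10%, found by bisection), decision zones
  A–C / D–F on the (D₁, D₂) plane at the 10% and 95% contours, the
  per-cycle follow-up algorithm, and the legacy extrapolation rule
  (expected cumulative = cum·(p+1)/p, boundary 18.75 Gy after 3 cycles)
  as a baseline.
- **Workload accounting** — post-treatment scans and inpatient nights
  under scan-every-cycle versus predictive follow-up.
- **Synthetic cohorts** — a calibrated generator (log-normal first-cycle
  dose with 66th percentile 5.6 Gy, the linear chain above with additive
  noise, realistic dropout) so everything is testable without patient
  data.

## Worked example

```r
library(prrtplan)

cfg   <- generator_config(n_patients = 400, seed = 11)
co    <- generate_cohort(cfg)
fits  <- fit_dose_models(co)
pol   <- risk_policy()            # 25 Gy, clear at <10%, preclude at >95%

first_cycle_threshold(fits$simple, pol)
#> [1] 5.5569

recommend(c(7, 7), fits, pol)
#> After cycle 2: give_three_only_no_pts
#> zones: C / D  (P4 = 0.978, P3 = 0.000)

plans <- plan_cohort(co, fits, pol)
reduction_report(count_empiric(co), count_predictive(co, plans))
#> Workload: empiric vs predictive follow-up
#>   post-treatment scans: 2015 -> 1369  (32.1% reduction)
#>   inpatient nights:     1215 -> 569  (53.2% reduction)
#>   optional pre-release planar exams: 646
#>   scanner time: 70525 -> 57605 min
```

The threshold of ≈5.6 Gy means a patient whose first-cycle kidney dose
is below it can receive all four cycles with <10% risk of exceeding
25 Gy — no further dosimetry scans needed. A patient at 7 Gy per cycle
lands at the intersection of zones C and D after the second cycle: the
four-cycle cumulative dose would exceed 25 Gy (P4 > 95%) but the
three-cycle one will not (P3 < 10%), so exactly three cycles are given
with no further scanning. Over the simulated cohort, predictive
follow-up removes about a third of the post-treatment scans and half of
the inpatient nights.

A command-line wrapper is installed at `inst/scripts/prrtplan`
(`synth`, `fit`, `classify`, `plan`, `workload`, `contour`, `report`).

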