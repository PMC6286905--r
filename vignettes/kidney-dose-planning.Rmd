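---
title: "Predictive kidney dosimetry for Lu-177 PRRT: models, decisions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive kidney dosimetry for Lu-177 PRRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prrtplan)
```

## The clinical problem

[<sup>177</sup>Lu]-DOTA-TATE therapy for neuroendocrine tumors is
typically administered as four fixed cycles of 7.4 GBq. The kidneys are
the dose-limiting organ: treatment is stopped once the expected
cumulative kidney absorbed dose would exceed a safety threshold
(25 Gy by default; 29 Gy is a commonly discussed alternative).
Monitoring that dose requires post-treatment SPECT/CT dosimetry — a
full three-scan series after the first cycle and one scan after each
later cycle — and each scanned cycle costs an inpatient night, because
the scan cannot be acquired until the tracer kinetics reach their late
descending phase (~24 h).

Per-cycle kidney doses are strongly correlated across cycles under
fixed administered activity. `prrtplan` exploits that: it fits linear
models predicting late-cycle doses from early ones, converts their
prediction uncertainty into the probability that the cumulative dose
exceeds the threshold, and uses those probabilities to decide — as
early as possible — how many cycles a patient can receive and whether
further scanning is informative.

## The model and the predicted-Y method

All four regressions are ordinary least squares with intercept:

* `simple`: $D_2+D_3+D_4 = a + b\,D_1$
* `eq1`: $D_3+D_4 = a_1 + b_1 D_1 + c_1 D_2$
* `eq2`: $D_3 = a_2 + b_2 D_1 + c_2 D_2$
* `eq3`: $D_4 = a_3 + b_3 D_1 + c_3 D_2 + d_3 D_3$

A `dose_model` stores the coefficients, the residual scale
$s=\sqrt{RSS/(n-p-1)}$, the unscaled covariance $(X^TX)^{-1}$ and the
residual degrees of freedom. For a new patient with predictor row
$x_0$, a future single response is modelled as

$$Y_0 \sim \hat y(x_0) + s\sqrt{1 + x_0^T (X^TX)^{-1} x_0}\; T_{df},$$

the *new-observation* (prediction) error — deliberately not the
narrower mean-response error, since the clinical question concerns one
patient's actual dose. The probability that the cumulative dose exceeds
a threshold $\tau$ given $k$ Gy already received is the upper t tail at
$t = (\tau - k - \hat y)/\mathrm{se_{pred}}$. It is one-sided by
construction: the question "will the dose exceed the limit" is
directional, and the 10%/95% contour pair used for decisions only makes
sense as one-sided tail levels.

Degrees of freedom follow the standard OLS convention $n-p-1$ with the
intercept counted. When $s=0$ (noiseless fixed-coefficient models, used
for worked examples and degenerate checks) the predictive law collapses
to a step function: probability 0 or 1, and 0.5 at exact equality. This
is handled explicitly rather than raised as an error so deterministic
fixtures flow through the whole planner.

Model assumptions are checked the way the method requires: residual
normality by a Lilliefors-corrected Kolmogorov–Smirnov test
(`nortest::lillie.test`) and independence by a Wald–Wolfowitz runs test
about the median. The runs test uses the normal approximation **with a
1/2 continuity correction** on the run count; without the correction
the approximation noticeably over-rejects at moderate sample sizes
(around 7–8% at the nominal 5% level for $n=50$), while with it the
size stays slightly conservative (~3–4%).

## The decision layer

**First-cycle threshold $T_1$.** The largest $D_1$ such that
$P(D_1 + (D_2+D_3+D_4) > \tau) <$ `continue_risk` (default 0.10),
found by bisection on $D_1$ to a default tolerance of $10^{-4}$ Gy
(tighter than the 0.001 Gy reporting precision, so the exceedance at
the returned $T_1$ sits within 0.002 of the target level for any
realistically smooth fit). Monotonicity of the tail in $D_1$ holds for
any slope $> -1$ because $D_1$ also enters the known cumulative; fits
violating that are rejected rather than searched. In the noiseless
limit the solver reproduces the closed form $T_1 = (\tau - a)/(1+b)$.

**Zones.** After two cycles, $P_4$ (exceedance after four cycles, via
`eq1`) and $P_3$ (after three, via `eq2`) partition the $(D_1, D_2)$
plane: zone A/B/C for $P_4$ below 10% / between / above 95%, and D/E/F
likewise for $P_3$. The zones are classified directly from the
probabilities rather than from precomputed polygons — equivalent, and
exact at the boundaries. Ties at exactly 0.10 or 0.95 fall in the
intermediate zones B/E: when a patient sits exactly on a contour, more
monitoring is the conservative failure mode.

**Follow-up algorithm.** After cycle 1: clear all four cycles if
$D_1 < T_1$, otherwise continue with scanning. After cycle 2, with an
explicit precedence that checks stopping conditions before clearances:
zone F stops treatment; C∩D gives exactly three cycles with no further
scans; A clears all four; E sends the decision to individual review;
the remaining case (B with D) continues with scanning. The published
branch structure is only available as a figure caption, so this
precedence is a reconstruction from the results text; it is encoded
explicitly so it can be audited. After cycle 3, the fourth cycle is
decided from `eq3` with the same asymmetric policy (clear below 10%,
stop above 95%, review between). Review outcomes are emitted as labels,
never auto-resolved — clinical override is out of scope.

The *legacy rule* — expected cumulative after the next cycle equals
$\mathrm{cum}\,(p+1)/p$, withhold above the threshold (boundary
18.75 Gy after three cycles against 25 Gy) — is retained as a
separately callable baseline (`legacy_expected_cumulative`,
`legacy_withhold`).

**Caution ordering.** For the monotone-safety property ("increasing an
observed dose never relaxes the recommendation") actions are ranked
`complete_all_four_no_pts < continue_with_pts <
give_three_only_no_pts < individual_review < stop_now`
(`action_severity()`). The design question here was where
give-three-only sits relative to continue-with-scanning: we rank it as
*more* cautious because it withholds a treatment cycle, and because any
increasing dose path that crosses from zone B∩D into C∩D necessarily
turns a continue into a give-three — under the opposite ranking the
monotonicity property would be violated by the algorithm's own
geometry for every continuous fit.

## The synthetic-cohort generator

The generator emulates the study conditions the models were derived
under; defaults are fixed once and are not tuning knobs.

* **First-cycle dose:** log-normal — positive and right-skewed, as
  organ-dose distributions are — parameterised by its median (4.7 Gy)
  and its 66th percentile, pinned at 5.6 Gy. The percentile is the
  empirically anchored quantity (it coincides with the reported
  clearance threshold); the median is a package choice of a plausible
  center. Setting `p66 == median` collapses to a point mass, giving the
  degenerate scale → 0 behaviour.
* **Later cycles:** $D_2 = D_1 + \varepsilon$ (the $D_2|D_1$
  conditional is never printed in the source models; unit slope and
  zero intercept encode cycles as near-replicates under fixed
  administered activity — a modelling choice, exposed in the config),
  then the `eq2`/`eq3` chain with independent Gaussian residuals.
  Residual scales (0.55, 0.7, 0.7 Gy) are calibrated so that ~13% of
  four-cycle completers exceed 25 Gy, matching the reported 12 of 90.
* **Joint mode** draws $D_3+D_4$ directly from the `eq1` form and
  splits it by a configurable fraction. Only joint mode promises that
  refitting $D_3+D_4$ on $(D_1,D_2)$ recovers the `eq1` coefficients;
  the sequential chain composes to a *different* implied coefficient
  vector (≈ (1.55, 0.33, 1.44)), and the test suite asserts both
  directions of that caveat.
* **Stopping:** each patient draws a planned non-kidney stop cycle
  (marginals 12% / 20.4% / 12.6% / 55% completion, approximating the
  reported attrition) and a stop reason from a configurable mix; the
  legacy extrapolation rule is applied mechanically before every
  subsequent cycle and stops the patient with reason `kidney_dose`.
  Applied strictly, that rule filters almost every would-be exceeder
  (<2% of completers would exceed 25 Gy), which contradicts the ~13%
  observed in practice — in reality the rule was overridden case by
  case on benefit/risk grounds. The generator therefore includes a
  per-patient override probability (default 0.4) under which a flagged
  patient continues; this is the mechanism that lets completers exceed
  the threshold, as they demonstrably did.
* **Positivity:** residuals are resampled while the resulting dose is
  non-positive (truncation would create a point mass at zero); the
  resampling budget is capped at 100 draws and exhaustion is an error,
  not a silent clamp.
* **Determinism:** one master seed; patient *i* uses a substream seed
  derived by a fixed counter scheme, so the same patient index always
  yields the same record and cohorts can be extended without
  reshuffling. `sample_first_cycle_doses` shares the same substreams.

What the generator does **not** emulate: SPECT imaging, time–activity
curves, organ segmentation, bone-marrow doses, inter-cycle activity
adjustment, or the exact (internally inconsistent) patient counts of
any particular institution's cohort. Passing tests on synthetic
cohorts demonstrate the statistical machinery is correct under the
assumed linear-chain data-generating process — not that the fitted
coefficients or workload savings transfer to another center, whose
dosimetry protocol and patient mix may differ.

## Workload accounting

Empiric protocol: 3 scans after cycle 1, one per later cycle, one
inpatient night per scanned cycle (the day-7 scan of the first series
is assumed ambulatory). Predictive protocol: cycle 1 is always scanned
(it anchors the predictions); a later cycle is scanned only while the
standing recommendation is `continue_with_pts`. Unscanned cycles allow
same-day release (~6 h decay) and zero nights by default; an optional
15-minute pre-release planar exam is tallied separately and never
counted as a dosimetry scan. Published workload totals cannot be
reconstructed exactly from published per-cycle counts (they disagree
by about 1%), so all counting rules are configurable and the defaults
are documented as an approximation. Scanner time multiplies scan
counts by 35 min per dosimetry scan; informational only.

## Numerical choices and problem sizes

* OLS via QR; rank deficiency declared below a relative singular-value
  tolerance of $10^{-10}$, reporting the offending column.
* Bisection tolerance $10^{-4}$ Gy; search bracket 0.001–50 Gy with
  explicit errors for non-monotone or never-attained targets.
* Activity conversions exact at 1 mCi = 37 MBq; rounding only at
  display time, which is what makes the observer-variability worked
  example (5.6 Gy + 13.3% → 6.34 Gy, displayed 6.3) come out as
  printed.
* Test problem sizes: coefficient recovery at $n = 10^4$ (single
  cohorts) and 200 replicates of $n = 90$; Monte-Carlo validation of
  the exceedance tail with $2\times10^5$ predictive draws per query;
  diagnostic calibration over 1000 null replications; the monotonicity
  property over $10^4$ randomized cases. These sizes make Monte-Carlo
  error comfortably smaller than the assertion tolerances while keeping
  the default suite quick.

## Known limitations

* The models are institution-specific: validity is tied to the
  dosimetry protocol that produced the training doses; coefficients
  should be refitted per center.
* The package treats "kidney absorbed dose" as a single scalar per
  cycle, as the source models do; whether that is a per-kidney or
  mean-of-both quantity is left to the data provider.
* No theoretical model justifies the linearity between early and late
  cycle doses; it is an empirical regularity, checked here by residual
  diagnostics rather than derived.
* Fixed 7.4 GBq activity is assumed throughout; activity
  individualisation would change the dose chain and is out of scope.
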