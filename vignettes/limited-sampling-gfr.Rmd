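---
title: "Methods: noncompartmental iohexol clearance and limited-sampling validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: noncompartmental iohexol clearance and limited-sampling validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ioxgfr)
```

## The measurement model

Iohexol is eliminated essentially exclusively by glomerular filtration, so
after a single IV bolus its plasma clearance equals GFR:

$$ \mathrm{GFR} = \frac{D_{exo}}{\mathrm{AUC}_{0-\infty} \cdot BW} $$

with $D_{exo}$ the exoiohexol dose in µg (total dose × 0.85, the isomer
fraction the HPLC assay quantifies), $\mathrm{AUC}_{0-\infty}$ in
µg·min/mL and body weight $BW$ in kg, giving GFR in mL/min/kg. The AUC is
assembled noncompartmentally from the observed seven-point curve
(5–480 min):

1. **C0 back-extrapolation.** An IV-bolus curve has its maximum at $t=0$
   but the first sample is at 5 min. C0 is the log-linear line through the
   first two (t, ln C) points evaluated at zero; if the first two samples
   do not decay (possible under assay noise) the first observation is used
   unchanged. Ignoring the 0–5 min segment would bias the AUC low by a
   non-trivial margin at these concentrations.
2. **Terminal slope.** $\lambda_z$ is an unweighted least-squares slope on
   (t, ln C). In automatic mode every tail of 3 to $n-1$ points ending at
   the last sample is fitted and the largest adjusted $R^2$ wins, ties
   going to the shortest tail — the point-selection behaviour of standard
   NCA software. Three-point profiles (Model D) use their last two points;
   a profile in which no candidate tail decays is flagged invalid and
   excluded from downstream statistics with its `n` made explicit.
3. **AUC to the last sample.** Trapezoidal quadrature over $[0, t_{last}]$
   with C0 prepended (see "Numerical choices" for the rule).
4. **Tail extrapolation.** $C_{last}/\lambda_z$, anchored at the *observed*
   last concentration rather than the fitted value — a stated, reproducible
   convention; the fitted-value alternative differs negligibly for
   well-behaved tails.

The extrapolated share of $\mathrm{AUC}_{0-\infty}$ is reported for every
estimate and flagged against a 25% ceiling (inclusive: exactly 25%
passes). A large share means the estimate leans on the model of the unseen
tail; flagged estimates are reported, not discarded.

## Limited-sampling models

Models A (5, 30, 60, 240), B (5, 30, 60, 120), C (5, 60, 120, 240) and
D (5, 30, 60 min) are computed by the *identical* pipeline on the
corresponding subset of samples, including refitting $\lambda_z$ per
subset. Reusing the seven-point $\lambda_z$ instead would make the
shortened schedules look artificially good precisely where they are
weakest (the tail), so recomputation is the default and the package's only
behaviour; the reference model run through the subsetting machinery is
bit-for-bit identical to direct NCA on the full profile, which the suite
checks.

Agreement with the reference is summarised per model — and per azotaemia
group, mirroring how such validations are reported — by Pearson r and OLS
regression of the model on the reference, Bland–Altman bias with 95%
limits of agreement (mean difference ± 1.96 SD, differences oriented
model − reference), and accuracy percentages P15/P30/P50: the share of
subjects whose estimate deviates at most 15/30/50% from the reference
value, the reference always the denominator and thresholds inclusive.
Accuracy proportions are compared across the four models with Pearson's
chi-square test of homogeneity on the k×2 table per threshold (no
continuity correction); if a margin is empty the function refuses and
points to an exact test. Group contrasts use the classic pooled-variance
Student's t-test, two-sided, α = 0.05. Plasma creatinine exactly at the
141 µmol/L cut-off falls between the two strict inequalities that define
the groups; it is assigned azotaemic (the conservative choice for a
screening context) with a warning.

## The synthetic cohort

No individual-level data from the underlying feline study are available,
so the simulator generates cohorts with the structure the analysis
assumes:

* **Disposition.** Two-compartment IV-bolus kinetics with renal clearance
  equal to the subject's true GFR. Defaults $V_c = 90$ mL/kg,
  $V_p = 160$ mL/kg, $CL_d = 3$ mL/min/kg give distribution and terminal
  phases (terminal half-life roughly 50–170 min across the GFR range) and
  5–480 min concentrations of the magnitude such studies report, with the
  seven-point extrapolated AUC share comfortably under 25%. The real
  compartmental behaviour of iohexol in cats is not established by the
  source data; the two-compartment default is an explicit assumption and
  every parameter is overridable in `cohort_spec()`.
* **True GFR.** Log-uniform within each group's range (1.21–8.62
  nonazotaemic, 1.36–3.47 azotaemic, mL/min/kg). The long right tail of
  the nonazotaemic range suggests a right-skewed distribution; log-uniform
  encodes that without attempting to match unpublished moments.
* **Assay noise.** Multiplicative Gaussian, CV 4% by default — the middle
  of the interday precision range of the validated HPLC assay (3.2–6.5%).
  Draws below the 0.1 µg/mL limit of quantification are flagged censored;
  negative draws are truncated to LOQ/2 (an assay floor) and flagged.
  Censored values are excluded from fitting and AUC, never imputed as
  zero.
* **Covariates.** Body weight uniform on 2–5.5 kg, dose 64.7 mg/kg × BW.
  Plasma creatinine is drawn uniformly inside each group's clinical range
  (78–140 / 143–209 µmol/L) and urea likewise (6.92–24.13 / 16.63–31.38
  mmol/L), *independently of GFR*. This is a deliberate simulator
  limitation: the source study reports group ranges but no
  creatinine–GFR regression, so the cohort reproduces the two-group
  design, not renal physiology. Group t-tests on creatinine and urea are
  therefore structural checks only.
* **Reproducibility.** One master seed; each subject's draws come from a
  substream hashed from (seed, group-offset index), so shrinking one group
  leaves the other group's subjects byte-identical.

What passing tests on this cohort do **not** show: robustness to
off-nominal sampling times (supported via a matching tolerance but not
simulated), non-lognormal assay error, infusion rather than bolus dosing,
or any relationship between azotaemia status and measurement quality.

## Numerical choices

* **AUC rule.** The default is linear-up/log-down: logarithmic trapezoids
  on strictly decreasing positive segments (exact for exponential decay),
  linear elsewhere. The plain linear rule is available via
  `auc_method = "linear"` and is kept as the exposed primitive
  `auc_trapezoid()` because its mathematical behaviour is easy to reason
  about (it over-covers any convex decay and converges from above). It is
  not the default because the schedule's 5→30 min gap spans a steep
  distribution phase where linear interpolation materially over-covers
  the curve, inflating the AUC and deflating clearance; the log-down rule
  removes that error at its source. The suite verifies that with the
  default rule the seven-point estimate recovers true clearance with a
  median error under 5% noise-free across the full GFR span (and under
  2% on a dense 200-point grid), which the linear rule does not achieve
  under these study conditions.
* **Tail-selection tie-break.** Equal adjusted $R^2$ prefers the shorter
  tail; with exact data all tails fit perfectly and the shortest (most
  terminal) wins, which is the intended limit.
* **Degenerate inputs.** Two equal macro rates cannot arise from strictly
  positive micro-parameters (the discriminant is bounded below by
  $(k_{10}-k_{21})^2 > 0$ whenever $k_{12} > 0$) but are rejected
  defensively. `cld_per_kg = 0` is accepted as the one-compartment limit.
  Profiles with fewer than two usable observations, all-rising tails, or
  non-positive reference GFRs in the accuracy functions raise immediate,
  named errors.
* **Problem sizes.** The test suite works at the study's own scale — a
  50-cat cohort for cohort-level properties, 200 single-cat seeds for the
  noisy recovery check, 60–100 seeds for coverage properties — which keeps
  the whole suite in the tens of seconds while leaving every statistic at
  a sample size where its behaviour is meaningful.

## Known limitations

* Clearance only: no mean residence time, no steady-state volume, no
  compartmental fitting of real data.
* The accuracy thresholds, the 25% extrapolation ceiling and the 141
  µmol/L cut-off are conventions of the protocol being reproduced, not
  tunable clinical guidance.
* Single-sample slope-intercept GFR methods are out of scope.
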