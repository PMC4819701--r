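---
title: "Stop-signal responder stratification: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stop-signal responder stratification: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopstrat)
```

stopstrat implements the analysis chain used to stratify patients with
Parkinson's disease into responders and nonresponders to noradrenergic
(atomoxetine) or serotonergic (citalopram) drugs on the basis of stopping
efficiency, together with a synthetic cohort generator that makes every
stage testable without patient data. This vignette explains the underlying
models, the estimators, the tunable parameters, and the design decisions
taken where the methodology left genuine choices open.

## The race model and the simulated task

On every trial of the stop-signal task a go stimulus (left/right arrow)
demands a speeded response; on a random quarter of trials a stop signal
follows after a stop-signal delay (SSD) and the response must be withheld.
The standard account is the independent horse-race model: a go process and
a stop process race, and the response is inhibited iff the stop process
finishes first.

`simulate_session()` implements one session of the design used throughout
the package: 360 go trials, 80 staircase-tracked stop trials and 40 NoGo
trials (stop trials with SSD fixed at 0 ms), randomly interleaved. Go
finishing times are ex-Gaussian, `Normal(mu, sigma) + Exp(tau)`, the
conventional positively skewed RT model; the stop latency is a constant
`ssrt_true_ms` per session. A constant stop process is the simplest model
under which the true SSRT is exactly defined, which is what makes the
estimator below testable by parameter recovery; real stop latencies are
themselves variable, so recovery results here are a best case.

Two lapse parameters make the go process realistic: `go_omission_rate`
(attentional lapses — on stop trials a lapse produces a "successful" stop
for the wrong reason, a small conservative bias that real data share) and
`go_error_rate` (wrong-side responses). Responses slower than the 1000 ms
response window count as omissions.

The SSD is tracked by a one-up-one-down staircase: +50 ms after a
successful stop, −50 ms after a failed one, clamped to [0, 900] ms. Step
size, start (250 ms) and bounds are not part of the published design and
follow field convention; all are exposed in `task_design()`. Any fixed-step
up/down staircase converges on the 50% success point, which the test suite
verifies empirically (mean stop success 0.50 ± 0.02 over 200 sessions).

## SSRT by the integration method

`estimate_ssrt()` estimates the stop-signal reaction time as

> SSRT = Q_p(go RT distribution) − mean SSD,

where p = P(respond | stop trial) over the staircase stop trials and Q_p is
the `ceiling(p * n_go)`-th order statistic (no interpolation — a
deterministic rule that brute-force rank arithmetic can check). Omitted go
trials are *adjusted for* by assigning them the maximum observed go RT
before taking the quantile; omissions otherwise deflate the quantile and
bias SSRT downward. The adjustment has the provable property that adding
omissions never decreases the estimate. Where the omission correction has
several published variants, the max-RT assignment was chosen for exact
testability; the alternative (rescaling p) produces nearly identical values
at the omission rates simulated here but has no closed-form order-statistic
oracle.

Two further conventions, both documented rather than asserted as the only
reading: wrong-side go responses keep their RT in the distribution used for
SSRT (the go process did finish) but are excluded from the reported mean go
RT; and NoGo trials never enter the SSRT, the staircase, or P(respond|stop).

Parameter recovery at the design's trial counts (360 go / 80 stop) gives a
mean bias of about −4 ms at a true SSRT of 200 ms (≈ 2%, within the 5%
band the tests enforce); the small negative bias is the footprint of go
lapses inflating apparent stop success.

## Deficit benchmarks and responder labels

Drug response is summarized per patient as ΔSSRT = SSRT(placebo) −
SSRT(drug), *improvement-positive*; every label in the package derives from
this single sign convention. A patient is a responder iff ΔSSRT strictly
exceeds a threshold equal to a fraction *b* of the group Parkinson's
deficit (mean patient placebo SSRT minus mean control SSRT), with b = 0.30
as the principal benchmark and 0.10–0.50 as the sweep range. Ties at the
threshold are nonresponders. A non-positive estimated deficit makes the
benchmark ill-posed and raises an error on the group scale.

The "individual scale" variant uses each patient's own deficit (their
placebo SSRT minus the control mean). This is an interpretation — the
per-patient benchmark is not fully specified in the source methodology —
and is flagged as such in `label_responders()`.

## The classifier stack

The responder classifier is a soft-margin SVM with the radial basis
function kernel K(x_i, x_j) = exp(−γ‖x_i − x_j‖²). The solver is LIBSVM
via e1071 (solver tolerance 1e-3, equal class weights); the package owns
everything around it:

- **Standardization.** Features are z-scored per feature *inside each
  cross-validation fold* from training rows only. The feature tables mix
  mg/day, years, unitless FA and diffusivity units, so standardization is
  mandatory for an RBF kernel; doing it per fold avoids test-set leakage,
  which the suite asserts with a canary feature equal to the label.
- **LOOCV.** Each subject is held out once; accuracy is the proportion of
  correct held-out predictions. A training fold reduced to a single class
  falls back to a constant majority predictor so degenerate folds remain
  defined.
- **Grid search.** Exhaustive evaluation over C, γ ∈ {2^−10, 2^−9.5, …,
  2^10} (41 × 41 pairs by default). Ties are broken toward the smallest C,
  then the smallest γ — determinism over elegance. Grid density is
  configurable; coarse grids (e.g. exponent step 2.5) are used inside
  selection loops and in routine tests, where the argmax is still verified
  against an independent brute-force re-evaluation.
- **Forward selection.** Greedy wrapper selection: each step grid-searches
  every remaining candidate joined to the selected set and admits the best;
  a *strict* accuracy increase is required to continue, and candidate ties
  go to the lowest column index. Whether the grid search should be re-run
  for every candidate set or once per step is ambiguous in wrapper-selection
  practice; the default here is the full grid per candidate set, reducible
  via `grid_spec()` when speed matters.
- **Permutation significance.** Labels are randomized (5000 times by
  default), the LOOCV accuracy recomputed, and p is the proportion of
  permuted accuracies *strictly* larger than the real one — so p = 0 is
  attainable and is displayed as "p < 1/n_perm". By default the selected
  features and (C, γ) are held fixed across permutations, the closest
  reading of recomputing "cross-validation accuracy" per randomization.
  This is anti-conservative: the real accuracy benefited from selection but
  the permuted ones do not. The stricter variant that re-runs selection
  inside every permutation is available (`reselect = TRUE`) and is the
  better choice when compute allows; with fixed features and parameters the
  test is correctly calibrated (empirical type-I rate ≈ 0.03–0.05 at
  α = 0.05 in the suite's 100-cohort null calibration).
- **Bonferroni.** Strict p < α/n_models across the models reported
  together.
- **ROC.** Sensitivity/specificity over all decision-value thresholds with
  trapezoid AUC, computed from the LOOCV decision values; cross-checked
  against pROC in the tests.
- **Benchmark sweep.** `benchmark_sweep()` re-optimizes a model at every
  benchmark fraction and, separately, stress-tests the principal-benchmark
  model (features and (C, γ) frozen) against every other fraction's labels.
  Fractions at which the labelling degenerates to a single class are
  reported as undefined rather than fatal.

## The synthetic cohort generator

`generate_cohort()` is the package's stand-in for the unavailable patient
cohort: 34 patients in a three-session placebo/atomoxetine/citalopram
crossover and 42 controls tested once, by default. It emulates:

- **Features.** Age, sex, UPDRS-III, MMSE and levodopa equivalent dose are
  drawn with the published cohort means/SDs (66.5 ± 7.0 y, 22.5 ± 7.8,
  28.6 ± 1.6, 913.7 ± 522.3 mg/day); plasma drug concentration, FA/MD of
  the anterior internal capsule and the eight ROI activation changes use
  plausible placeholder distributions, marked as such in the config.
  Features are emitted in natural units; covariance structure beyond
  means/SDs is not modelled.
- **The deficit.** Patients' placebo stop latency is shifted +30 ms above
  the control mean (configurable), the "Parkinson's deficit" the benchmarks
  are anchored to.
- **The responder signal.** True per-drug ΔSSRT is
  `link(intercept + Σ w_j z_j) + Normal(0, sd)`, with weights applied to
  *population-standardized* features so one number per feature sets its
  effect in ms per SD, and one `drug_effect_sd_ms` knob sets the
  signal-to-noise ratio. All-zero weights give a null cohort (response
  independent of features — the basis of the calibration tests); zero noise
  with a large weight gives near-perfect recoverability (the basis of the
  selection-recovery tests). The default intercept (9 ms) sits at the
  ground-truth threshold (0.30 × 30 ms) so labellings are near-balanced.
  One effect model is shared by both drugs with independent noise draws;
  per-drug mechanisms can be emulated by running per-drug configs.
- **Sessions.** Each subject-session receives race-model parameters (drug
  sessions inherit the placebo stop latency minus the subject's true drug
  effect, floored at 50 ms), and `simulate_cohort_sessions()` turns them
  into trial-level logs under deterministically derived child seeds.

What passing tests on this cohort do *not* show: real go/stop processes are
not exactly ex-Gaussian-plus-constant, real feature-outcome links are not
linear, and real features are correlated. The generator establishes that
the pipeline recovers what was planted under its own assumptions — a
necessary, not sufficient, condition for trusting it on real data.

## Numerical and reproducibility choices

- Quantiles by order statistic, no interpolation; strict inequalities at
  every decision boundary (responder threshold, permutation count,
  Bonferroni) so boundary cases are assertable.
- SVM solver tolerance 1e-3; constant feature columns standardize to zero
  rather than NaN inside folds.
- Every stochastic entry point takes an explicit seed. `run_pipeline()`
  fans one master seed into per-stage child seeds by a fixed integer rule,
  and its manifest records them; a rerun with the same config and seed is
  byte-identical.
- Problem sizes used by the test suite: 200 sessions for tracking and
  recovery checks, 20 cohorts of n = 34 for selection recovery, 100 null
  cohorts of n = 30 at 200 permutations for calibration, coarse
  (5–9-value) grids inside selection loops with the 41-value grid reserved
  for the density test and final fits.

## Known limitations

- LOOCV accuracy has high variance at n = 34, and with selection held
  fixed the permutation p-values inherit the optimism described above;
  treat default-mode p-values as the methodology's literal reading, not as
  the most conservative available.
- The integration method assumes a constant stop latency; its omission
  adjustment is one of several published variants.
- The generator's independence assumptions make planted-feature recovery
  easier than in correlated real data.
- The mean-shift deficit plus strict-threshold labelling ignores
  measurement error in the deficit itself; near-threshold patients flip
  labels under estimation noise, which bounds achievable label agreement
  with ground truth at realistic trial counts.
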