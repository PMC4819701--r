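# stopstrat

Stop-signal task simulation and drug-responder stratification for
Parkinson's disease pharmacology.

Noradrenergic (atomoxetine) and serotonergic (citalopram) reuptake
inhibitors improve response inhibition in *some* patients with Parkinson's
disease; unstratified trials average responders with nonresponders and risk
false negatives. stopstrat implements the full analysis chain needed to
study and stress-test responder stratification on stopping efficiency, for
methodologists and trialists who want a tested, reproducible reference
implementation:

- **Task simulation** — the stop-signal task (360 go / 80 stop / 40 NoGo
  trials) under the independent horse-race model, with a one-up-one-down
  staircase tracking the stop-signal delay (SSD) to 50% successful
  inhibition.
- **SSRT estimation** — the integration method with omission adjustment:
  `SSRT = Q_p(go RT) − mean SSD`, where p = P(respond | stop) and Q_p is
  the `⌈p·n⌉`-th order statistic of the go-RT distribution with omitted
  trials assigned the maximum RT.
- **Responder labelling** — ΔSSRT = SSRT(placebo) − SSRT(drug); a patient
  is a responder iff ΔSSRT strictly exceeds a fraction *b* (principal
  b = 0.30, sweeps 0.10–0.50) of the group Parkinson's deficit in SSRT.
- **Classification** — soft-margin SVM with RBF kernel
  K(x_i, x_j) = exp(−γ‖x_i − x_j‖²), leave-one-out cross-validation with
  per-fold standardization, exhaustive (C, γ) grid search over
  2^−10 … 2^10, greedy forward feature selection, permutation significance
  (strict ">", Bonferroni over models), ROC curves and
  benchmark-robustness sweeps.
- **Synthetic cohorts** — a generator that plants a configurable responder
  signal (chosen features, effect sizes in ms/SD, noise) in a
  34-patient / 42-control crossover cohort, so every downstream stage is
  testable by parameter recovery without any patient data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()` plots.

## Worked example

```r
library(stopstrat)

run <- run_pipeline(out_dir = "stopstrat_out", seed = 42)
#> [stopstrat] stage 1/5: generating cohort (34 patients, 42 controls)
#> [stopstrat] stage 2/5: simulating 144 stop-signal sessions
#> ...
run$report_table
#> # A tibble: 4 × 11
#>   model_type  drug        optimal_features              C  gamma accuracy_pct
#>   <chr>       <chr>       <chr>                     <dbl>  <dbl>        <dbl>
#> 1 clinical    atomoxetine plasma_conc, LED, MD_R       1  1              88.2
#> 2 mechanistic atomoxetine act_RIFG_L, act_caudate_R  181. 0.0312         76.5
#> 3 clinical    citalopram  MD_L, plasma_conc            1  5.66           82.4
#> 4 mechanistic citalopram  act_preSMA_R              1024  1              79.4
#> # plus permutation_p, n_permutations, significant, p_display,
#> # planted_features_selected
run$deficit_ms
#> [1] 20.2266
```

Reading the output: the estimated group deficit (patients' placebo SSRT
minus controls', here ≈ 20 ms versus the planted 30 ms — n = 34/42 leaves
visible sampling noise) anchors the
responder threshold at 0.30 × deficit. For each drug × model type the
table reports the greedily selected features, the grid-optimal (C, γ), the
LOOCV accuracy on the synthetic cohort's estimated labels, and the
permutation p-value (with the Bonferroni decision across the models in the
table). `planted_features_selected` shows which of the generator's truly
informative features the selector recovered — the diagnostic that matters
on synthetic data.

Individual stages compose with the pipe:

```r
log <- simulate_session(task_design(), race_params(ssrt_true_ms = 220), seed = 1)
estimate_ssrt(log)
#> # A tibble: 1 × 7
#>   ssrt_ms p_respond_stop mean_ssd_ms  n_go n_go_omitted n_stop flagged
#>     <dbl>          <dbl>       <dbl> <int>        <int>  <int> <lgl>
#> 1    248.          0.512        209.   360            7     80 FALSE
```

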