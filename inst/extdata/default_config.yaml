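# Default stopstrat pipeline configuration.
# Values without a published source are plausible placeholders and are
# marked as such; everything here can be overridden per run.
cohort:
  n_patients: 34
  n_controls: 42
  drug_labels: [placebo, atomoxetine, citalopram]
  deficit_ms: 30            # mean patient-placebo vs control shift in true SSRT
  control_ssrt_mean_ms: 200
  ssrt_sd_ms: 25            # between-subject SD of true SSRT (placeholder)
  # planted responder signal: ms of true delta-SSRT per population SD
  effect_weights:
    MD_L: 12
    LED: -10
    FA_R: -12
    act_caudate_R: 12
    act_caudate_L: 10
    act_preSMA_R: 10
  effect_intercept: 9
  effect_sd_ms: 8
task:
  n_go: 360
  n_stop: 80
  n_nogo: 40
  ssd_initial_ms: 250       # staircase start (convention, not a published value)
  ssd_step_ms: 50           # staircase step (convention)
  ssd_min_ms: 0
  ssd_max_ms: 900
  response_window_ms: 1000
benchmark:
  fraction: 0.30            # principal benchmark: 30% of the group deficit
classify:
  drugs: [atomoxetine, citalopram]
  model_types: [clinical, mechanistic]
  n_perm: 200               # raise to 5000 for publication-grade significance
  grid:                     # coarse default for pipeline runs; grid_spec()
    exponent_min: -10       # with exponent_step 0.5 gives the full 41x41 grid
    exponent_max: 10
    exponent_step: 2.5
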