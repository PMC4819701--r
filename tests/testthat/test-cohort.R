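test_that("cohort generation honors sizes, sessions and determinism", {
  cfg <- cohort_config(n_patients = 34, n_controls = 42, seed = 1)
  cohort <- generate_cohort(cfg)
  expect_equal(sum(cohort$subjects$role == "patient"), 34)
  expect_equal(sum(cohort$subjects$role == "control"), 42)
  # patients: one session per drug label; controls: exactly one
  pat_sessions <- cohort$sessions[cohort$sessions$role == "patient", ]
  expect_equal(nrow(pat_sessions), 34 * 3)
  expect_setequal(unique(pat_sessions$session_id),
                  c("placebo", "atomoxetine", "citalopram"))
  ctl_sessions <- cohort$sessions[cohort$sessions$role == "control", ]
  expect_equal(nrow(ctl_sessions), 42)

  again <- generate_cohort(cfg)
  expect_identical(cohort$subjects, again$subjects)
  expect_identical(cohort$sessions, again$sessions)
  expect_identical(cohort$ground_truth, again$ground_truth)
})

test_that("the placebo stop-latency deficit is planted at the configured size", {
  devs <- vapply(1:40, function(s) {
    cohort <- generate_cohort(cohort_config(n_patients = 20, n_controls = 20,
                                            seed = s))
    ses <- cohort$sessions
    mean(ses$ssrt_true_ms[ses$session_id == "placebo"]) -
      mean(ses$ssrt_true_ms[ses$session_id == "control"])
  }, numeric(1))
  expect_lt(abs(mean(devs) - 30), 2 * sd(devs) / sqrt(length(devs)) + 1)
})

test_that("a null effect model yields a feature-independent constant response", {
  cfg <- cohort_config(
    n_patients = 8, n_controls = 4, seed = 3,
    effect_model = effect_model(weights = numeric(0), intercept = 7,
                                drug_effect_sd_ms = 0),
    feature_spec = feature_spec_default(informative = character(0))
  )
  cohort <- generate_cohort(cfg)
  expect_true(all(cohort$ground_truth$true_delta_ssrt_ms == 7))
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(drug_labels = c("atomoxetine", "citalopram")),
               "drug_labels")
  expect_error(cohort_config(drug_labels = c("placebo", "placebo", "x")),
               "drug_labels")
  spec <- feature_spec_default()
  spec$population_sd[1] <- 0
  expect_error(cohort_config(feature_spec = spec), "population_sd")
  expect_error(
    cohort_config(effect_model = effect_model(weights = c(bogus = 1))),
    "bogus")
})

test_that("feature tables carry the requested groups only, one row per patient", {
  cohort <- generate_cohort(cohort_config(n_patients = 7, n_controls = 4,
                                          seed = 5))
  clin <- build_feature_table(cohort, "atomoxetine",
                              c("clinical", "diffusion"))
  expect_equal(nrow(clin), 7)
  expect_setequal(names(clin),
                  c("subject_id", "age", "sex", "UPDRS_III", "MMSE", "LED",
                    "plasma_conc", "FA_L", "FA_R", "MD_L", "MD_R"))
  act <- build_feature_table(cohort, "citalopram", "activation")
  expect_equal(ncol(act) - 1L, 8)  # 2 hemispheres x 4 ROIs
  expect_true(all(startsWith(setdiff(names(act), "subject_id"), "act_")))
  expect_error(build_feature_table(cohort, "atomoxetine", character(0)),
               "at least one")
  expect_error(build_feature_table(cohort, "atomoxetine", "genetics"),
               "valid groups")
  expect_error(build_feature_table(cohort, "placebo"), "drug session")
})

test_that("activation features equal drug-minus-placebo session activations", {
  cohort <- generate_cohort(cohort_config(n_patients = 5, n_controls = 4,
                                          seed = 6))
  act <- build_feature_table(cohort, "atomoxetine", "activation")
  ses <- cohort$sessions
  drug <- ses[ses$session_id == "atomoxetine", ]
  plac <- ses[ses$session_id == "placebo", ]
  i <- match(act$subject_id, drug$subject_id)
  j <- match(act$subject_id, plac$subject_id)
  expect_equal(act$act_caudate_R,
               drug$act_caudate_R[i] - plac$act_caudate_R[j])
})

test_that("null cohorts give chance-level downstream classification", {
  accs <- vapply(1:60, function(s) {
    cohort <- generate_cohort(cohort_config(
      n_patients = 16, n_controls = 4, seed = 700 + s,
      # intercept at the ground-truth threshold (0.3 x 30 ms) makes the null
      # labelling balanced on average
      effect_model = effect_model(weights = numeric(0), intercept = 9,
                                  drug_effect_sd_ms = 10),
      feature_spec = feature_spec_default(informative = character(0))
    ))
    truth <- cohort$ground_truth
    y <- truth$true_responder[truth$drug == "atomoxetine"]
    if (length(unique(y)) < 2) return(NA_real_)
    feats <- build_feature_table(cohort, "atomoxetine",
                                 c("clinical", "diffusion"))
    loocv_accuracy(feats, y, C = 1, gamma = 0.1)
  }, numeric(1))
  # chance for a balanced null labelling is 0.5; allow Monte-Carlo slack
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.08)
})
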