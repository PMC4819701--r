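#' Default feature specification for the synthetic cohort
#'
#' One row per subject-level feature: demographic/clinical measures,
#' diffusion metrics of the left/right anterior internal capsule and
#' drug-induced activation changes in the four stop-network ROIs (right
#' inferior frontal gyrus, pre-SMA, caudate, putamen; both hemispheres).
#' Means and SDs of age, MMSE, UPDRS-III and levodopa equivalent dose follow
#' published Parkinson's cohort values; the remaining rows are plausible
#' placeholders (see the feature table vignette section).  All features are
#' emitted in natural units (years, mg/day, ng/mL, unitless FA, MD in
#' 10^-3 mm^2/s, activation change in parameter-estimate units);
#' standardization is the classifier's job, not the generator's.
#'
#' @param informative Character vector of feature names that carry the
#'   responder signal (must match the effect-model weights).
#' @return A tibble `name`, `group`, `population_mean`, `population_sd`,
#'   `type`, `informative`.
#' @export
feature_spec_default <- function(informative = names(effect_model_default()$weights)) {
  spec <- tibble::tribble(
    ~name,            ~group,       ~population_mean, ~population_sd, ~type,
    "age",            "clinical",   66.5,             7.0,            "continuous",
    "sex",            "clinical",   0.62,             0.49,           "binary",
    "UPDRS_III",      "clinical",   22.5,             7.8,            "continuous",
    "MMSE",           "clinical",   28.6,             1.6,            "continuous",
    "LED",            "clinical",   913.7,            522.3,          "continuous",
    "plasma_conc",    "clinical",   400,              200,            "continuous",
    "FA_L",           "diffusion",  0.45,             0.04,           "continuous",
    "FA_R",           "diffusion",  0.45,             0.04,           "continuous",
    "MD_L",           "diffusion",  0.75,             0.05,           "continuous",
    "MD_R",           "diffusion",  0.75,             0.05,           "continuous",
    "act_RIFG_L",     "activation", 0.2,              0.5,            "continuous",
    "act_RIFG_R",     "activation", 0.2,              0.5,            "continuous",
    "act_preSMA_L",   "activation", 0.2,              0.5,            "continuous",
    "act_preSMA_R",   "activation", 0.2,              0.5,            "continuous",
    "act_caudate_L",  "activation", 0.2,              0.5,            "continuous",
    "act_caudate_R",  "activation", 0.2,              0.5,            "continuous",
    "act_putamen_L",  "activation", 0.2,              0.5,            "continuous",
    "act_putamen_R",  "activation", 0.2,              0.5,            "continuous"
  )
  dplyr::mutate(spec, informative = .data$name %in% informative)
}

#' Effect model: how features generate the true drug response
#'
#' The true per-drug change in SSRT for each patient is
#' `link(intercept + sum_j weights[j] * z_j) + Normal(0, drug_effect_sd_ms)`,
#' where `z_j` is feature j standardized by its population mean/SD from the
#' feature spec (so weights read as "ms of true delta-SSRT per population
#' SD") and `link` is the identity by default.  Setting all weights to zero
#' yields a null cohort whose response is independent of every feature;
#' setting `drug_effect_sd_ms = 0` makes the mapping noiseless.
#'
#' @param weights Named numeric vector; names must be informative features.
#' @param intercept Baseline true delta-SSRT in ms.
#' @param drug_effect_sd_ms SD of the per-drug Gaussian response noise (ms).
#' @param link Function mapping the linear predictor to ms of delta-SSRT.
#' @return An `effect_model` object.
#' @export
effect_model <- function(weights, intercept = 9, drug_effect_sd_ms = 8,
                         link = identity) {
  if (length(weights) > 0 &&
      (is.null(names(weights)) || any(!nzchar(names(weights))))) {
    stop_config("`weights` must be a named numeric vector", field = "weights")
  }
  check_number(drug_effect_sd_ms, "drug_effect_sd_ms", min = 0)
  structure(list(weights = weights, intercept = intercept,
                 drug_effect_sd_ms = drug_effect_sd_ms, link = link),
            class = "effect_model")
}

#' @rdname effect_model
#' @export
effect_model_default <- function() {
  effect_model(
    weights = c(MD_L = 12, LED = -10, FA_R = -12,
                act_caudate_R = 12, act_caudate_L = 10, act_preSMA_R = 10),
    intercept = 9, drug_effect_sd_ms = 8
  )
}

#' Configuration of a synthetic patient/control cohort
#'
#' Defaults reflect the study conditions the generator emulates: 34 patients
#' with Parkinson's disease in a three-way placebo/atomoxetine/citalopram
#' crossover and 42 controls tested once without drug, with a +30 ms mean
#' shift ("Parkinson's deficit") in patients' placebo stop latency.
#'
#' @param n_patients,n_controls Cohort sizes (each >= 2).
#' @param seed Integer seed; identical (config, seed) pairs reproduce the
#'   cohort exactly.
#' @param drug_labels Session identifiers; must contain "placebo" exactly
#'   once.
#' @param feature_spec Tibble from [feature_spec_default()].
#' @param effect_model An [effect_model()].
#' @param deficit_ms Mean shift of patients' placebo true SSRT vs. controls.
#' @param control_ssrt_mean_ms,ssrt_sd_ms Control mean and between-subject SD
#'   of the true stop latency (ms).
#' @param go_mu_patient_ms,go_mu_control_ms Mean ex-Gaussian mu of the go
#'   process (patients respond more slowly).
#' @param benchmark_fraction Fraction of the deficit used for the
#'   ground-truth responder labels.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 34, n_controls = 42, seed = 1,
                          drug_labels = c("placebo", "atomoxetine", "citalopram"),
                          feature_spec = feature_spec_default(),
                          effect_model = effect_model_default(),
                          deficit_ms = 30, control_ssrt_mean_ms = 200,
                          ssrt_sd_ms = 25, go_mu_patient_ms = 450,
                          go_mu_control_ms = 420, benchmark_fraction = 0.30) {
  check_number(n_patients, "n_patients", min = 2)
  check_number(n_controls, "n_controls", min = 2)
  if (sum(drug_labels == "placebo") != 1) {
    stop_config("`drug_labels` must contain \"placebo\" exactly once",
                field = "drug_labels")
  }
  if (anyDuplicated(feature_spec$name)) {
    stop_config("feature names must be unique", field = "feature_spec")
  }
  if (any(feature_spec$population_sd <= 0)) {
    stop_config("every `population_sd` must be > 0", field = "feature_spec")
  }
  bad <- setdiff(names(effect_model$weights),
                 feature_spec$name[feature_spec$informative])
  if (length(bad) > 0) {
    stop_config(paste0("effect-model weight(s) on non-informative feature(s): ",
                       paste(bad, collapse = ", ")), field = "effect_model")
  }
  check_number(deficit_ms, "deficit_ms")
  check_number(benchmark_fraction, "benchmark_fraction", min = 0, max = 1,
               strict_min = TRUE)
  structure(
    list(n_patients = as.integer(n_patients),
         n_controls = as.integer(n_controls), seed = as.integer(seed),
         drug_labels = drug_labels, feature_spec = feature_spec,
         effect_model = effect_model, deficit_ms = deficit_ms,
         control_ssrt_mean_ms = control_ssrt_mean_ms, ssrt_sd_ms = ssrt_sd_ms,
         go_mu_patient_ms = go_mu_patient_ms,
         go_mu_control_ms = go_mu_control_ms,
         benchmark_fraction = benchmark_fraction),
    class = "cohort_config"
  )
}

draw_feature <- function(n, mean, sd, type) {
  if (type == "binary") {
    as.numeric(runif(n) < mean)
  } else {
    rnorm(n, mean, sd)
  }
}

#' Generate a synthetic cohort
#'
#' Draws every feature for every subject from the feature spec, assigns each
#' patient one race-model parameter set per session (placebo and each drug)
#' and each control a single no-drug session, and records the ground truth:
#' each patient's true per-drug change in SSRT (from the effect model) and
#' the true responder label at the configured benchmark fraction of the
#' configured deficit.
#'
#' Patients' placebo true SSRT is the control mean plus the configured
#' deficit plus subject noise; a drug session's true SSRT is the placebo
#' value minus that drug's true delta (floored at 50 ms).  Activation
#' features are generated as drug-minus-placebo change scores on top of a
#' per-subject placebo baseline, so the per-session activation table carries
#' both.  `plasma_conc` is drawn per patient and drug (zero under placebo).
#'
#' @param config A [cohort_config()].
#' @return An `ssrt_cohort` list: `subjects` (subject-level features),
#'   `sessions` (one row per subject-session: race-model parameters, plasma
#'   concentration, per-session activation), `ground_truth` (`subject_id`,
#'   `drug`, `true_delta_ssrt_ms`, `true_responder`), and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4, n_controls = 4))
#' cohort$ground_truth
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    stop_config("`config` must be built by cohort_config()", field = "config")
  }
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  spec <- config$feature_spec
  drugs <- setdiff(config$drug_labels, "placebo")
  n_pat <- config$n_patients
  n_ctl <- config$n_controls
  ids_pat <- sprintf("pd%02d", seq_len(n_pat))
  ids_ctl <- sprintf("hc%02d", seq_len(n_ctl))

  subject_level <- spec[spec$group != "activation" & spec$name != "plasma_conc", ]
  subjects <- tibble(
    subject_id = c(ids_pat, ids_ctl),
    role = rep(c("patient", "control"), c(n_pat, n_ctl))
  )
  for (j in seq_len(nrow(subject_level))) {
    s <- subject_level[j, ]
    subjects[[s$name]] <- draw_feature(nrow(subjects), s$population_mean,
                                       s$population_sd, s$type)
  }

  act_spec <- spec[spec$group == "activation", ]
  plasma_spec <- spec[spec$name == "plasma_conc", ]

  # per-session activation = per-subject placebo baseline + per-drug change
  act_baseline <- matrix(rnorm(n_pat * nrow(act_spec), 1, 0.5),
                         nrow = n_pat,
                         dimnames = list(ids_pat, act_spec$name))
  act_change <- lapply(drugs, function(d) {
    m <- vapply(seq_len(nrow(act_spec)), function(j) {
      rnorm(n_pat, act_spec$population_mean[j], act_spec$population_sd[j])
    }, numeric(n_pat))
    if (n_pat == 1) m <- matrix(m, nrow = 1)
    dimnames(m) <- list(ids_pat, act_spec$name)
    m
  })
  names(act_change) <- drugs

  plasma <- lapply(drugs, function(d) {
    if (nrow(plasma_spec) == 1) {
      pmax(rnorm(n_pat, plasma_spec$population_mean, plasma_spec$population_sd), 0)
    } else {
      rep(NA_real_, n_pat)
    }
  })
  names(plasma) <- drugs

  # true delta-SSRT per drug from the effect model on standardized features
  em <- config$effect_model
  z_of <- function(name, drug) {
    row <- spec[spec$name == name, ]
    x <- if (row$group == "activation") {
      act_change[[drug]][, name]
    } else if (name == "plasma_conc") {
      plasma[[drug]]
    } else {
      subjects[[name]][seq_len(n_pat)]
    }
    (x - row$population_mean) / row$population_sd
  }
  true_delta <- purrr::map_dfr(drugs, function(d) {
    lp <- rep(em$intercept, n_pat)
    for (w in names(em$weights)) {
      lp <- lp + em$weights[[w]] * z_of(w, d)
    }
    tibble(subject_id = ids_pat, drug = d,
           true_delta_ssrt_ms = em$link(lp) +
             rnorm(n_pat, 0, em$drug_effect_sd_ms))
  })
  true_threshold <- config$benchmark_fraction * config$deficit_ms
  ground_truth <- dplyr::mutate(
    true_delta, true_responder = .data$true_delta_ssrt_ms > true_threshold)

  # race-model parameters per subject-session
  placebo_ssrt <- config$control_ssrt_mean_ms + config$deficit_ms +
    rnorm(n_pat, 0, config$ssrt_sd_ms)
  control_ssrt <- config$control_ssrt_mean_ms +
    rnorm(n_ctl, 0, config$ssrt_sd_ms)
  go_mu_pat <- rnorm(n_pat, config$go_mu_patient_ms, 30)
  go_mu_ctl <- rnorm(n_ctl, config$go_mu_control_ms, 30)
  go_sigma <- pmax(rnorm(n_pat + n_ctl, 50, 10), 10)
  go_tau <- pmax(rnorm(n_pat + n_ctl, 60, 15), 5)

  pat_sessions <- purrr::map_dfr(config$drug_labels, function(s) {
    delta <- if (s == "placebo") 0 else {
      ground_truth$true_delta_ssrt_ms[ground_truth$drug == s]
    }
    out <- tibble(
      subject_id = ids_pat, session_id = s, role = "patient",
      go_mu_ms = go_mu_pat, go_sigma_ms = go_sigma[seq_len(n_pat)],
      go_tau_ms = go_tau[seq_len(n_pat)],
      ssrt_true_ms = pmax(placebo_ssrt - delta, 50),
      go_omission_rate = 0.02, go_error_rate = 0.03,
      plasma_conc = if (s == "placebo") 0 else plasma[[s]]
    )
    act <- if (s == "placebo") act_baseline else act_baseline + act_change[[s]]
    dplyr::bind_cols(out, as_tibble(act))
  })
  ctl_sessions <- tibble(
    subject_id = ids_ctl, session_id = "control", role = "control",
    go_mu_ms = go_mu_ctl, go_sigma_ms = go_sigma[n_pat + seq_len(n_ctl)],
    go_tau_ms = go_tau[n_pat + seq_len(n_ctl)],
    ssrt_true_ms = pmax(control_ssrt, 50),
    go_omission_rate = 0.02, go_error_rate = 0.03, plasma_conc = 0
  )
  sessions <- dplyr::bind_rows(pat_sessions, ctl_sessions)

  structure(
    list(subjects = subjects, sessions = sessions,
         ground_truth = ground_truth, config = config),
    class = "ssrt_cohort"
  )
}

#' Build a subjects-by-features table for one drug-versus-placebo contrast
#'
#' Restricts the cohort's features to the requested groups.  `clinical`
#' yields age, sex, UPDRS-III, MMSE, levodopa equivalent dose and the drug's
#' plasma concentration; `diffusion` yields FA/MD of the left and right
#' anterior internal capsule; `activation` yields the eight ROI
#' drug-minus-placebo activation changes.
#'
#' @param cohort An `ssrt_cohort` from [generate_cohort()].
#' @param drug A non-placebo session identifier.
#' @param groups Subset of `c("clinical", "diffusion", "activation")`.
#' @return A tibble with one row per patient: `subject_id` plus the
#'   requested feature columns.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4, n_controls = 4))
#' build_feature_table(cohort, "atomoxetine", c("clinical", "diffusion"))
#' @export
build_feature_table <- function(cohort, drug,
                                groups = c("clinical", "diffusion")) {
  valid <- c("clinical", "diffusion", "activation")
  if (length(groups) == 0) {
    abort(paste0("at least one feature group is required; valid groups: ",
                 paste(valid, collapse = ", ")))
  }
  unknown <- setdiff(groups, valid)
  if (length(unknown) > 0) {
    abort(paste0("unknown feature group(s): ", paste(unknown, collapse = ", "),
                 "; valid groups: ", paste(valid, collapse = ", ")))
  }
  if (!drug %in% setdiff(cohort$config$drug_labels, "placebo")) {
    abort(sprintf("'%s' is not a drug session of this cohort", drug))
  }
  spec <- cohort$config$feature_spec
  patients <- cohort$subjects[cohort$subjects$role == "patient", ]
  out <- patients["subject_id"]

  if ("clinical" %in% groups) {
    clin <- spec$name[spec$group == "clinical" & spec$name != "plasma_conc"]
    out <- dplyr::bind_cols(out, patients[clin])
    drug_rows <- cohort$sessions[cohort$sessions$session_id == drug, ]
    out$plasma_conc <- drug_rows$plasma_conc[match(out$subject_id,
                                                   drug_rows$subject_id)]
  }
  if ("diffusion" %in% groups) {
    diff_names <- spec$name[spec$group == "diffusion"]
    out <- dplyr::bind_cols(out, patients[diff_names])
  }
  if ("activation" %in% groups) {
    act_names <- spec$name[spec$group == "activation"]
    ses <- cohort$sessions
    drug_rows <- ses[ses$session_id == drug, c("subject_id", act_names)]
    plac_rows <- ses[ses$session_id == "placebo", c("subject_id", act_names)]
    i <- match(out$subject_id, drug_rows$subject_id)
    j <- match(out$subject_id, plac_rows$subject_id)
    chg <- as.matrix(drug_rows[i, act_names]) - as.matrix(plac_rows[j, act_names])
    out <- dplyr::bind_cols(out, as_tibble(chg))
  }
  out
}

#' Simulate stop-signal sessions for every subject-session of a cohort
#'
#' Each subject-session gets its own child seed derived deterministically
#' from `seed`, so a cohort's full set of trial logs is reproducible from
#' one integer.
#'
#' @param cohort An `ssrt_cohort`.
#' @param design A [task_design()].
#' @param seed Integer master seed.
#' @return A tibble of trials with `subject_id` and `session_id` columns
#'   (input to [summarize_sessions()]).
#' @export
simulate_cohort_sessions <- function(cohort, design = task_design(), seed = 1) {
  ses <- cohort$sessions
  purrr::map_dfr(seq_len(nrow(ses)), function(i) {
    row <- ses[i, ]
    params <- race_params(
      go_mu_ms = row$go_mu_ms, go_sigma_ms = row$go_sigma_ms,
      go_tau_ms = row$go_tau_ms, ssrt_true_ms = row$ssrt_true_ms,
      go_omission_rate = row$go_omission_rate,
      go_error_rate = row$go_error_rate
    )
    log <- simulate_session(design, params, seed = child_seed(seed, i),
                            subject_id = row$subject_id,
                            session_id = row$session_id)
    dplyr::mutate(as_tibble(log), subject_id = row$subject_id,
                  session_id = row$session_id, .before = 1)
  })
}
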