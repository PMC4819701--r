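#' Run the full stratification pipeline
#'
#' Orchestrates one end-to-end analysis: generate a synthetic cohort,
#' simulate every stop-signal session, summarize behavior (SSRT, go RT, go
#' errors), estimate the group Parkinson's deficit, label responders at the
#' benchmark fraction, then for every requested drug x model type select
#' features and hyperparameters, test significance by permutation, compute
#' the LOOCV ROC, and write all tables plus a reproducibility manifest under
#' `out_dir`.
#'
#' One master `seed` fans out deterministically into per-stage child seeds
#' (cohort, sessions, permutations), so a rerun with the same config and
#' seed reproduces every output byte for byte.
#'
#' @param config A list as produced by [read_pipeline_config()], or a path
#'   to a YAML config file, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @return A `run_manifest` list (invisibly written to
#'   `manifest.json`): config snapshot, seeds, package version, per-stage
#'   row counts, output file names, and the model reports.
#' @examples
#' \donttest{
#' cfg <- read_pipeline_config()
#' cfg$cohort$n_patients <- 12; cfg$cohort$n_controls <- 12
#' cfg$classify$n_perm <- 50
#' run <- run_pipeline(cfg, out_dir = tempfile(), seed = 7)
#' run$reports
#' }
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else
    config %||% read_pipeline_config()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[stopstrat] ", sprintf(...))

  drugs <- cfg$classify$drugs
  known <- setdiff(cfg$cohort$drug_labels, "placebo")
  if (length(setdiff(drugs, known)) > 0) {
    stop_config(paste0("unknown drug(s) requested: ",
                       paste(setdiff(drugs, known), collapse = ", ")),
                field = "classify$drugs")
  }

  log_stage("stage 1/5: generating cohort (%d patients, %d controls)",
            cfg$cohort$n_patients, cfg$cohort$n_controls)
  cohort <- generate_cohort(config_to_cohort(cfg, seed = child_seed(seed, 1)))

  log_stage("stage 2/5: simulating %d stop-signal sessions",
            nrow(cohort$sessions))
  design <- do.call(task_design, cfg$task)
  trials <- simulate_cohort_sessions(cohort, design, seed = child_seed(seed, 2))

  log_stage("stage 3/5: summarizing sessions")
  summaries <- summarize_sessions(trials)

  pd_placebo <- summaries[summaries$session_id == "placebo", ]
  controls <- summaries[summaries$session_id == "control", ]
  deficit <- group_deficit(pd_placebo$ssrt_ms, controls$ssrt_ms)
  log_stage("stage 4/5: group deficit %.1f ms; labelling at fraction %.2f",
            deficit, cfg$benchmark$fraction)

  grid <- do.call(grid_spec, cfg$classify$grid)
  labels_out <- list()
  reports <- list()
  rocs <- list()
  for (drug in drugs) {
    deltas <- compute_deltas(summaries, drug)
    labels <- label_responders(deltas, deficit = deficit,
                               fraction = cfg$benchmark$fraction)
    labels_out[[drug]] <- labels
    for (mt in cfg$classify$model_types) {
      groups <- model_type_groups(mt)
      feats <- build_feature_table(cohort, drug, groups)
      log_stage("stage 5/5: %s %s model (%d features)", drug, mt,
                ncol(feats) - 1L)
      model <- forward_select(feats, labels$responder, grid = grid,
                              drug = drug, model_type = mt)
      pt <- permutation_test(model, n_perm = cfg$classify$n_perm,
                             seed = child_seed(seed, 100 + length(reports)))
      model <- pt$model
      preds <- loocv_predictions(feats, labels$responder, C = model$C,
                                 gamma = model$gamma,
                                 feature_subset = model$selected_features)
      reports[[paste(drug, mt, sep = "_")]] <- model
      rocs[[paste(drug, mt, sep = "_")]] <-
        roc_curve(preds$decision_value, preds$truth)
    }
  }

  files <- c(trials = "trials.tsv", summaries = "summaries.tsv",
             labels = "labels.tsv", reports = "model_reports.tsv",
             subjects = "subjects.tsv", ground_truth = "ground_truth.tsv",
             manifest = "manifest.json")
  readr::write_tsv(trials, file.path(out_dir, files["trials"]))
  readr::write_tsv(summaries, file.path(out_dir, files["summaries"]))
  readr::write_tsv(dplyr::bind_rows(labels_out), file.path(out_dir, files["labels"]))
  readr::write_tsv(cohort$subjects, file.path(out_dir, files["subjects"]))
  readr::write_tsv(cohort$ground_truth, file.path(out_dir, files["ground_truth"]))
  feature_files <- character(0)
  for (drug in drugs) {
    f <- sprintf("features_%s.tsv", drug)
    groups <- unique(unlist(lapply(cfg$classify$model_types,
                                   model_type_groups)))
    readr::write_tsv(build_feature_table(cohort, drug, groups),
                     file.path(out_dir, f))
    feature_files <- c(feature_files, f)
  }
  spec <- cohort$config$feature_spec
  report_tbl <- report_models(reports, ground_truth = cohort$ground_truth,
                              informative = spec$name[spec$informative])
  readr::write_tsv(report_tbl, file.path(out_dir, files["reports"]))
  for (nm in names(reports)) {
    writeLines(model_report_text(reports[[nm]], rocs[[nm]]),
               file.path(out_dir, paste0("model_", nm, ".txt")))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("stopstrat")),
    seed = seed,
    child_seeds = list(cohort = child_seed(seed, 1),
                       sessions = child_seed(seed, 2)),
    config = cfg,
    row_counts = list(subjects = nrow(cohort$subjects),
                      sessions = nrow(cohort$sessions),
                      trials = nrow(trials), summaries = nrow(summaries)),
    deficit_ms = deficit,
    outputs = c(as.list(files),
                list(features = feature_files,
                     model_text = paste0("model_", names(reports), ".txt")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, files["manifest"]),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(structure(
    list(manifest = manifest, cohort = cohort, summaries = summaries,
         labels = labels_out, reports = reports, rocs = rocs,
         report_table = report_tbl, deficit_ms = deficit, out_dir = out_dir),
    class = "stopstrat_run"
  ))
}

model_type_groups <- function(model_type) {
  switch(model_type,
         clinical = c("clinical", "diffusion"),
         mechanistic = "activation",
         mixed = c("clinical", "diffusion", "activation"),
         abort(sprintf("unknown model type '%s' (use clinical, mechanistic or mixed)",
                       model_type)))
}

#' Tabular summary of fitted responder models
#'
#' One row per model with its type, drug, selected features, `(C, gamma)`,
#' LOOCV accuracy and Bonferroni-corrected permutation significance
#' (corrected over the number of models in the table).  When a cohort
#' ground truth is supplied, recovery diagnostics are appended: which
#' selected features were planted as informative, and the agreement between
#' estimated and true responder labels is left to the caller's labels table.
#'
#' @param reports A list of `responder_model` objects (with permutation
#'   p-values filled in by [permutation_test()]).
#' @param ground_truth Optional `ground_truth` tibble of an `ssrt_cohort`.
#' @param informative Optional character vector of planted informative
#'   features (defaults to none; supplied by [run_pipeline()] via the
#'   cohort config).
#' @return A tibble mirroring the usual optimal-model table layout.
#' @export
report_models <- function(reports, ground_truth = NULL, informative = NULL) {
  if (length(reports) == 0) abort("at least one model report is required")
  tbl <- purrr::map_dfr(reports, function(m) {
    tibble(
      model_type = m$model_type, drug = m$drug,
      optimal_features = paste(m$selected_features, collapse = ", "),
      C = m$C, gamma = m$gamma,
      accuracy_pct = 100 * m$cv_accuracy,
      permutation_p = m$permutation_p %||% NA_real_,
      n_permutations = m$n_permutations %||% NA_integer_
    )
  })
  corr <- bonferroni(tbl$permutation_p, n_models = nrow(tbl))
  tbl$significant <- corr$significant
  tbl$p_display <- purrr::map2_chr(tbl$permutation_p, tbl$n_permutations,
                                   function(p, n) {
                                     if (is.na(p)) NA_character_ else format_p(p, n)
                                   })
  if (!is.null(informative) && length(informative) > 0) {
    tbl$planted_features_selected <- purrr::map_chr(reports, function(m) {
      hit <- intersect(m$selected_features, informative)
      if (length(hit) == 0) "" else paste(hit, collapse = ", ")
    })
  }
  tbl
}

model_report_text <- function(model, roc = NULL) {
  lines <- c(
    paste0("drug: ", model$drug),
    paste0("model_type: ", model$model_type),
    paste0("selected_features: ", paste(model$selected_features, collapse = ", ")),
    sprintf("C: %g", model$C),
    sprintf("gamma: %g", model$gamma),
    sprintf("cv_accuracy: %.4f", model$cv_accuracy),
    sprintf("n_subjects: %d", model$n)
  )
  if (!is.null(model$permutation_p)) {
    lines <- c(lines,
               sprintf("permutation_p: %.6g", model$permutation_p),
               sprintf("n_permutations: %d", model$n_permutations),
               paste0("permutation_p_display: ",
                      format_p(model$permutation_p, model$n_permutations)))
  }
  if (!is.null(roc)) lines <- c(lines, sprintf("roc_auc: %.4f", roc$auc))
  c(lines, "selection_trace:",
    sprintf("  - %s: %.4f", model$selection_trace$feature,
            model$selection_trace$accuracy))
}

#' Read (or default) the pipeline YAML configuration
#'
#' The configuration mirrors the pipeline stages: `cohort` (sizes, deficit,
#' effect-model weights), `task` (trial counts, staircase), `benchmark`
#' (fraction), `classify` (drugs, model types, grid exponents, n_perm).
#' `read_pipeline_config()` with no argument returns the package default
#' (installed at `extdata/default_config.yaml`).
#'
#' @param path Path to a YAML file, or `NULL` for the packaged default.
#' @return A nested list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "default_config.yaml",
                                package = "stopstrat")
  cfg <- yaml::read_yaml(path)
  required <- c("cohort", "task", "benchmark", "classify")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop_config(paste0("config is missing section(s): ",
                       paste(missing, collapse = ", ")),
                field = missing[1])
  }
  cfg
}

config_to_cohort <- function(cfg, seed) {
  co <- cfg$cohort
  weights <- unlist(co$effect_weights %||% list())
  em <- if (length(weights) == 0 && is.null(co$effect_intercept)) {
    effect_model_default()
  } else {
    effect_model(weights = weights,
                 intercept = co$effect_intercept %||% 9,
                 drug_effect_sd_ms = co$effect_sd_ms %||% 8)
  }
  cohort_config(
    n_patients = co$n_patients, n_controls = co$n_controls, seed = seed,
    drug_labels = co$drug_labels %||% c("placebo", "atomoxetine", "citalopram"),
    feature_spec = feature_spec_default(informative = names(em$weights)),
    effect_model = em,
    deficit_ms = co$deficit_ms %||% 30,
    control_ssrt_mean_ms = co$control_ssrt_mean_ms %||% 200,
    ssrt_sd_ms = co$ssrt_sd_ms %||% 25,
    benchmark_fraction = cfg$benchmark$fraction %||% 0.30
  )
}
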