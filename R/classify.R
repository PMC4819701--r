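#' Exponential (C, gamma) search grid
#'
#' Hyperparameters are searched over exponentially growing sequences
#' `base^exponent_min, base^(exponent_min + exponent_step), ...,
#' base^exponent_max`, used for both `C` and `gamma`.  The default produces
#' the canonical 41-value sequence `2^-10, 2^-9.5, ..., 2^10` (so 41 x 41 =
#' 1681 grid pairs); coarser grids trade optimality for speed and are the
#' usual choice inside feature-selection loops.
#'
#' @param exponent_min,exponent_max,exponent_step Exponent range and step.
#' @param base Base of the sequence (default 2).
#' @return A `grid_spec` object.  `grid_values()` returns the numeric
#'   sequence.
#' @examples
#' length(grid_values(grid_spec()))  # 41
#' @export
grid_spec <- function(exponent_min = -10, exponent_max = 10,
                      exponent_step = 0.5, base = 2) {
  check_number(exponent_step, "exponent_step", min = 0, strict_min = TRUE)
  if (exponent_min > exponent_max) {
    stop_config("`exponent_min` must be <= `exponent_max`",
                field = "exponent_min")
  }
  structure(list(exponent_min = exponent_min, exponent_max = exponent_max,
                 exponent_step = exponent_step, base = base),
            class = "grid_spec")
}

#' @param spec A `grid_spec`.
#' @rdname grid_spec
#' @export
grid_values <- function(spec = grid_spec()) {
  spec$base^seq(spec$exponent_min, spec$exponent_max, by = spec$exponent_step)
}

#' Exhaustive (C, gamma) grid search maximizing LOOCV accuracy
#'
#' Evaluates every pair of grid values for `C` and `gamma` with
#' [loocv_accuracy()] and returns the maximizer.  Ties are broken
#' deterministically: smallest `C`, then smallest `gamma`.
#'
#' @inheritParams loocv_predictions
#' @param grid A [grid_spec()].
#' @return A `grid_search` object: `C`, `gamma`, `accuracy`, and `surface`
#'   (a tibble of every evaluated `(C, gamma, accuracy)` triple, for
#'   plotting).
#' @export
grid_search <- function(features, labels, grid = grid_spec(),
                        feature_subset = NULL) {
  vals <- grid_values(grid)
  surface <- tidyr::expand_grid(C = vals, gamma = vals)
  folds <- loocv_folds(features, feature_subset)  # shared across all pairs
  y <- as_responder_factor(labels)
  acc <- purrr::map2_dbl(surface$C, surface$gamma, function(C, g) {
    loocv_accuracy_folds(folds, y, C = C, gamma = g)
  })
  surface$accuracy <- acc
  # rows are ordered by (C, gamma) ascending, so the first maximum realizes
  # the smallest-C-then-smallest-gamma tie-break
  best <- which.max(acc)
  structure(
    list(C = surface$C[best], gamma = surface$gamma[best],
         accuracy = acc[best], surface = surface,
         feature_subset = feature_subset),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat(sprintf("grid search: best (C, gamma) = (%g, %g), LOOCV accuracy %.3f over %d pairs\n",
              x$C, x$gamma, x$accuracy, nrow(x$surface)))
  invisible(x)
}

#' Greedy forward feature selection wrapped around the SVM
#'
#' Starting from an empty set, each iteration evaluates every remaining
#' candidate feature joined to the selected set -- each candidate set gets
#' its own full (C, gamma) grid search -- and admits the candidate whose
#' grid-optimal LOOCV accuracy is highest.  Selection terminates when no
#' candidate strictly increases the accuracy, or when all features are
#' selected.  Candidate ties go to the lowest column index.  The final
#' `(C, gamma)` is the grid optimum on the final feature set.
#'
#' @inheritParams grid_search
#' @param drug,model_type Optional metadata recorded on the report.
#' @return A `responder_model` object: `selected_features`, `C`, `gamma`,
#'   `cv_accuracy`, `selection_trace` (tibble of feature added and accuracy
#'   after adding), plus the training `features`/`labels` for downstream
#'   permutation tests and ROC curves.  [generics::tidy()] returns the
#'   trace, [generics::glance()] a one-row summary.
#' @export
forward_select <- function(features, labels, grid = grid_spec(),
                           drug = NA_character_, model_type = NA_character_) {
  x <- as_feature_matrix(features)
  pool <- colnames(x)
  if (length(pool) < 1) abort("at least one candidate feature is required")
  y <- as_responder_factor(labels)

  selected <- character(0)
  best_acc <- -Inf
  best_fit <- NULL
  trace <- list()
  repeat {
    if (length(pool) == 0) break
    step_best <- NULL
    step_acc <- -Inf
    for (cand in pool) {  # pool keeps column order: first-come wins ties
      gs <- grid_search(features, y, grid = grid,
                        feature_subset = c(selected, cand))
      if (gs$accuracy > step_acc) {
        step_acc <- gs$accuracy
        step_best <- cand
        step_fit <- gs
      }
    }
    if (step_acc <= best_acc) break  # strict improvement required
    selected <- c(selected, step_best)
    pool <- setdiff(pool, step_best)
    best_acc <- step_acc
    best_fit <- step_fit
    trace[[length(trace) + 1L]] <- tibble(feature = step_best,
                                          accuracy = step_acc)
  }
  structure(
    list(drug = drug, model_type = model_type,
         selected_features = selected, C = best_fit$C, gamma = best_fit$gamma,
         cv_accuracy = best_acc,
         selection_trace = dplyr::bind_rows(trace),
         grid = grid, features = as_tibble(as.data.frame(x)), labels = y,
         n = nrow(x)),
    class = "responder_model"
  )
}

#' @export
print.responder_model <- function(x, ...) {
  cat("Responder classifier (RBF-SVM, LOOCV)\n")
  if (!is.na(x$drug)) cat("  drug:       ", x$drug, "\n")
  if (!is.na(x$model_type)) cat("  model type: ", x$model_type, "\n")
  cat("  features:   ", paste(x$selected_features, collapse = ", "), "\n")
  cat(sprintf("  (C, gamma):  (%g, %g)\n", x$C, x$gamma))
  cat(sprintf("  accuracy:    %.1f%% (n = %d)\n", 100 * x$cv_accuracy, x$n))
  if (!is.null(x$permutation_p)) {
    cat("  permutation:", format_p(x$permutation_p, x$n_permutations), "\n")
  }
  invisible(x)
}

format_p <- function(p, n_perm) {
  if (p == 0) sprintf("p < %.1e", 1 / n_perm) else sprintf("p = %.4f", p)
}

#' Permutation test of a responder classifier's LOOCV accuracy
#'
#' The responder labels are randomized `n_perm` times; for each permutation
#' the LOOCV accuracy is recomputed with the model's selected features and
#' `(C, gamma)` held fixed (the default), or with feature selection and grid
#' search re-run from scratch on the permuted labels
#' (`reselect = TRUE`, a stricter variant that also charges the selection
#' procedure for optimism).  The p-value is the proportion of permuted
#' models whose accuracy is strictly larger than the real model's, so p = 0
#' is attainable and is reported as "< 1/n_perm".
#'
#' @param model A `responder_model` from [forward_select()].
#' @param n_perm Number of label randomizations (default 5000).
#' @param seed Integer seed for the permutations.
#' @param reselect Re-run selection + grid search per permutation?
#' @return A `permutation_test` object: `p_value`, `real_accuracy`,
#'   `perm_accuracies`, `n_perm`, `reselect`.  The input model is also
#'   returned (under `$model`) with `permutation_p`/`n_permutations` filled
#'   in.
#' @export
permutation_test <- function(model, n_perm = 5000, seed = NULL,
                             reselect = FALSE) {
  check_number(n_perm, "n_perm", min = 1)
  features <- model$features
  labels <- as_responder_factor(model$labels)
  real_acc <- model$cv_accuracy
  folds <- if (!reselect) loocv_folds(features, model$selected_features)
  run <- function() {
    perm_acc <- vapply(seq_len(n_perm), function(b) {
      y_b <- sample(labels)
      if (reselect) {
        forward_select(features, y_b, grid = model$grid)$cv_accuracy
      } else {
        loocv_accuracy_folds(folds, y_b, C = model$C, gamma = model$gamma)
      }
    }, numeric(1))
    p <- sum(perm_acc > real_acc) / n_perm  # strict "larger than"
    model$permutation_p <- p
    model$n_permutations <- n_perm
    structure(list(p_value = p, real_accuracy = real_acc,
                   perm_accuracies = perm_acc, n_perm = n_perm,
                   reselect = reselect, model = model),
              class = "permutation_test")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("permutation test: real LOOCV accuracy %.3f, %s (%d randomizations%s)\n",
              x$real_accuracy, format_p(x$p_value, x$n_perm), x$n_perm,
              if (x$reselect) ", selection re-run per permutation" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance decisions
#'
#' A model is significant iff its permutation p-value is strictly below
#' `alpha / n_models`.
#'
#' @param p_values Numeric vector of p-values.
#' @param n_models Number of models tested (defaults to
#'   `length(p_values)`).
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble `p_value`, `alpha_adjusted`, `significant`.
#' @examples
#' bonferroni(c(0.01, 0.0125), n_models = 4)
#' @export
bonferroni <- function(p_values, n_models = length(p_values), alpha = 0.05) {
  check_number(n_models, "n_models", min = 1)
  tibble(p_value = p_values, alpha_adjusted = alpha / n_models,
         significant = p_values < alpha / n_models)
}

#' Receiver operating characteristic curve from decision values
#'
#' Sweeps a threshold over the signed decision values (higher = more
#' responder-like), records sensitivity and specificity at every distinct
#' threshold, and computes the AUC by the trapezoid rule over the
#' (1 - specificity, sensitivity) curve.
#'
#' @param decision_values Numeric scores, e.g. the `decision_value` column
#'   of [loocv_predictions()].
#' @param labels Responder labels; both classes must be present.
#' @return A `roc_result`: `points` (tibble `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @examples
#' roc_curve(c(-2, -1, 1, 2), c(FALSE, FALSE, TRUE, TRUE))$auc  # 1
#' @export
roc_curve <- function(decision_values, labels) {
  y <- as_responder_factor(labels)
  pos <- y == "responder"
  if (!any(pos) || all(pos)) {
    abort("both responder classes must be present to compute a ROC curve")
  }
  # thresholds between -Inf and +Inf give the full curve from (FPR, TPR) =
  # (1, 1) down to (0, 0); a point predicts "responder" iff value > threshold
  thr <- c(-Inf, sort(unique(decision_values)))
  sens <- vapply(thr, function(t) mean(decision_values[pos] > t), numeric(1))
  spec <- vapply(thr, function(t) mean(decision_values[!pos] <= t), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  structure(list(points = tibble(threshold = thr, sensitivity = sens,
                                 specificity = spec),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Benchmark-robustness sweep
#'
#' Re-runs the responder analysis across a range of benchmark fractions:
#' (a) *optimized* -- at each fraction, labels are recomputed and a fresh
#' model is selected (features and hyperparameters re-optimized); (b)
#' *robustness* -- the model optimized for the principal fraction is held
#' fixed (features and `(C, gamma)` unchanged) and its LOOCV accuracy is
#' evaluated against the labels of every other fraction.  A fraction at
#' which all patients fall on one side of the threshold yields a
#' single-class labelling; its cells are marked undefined (`NA`) and the
#' sweep continues.
#'
#' @param features Patient feature table (e.g. [build_feature_table()]).
#' @param deltas Tibble from [compute_deltas()].
#' @param deficit Group Parkinson's deficit in ms.
#' @param fractions Benchmark fractions to sweep (default 0.10--0.50).
#' @param principal The principal fraction whose optimal model is
#'   stress-tested (default 0.30; must be in `fractions`).
#' @param grid A [grid_spec()] used for every optimization.
#' @param drug,model_type Metadata passed through to the models.
#' @return A `benchmark_sweep`: `results` (tibble `fraction`,
#'   `n_responders`, `optimized_accuracy`, `robustness_accuracy`,
#'   `features`, `C`, `gamma`), `principal_model`, `principal`.
#' @export
benchmark_sweep <- function(features, deltas, deficit,
                            fractions = seq(0.10, 0.50, by = 0.10),
                            principal = 0.30, grid = grid_spec(),
                            drug = NA_character_,
                            model_type = NA_character_) {
  if (!any(abs(fractions - principal) < 1e-12)) {
    stop_config("`principal` must be one of `fractions`", field = "principal")
  }
  labels_at <- lapply(fractions, function(f) {
    label_responders(deltas, deficit = deficit, fraction = f)
  })
  names(labels_at) <- sprintf("%.2f", fractions)

  fit_at <- function(lab) {
    if (dplyr::n_distinct(lab$responder) < 2) return(NULL)
    forward_select(features, lab$responder, grid = grid, drug = drug,
                   model_type = model_type)
  }
  models <- lapply(labels_at, fit_at)
  principal_model <- models[[sprintf("%.2f", principal)]]
  if (is.null(principal_model)) {
    abort("labels are single-class at the principal fraction: no model to sweep")
  }

  results <- purrr::map_dfr(seq_along(fractions), function(i) {
    lab <- labels_at[[i]]
    m <- models[[i]]
    robust <- if (dplyr::n_distinct(lab$responder) < 2) NA_real_ else {
      loocv_accuracy(features, lab$responder, C = principal_model$C,
                     gamma = principal_model$gamma,
                     feature_subset = principal_model$selected_features)
    }
    tibble(
      fraction = fractions[i],
      n_responders = sum(lab$responder),
      optimized_accuracy = if (is.null(m)) NA_real_ else m$cv_accuracy,
      robustness_accuracy = robust,
      features = if (is.null(m)) NA_character_ else
        paste(m$selected_features, collapse = ", "),
      C = if (is.null(m)) NA_real_ else m$C,
      gamma = if (is.null(m)) NA_real_ else m$gamma
    )
  })
  structure(list(results = results, principal_model = principal_model,
                 principal = principal),
            class = "benchmark_sweep")
}

#' @export
print.benchmark_sweep <- function(x, ...) {
  cat(sprintf("benchmark sweep (principal fraction %.2f):\n", x$principal))
  print(x$results)
  invisible(x)
}
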