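#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy and glance methods for fitted responder models
#'
#' `tidy()` returns the forward-selection trace (one row per admitted
#' feature with the grid-optimal LOOCV accuracy after adding it); `glance()`
#' returns a one-row model summary.
#'
#' @param x A `responder_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.responder_model <- function(x, ...) {
  dplyr::mutate(x$selection_trace, step = dplyr::row_number(), .before = 1)
}

#' @rdname tidy.responder_model
#' @export
glance.responder_model <- function(x, ...) {
  tibble(
    drug = x$drug, model_type = x$model_type,
    n_features = length(x$selected_features),
    C = x$C, gamma = x$gamma, cv_accuracy = x$cv_accuracy,
    permutation_p = x$permutation_p %||% NA_real_,
    n = x$n
  )
}

#' Tidy methods for ROC results and benchmark sweeps
#'
#' @param x A `roc_result` or `benchmark_sweep`.
#' @param ... Unused.
#' @return A tibble of curve points (ROC: `threshold`, `sensitivity`,
#'   `specificity`) or one row per benchmark fraction.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) tibble(auc = x$auc)

#' @rdname tidy.roc_result
#' @export
tidy.benchmark_sweep <- function(x, ...) x$results
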