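#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_abline
#'   geom_point labs scale_fill_viridis_c theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  pts <- dplyr::arrange(object$points, 1 - .data$specificity,
                        .data$sensitivity)
  ggplot(pts, aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                colour = "grey60") +
    geom_line() +
    geom_point(size = 1) +
    coord_equal() +
    labs(x = "1 - specificity", y = "Sensitivity",
         title = sprintf("ROC curve (AUC = %.2f)", object$auc)) +
    theme_minimal()
}

#' Plot the (C, gamma) cross-validation accuracy surface
#'
#' The familiar grid-search heat map: each tile is one `(C, gamma)` pair
#' coloured by its LOOCV accuracy, on log2 axes.
#'
#' @param object A `grid_search` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_search <- function(object, ...) {
  surf <- dplyr::mutate(object$surface, log2C = log2(.data$C),
                        log2gamma = log2(.data$gamma))
  ggplot(surf, aes(x = .data$log2C, y = .data$log2gamma,
                   fill = .data$accuracy)) +
    geom_tile() +
    scale_fill_viridis_c(name = "LOOCV\naccuracy") +
    labs(x = expression(log[2] ~ C), y = expression(log[2] ~ gamma),
         title = sprintf("Grid search (best: C = 2^%g, gamma = 2^%g, %.1f%%)",
                         log2(object$C), log2(object$gamma),
                         100 * object$accuracy)) +
    theme_minimal()
}

#' Plot a benchmark-robustness sweep
#'
#' Accuracy of freshly optimized models at each benchmark fraction,
#' alongside the principal-benchmark model's accuracy when stress-tested
#' against the other fractions' labels.
#'
#' @param object A `benchmark_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$results,
    cols = c("optimized_accuracy", "robustness_accuracy"),
    names_to = "kind", values_to = "accuracy"
  )
  long$kind <- ifelse(long$kind == "optimized_accuracy",
                      "re-optimized per benchmark",
                      sprintf("fixed %.2f-optimal model", object$principal))
  ggplot(long, aes(x = .data$fraction, y = .data$accuracy,
                   colour = .data$kind)) +
    geom_line() +
    geom_point() +
    labs(x = "Benchmark fraction of Parkinson's deficit",
         y = "LOOCV accuracy", colour = NULL) +
    theme_minimal()
}
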