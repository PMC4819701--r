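#' Radial basis function kernel
#'
#' `K(x1, x2) = exp(-gamma * ||x1 - x2||^2)`, the similarity function of the
#' responder classifier.  Symmetric, bounded in (0, 1], and equal to 1 iff
#' the inputs coincide.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param gamma Kernel width parameter (> 0).
#' @return The kernel value.
#' @examples
#' rbf_kernel(c(0, 0), c(0.5, 0), gamma = 8)  # exp(-2)
#' @export
rbf_kernel <- function(x1, x2, gamma) {
  if (length(x1) != length(x2)) {
    abort("x1 and x2 must have the same length")
  }
  check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  exp(-gamma * sum((x1 - x2)^2))
}

# z-score columns of `x` using statistics of the training rows only;
# constant columns get sd 1 so they standardize to 0 rather than NaN
fold_standardizer <- function(x_train) {
  mu <- colMeans(x_train)
  sd <- apply(x_train, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  function(x) sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

as_feature_matrix <- function(features, feature_subset = NULL) {
  x <- as.data.frame(features)
  if ("subject_id" %in% names(x)) x$subject_id <- NULL
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, names(x))
    if (length(missing) > 0) {
      abort(paste0("unknown feature(s): ", paste(missing, collapse = ", ")))
    }
    x <- x[, feature_subset, drop = FALSE]
  }
  as.matrix(x)
}

#' Train a soft-margin RBF-kernel SVM
#'
#' A thin, deterministic wrapper around the LIBSVM C-classification solver
#' (via \pkg{e1071}) with the radial basis function kernel, misclassification
#' cost `C` and kernel width `gamma`.  Features are expected to be
#' standardized by the caller (cross-validation standardizes inside each
#' fold); no scaling happens here.  A single-class training set yields a
#' constant majority-class predictor with a warning, which keeps degenerate
#' leave-one-out folds well defined.
#'
#' @param x Numeric matrix (rows = subjects).
#' @param labels Logical (`TRUE` = responder) or factor with levels
#'   nonresponder/responder.
#' @param C Misclassification cost (> 0).
#' @param gamma RBF kernel width (> 0).
#' @return A `strat_svm` object; `predict()` returns labels, or signed
#'   decision values (positive = responder) with `type = "decision"`.
#' @examples
#' x <- matrix(c(-2, -1.5, 1.5, 2), ncol = 1)
#' fit <- train_svm(x, c(FALSE, FALSE, TRUE, TRUE), C = 1, gamma = 1)
#' predict(fit, x)
#' @export
train_svm <- function(x, labels, C, gamma) {
  check_number(C, "C", min = 0, strict_min = TRUE)
  check_number(gamma, "gamma", min = 0, strict_min = TRUE)
  y <- as_responder_factor(labels)
  x <- as.matrix(x)
  present <- unique(as.character(y))
  if (length(present) < 2) {
    warn("single-class training set: returning constant majority predictor")
    return(structure(list(constant = present, C = C, gamma = gamma),
                     class = "strat_svm"))
  }
  fit <- e1071::svm(x = x, y = droplevels(y), type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE, tolerance = 1e-3)
  # e1071 decision values are positive for the first training label seen;
  # record the sign that makes positive mean "responder"
  sign_flip <- if (fit$labels[1] == which(levels(droplevels(y)) == "responder")) 1 else -1
  structure(list(fit = fit, sign = sign_flip, C = C, gamma = gamma),
            class = "strat_svm")
}

#' @param object A `strat_svm`.
#' @param newdata Numeric matrix of test rows.
#' @param type `"class"` for labels, `"decision"` for signed decision values.
#' @param ... Unused.
#' @rdname train_svm
#' @export
predict.strat_svm <- function(object, newdata, type = c("class", "decision"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    if (type == "decision") {
      d <- if (object$constant == "responder") 1 else -1
      return(rep(d, nrow(newdata)))
    }
    return(factor(rep(object$constant, nrow(newdata)),
                  levels = responder_levels))
  }
  pred <- predict(object$fit, newdata, decision.values = TRUE)
  if (type == "decision") {
    return(object$sign * as.numeric(attr(pred, "decision.values")))
  }
  factor(as.character(pred), levels = responder_levels)
}

#' Leave-one-out cross-validated predictions and accuracy
#'
#' Each subject is held out once; the classifier is trained on the remaining
#' n - 1 subjects and predicts the held-out one.  Feature standardization
#' (per-feature z-scoring) is recomputed inside every fold from its training
#' rows only, so no information leaks from the test subject.  When a
#' training fold contains a single class the fold falls back to the
#' majority-class constant predictor.
#'
#' @param features Tibble or matrix of subject rows (a `subject_id` column,
#'   if present, is dropped).
#' @param labels Responder labels (logical or nonresponder/responder factor).
#' @param C,gamma SVM hyperparameters.
#' @param feature_subset Optional character vector restricting the columns
#'   used.
#' @return `loocv_predictions()`: a tibble `fold`, `truth`, `prediction`,
#'   `decision_value`; `loocv_accuracy()`: the proportion of correct
#'   held-out predictions.
#' @examples
#' x <- tibble::tibble(f = c(-2, -1.5, -1, 1, 1.5, 2))
#' loocv_accuracy(x, c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
#'                C = 1, gamma = 1)
#' @export
loocv_predictions <- function(features, labels, C, gamma,
                              feature_subset = NULL) {
  folds <- loocv_folds(features, feature_subset)
  loocv_predict_folds(folds, as_responder_factor(labels), C, gamma)
}

#' @rdname loocv_predictions
#' @export
loocv_accuracy <- function(features, labels, C, gamma, feature_subset = NULL) {
  p <- loocv_predictions(features, labels, C, gamma, feature_subset)
  mean(p$prediction == p$truth)
}

# Precompute the fold-standardized train/test matrices once per feature set:
# they depend on the features only, so grid search and label-permutation
# loops can reuse them across thousands of SVM fits.
loocv_folds <- function(features, feature_subset = NULL) {
  x <- as_feature_matrix(features, feature_subset)
  n <- nrow(x)
  if (n < 3) abort("leave-one-out cross-validation needs n >= 3 subjects")
  lapply(seq_len(n), function(i) {
    x_tr <- x[-i, , drop = FALSE]
    std <- fold_standardizer(x_tr)
    list(train = std(x_tr), test = std(x[i, , drop = FALSE]))
  })
}

# lean inner loop: same fit/predict semantics as train_svm()/predict(), with
# per-fit validation hoisted out (folds are standardized, C/gamma prechecked)
loocv_predict_folds <- function(folds, y, C, gamma) {
  n <- length(folds)
  if (length(y) != n) abort("labels and features disagree on n")
  responder_code <- which(responder_levels == "responder")
  preds <- character(n)
  dvals <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- droplevels(y[-i])
    if (nlevels(y_tr) < 2) {  # degenerate fold: constant majority predictor
      preds[i] <- levels(y_tr)
      dvals[i] <- if (preds[i] == "responder") 1 else -1
      next
    }
    fit <- e1071::svm(x = folds[[i]]$train, y = y_tr,
                      type = "C-classification", kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE,
                      tolerance = 1e-3)
    pred <- predict(fit, folds[[i]]$test, decision.values = TRUE)
    flip <- if (fit$labels[1] == responder_code) 1 else -1
    preds[i] <- as.character(pred)
    dvals[i] <- flip * as.numeric(attr(pred, "decision.values"))[1]
  }
  tibble(fold = seq_len(n), truth = y,
         prediction = factor(preds, levels = responder_levels),
         decision_value = dvals)
}

loocv_accuracy_folds <- function(folds, y, C, gamma) {
  p <- loocv_predict_folds(folds, y, C, gamma)
  mean(p$prediction == p$truth)
}
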