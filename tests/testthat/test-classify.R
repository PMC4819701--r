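test_that("the default grid is the canonical 41-value exponential sequence", {
  vals <- grid_values(grid_spec())
  expect_length(vals, 41)
  expect_equal(vals[1], 2^-10)
  expect_equal(vals[41], 2^10)
  expect_equal(vals[2] / vals[1], 2^0.5)
  expect_error(grid_spec(exponent_step = 0), "exponent_step")
  expect_error(grid_spec(2, -2), "exponent_min")
})

test_that("grid search equals a brute-force argmax with the documented tie-break", {
  withr::with_seed(10, {
    feats <- tibble::tibble(a = c(rnorm(8, -1), rnorm(8, 1)), b = rnorm(16))
  })
  labels <- rep(c(FALSE, TRUE), each = 8)
  grid <- coarse_grid()
  gs <- grid_search(feats, labels, grid = grid)
  # independent brute force: re-evaluate every pair and apply the tie-break
  vals <- grid_values(grid)
  best <- list(acc = -Inf, C = NA, gamma = NA)
  for (C in vals) for (g in vals) {
    acc <- loocv_accuracy(feats, labels, C = C, gamma = g)
    if (acc > best$acc) best <- list(acc = acc, C = C, gamma = g)
  }
  expect_equal(gs$accuracy, best$acc)
  expect_equal(gs$C, best$C)
  expect_equal(gs$gamma, best$gamma)
  expect_equal(nrow(gs$surface), length(vals)^2)
})

test_that("a flat accuracy surface resolves ties to the smallest C then gamma", {
  # all labels identical: every fold majority-falls-back, accuracy 1 everywhere
  feats <- tibble::tibble(f = c(0.1, 0.5, 0.9, 0.3))
  gs <- suppressWarnings(grid_search(feats, rep(TRUE, 4), grid = coarse_grid()))
  expect_equal(gs$C, 2^-4)
  expect_equal(gs$gamma, 2^-4)
})

test_that("forward selection finds a planted feature and stops without strict gains", {
  hits <- vapply(1:5, function(s) {
    sep <- make_separable(n_per_class = 8, n_noise = 4, seed = 100 + s)
    m <- forward_select(sep$features, sep$labels, grid = coarse_grid())
    m$selection_trace$feature[1] == "signal"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  sep <- make_separable(n_per_class = 8, n_noise = 4, seed = 101)
  m <- forward_select(sep$features, sep$labels, grid = coarse_grid())
  expect_true(all(diff(m$selection_trace$accuracy) > 0))  # strict admission
  expect_equal(m$cv_accuracy, max(m$selection_trace$accuracy))
})

test_that("duplicate features add nothing and ties go to the earliest column", {
  sep <- make_separable(n_per_class = 6, seed = 2)
  feats <- tibble::tibble(copy1 = sep$features$signal,
                          copy2 = sep$features$signal,
                          copy3 = sep$features$signal)
  m <- forward_select(feats, sep$labels, grid = coarse_grid())
  expect_equal(m$selected_features, "copy1")
})

test_that("tidy and glance expose the selection trace and model summary", {
  sep <- make_separable(n_per_class = 5, n_noise = 1, seed = 3)
  m <- forward_select(sep$features, sep$labels, grid = coarse_grid(),
                      drug = "atomoxetine", model_type = "clinical")
  td <- generics::tidy(m)
  expect_true(all(c("step", "feature", "accuracy") %in% names(td)))
  gl <- generics::glance(m)
  expect_equal(gl$drug, "atomoxetine")
  expect_equal(gl$n_features, length(m$selected_features))
  expect_equal(gl$cv_accuracy, m$cv_accuracy)
})

test_that("permutation p-values count strictly greater accuracies", {
  sep <- make_separable(n_per_class = 5, seed = 4)
  m <- forward_select(sep$features, sep$labels, grid = coarse_grid())
  expect_equal(m$cv_accuracy, 1)
  pt <- permutation_test(m, n_perm = 30, seed = 5)
  expect_equal(pt$p_value, 0)  # nothing can strictly exceed accuracy 1
  expect_match(format(pt$p_value, nsmall = 0), "0")
  # internal consistency of the strict count on a non-degenerate model
  withr::with_seed(6, {
    feats <- tibble::tibble(a = rnorm(14), b = rnorm(14))
    labels <- sample(rep(c(TRUE, FALSE), 7))
  })
  m2 <- forward_select(feats, labels, grid = coarse_grid())
  pt2 <- permutation_test(m2, n_perm = 40, seed = 7)
  expect_equal(pt2$p_value,
               sum(pt2$perm_accuracies > pt2$real_accuracy) / 40)
  same <- permutation_test(m2, n_perm = 40, seed = 7)
  expect_identical(pt2$p_value, same$p_value)  # seeded determinism
  expect_error(permutation_test(m2, n_perm = 0), "n_perm")
})

test_that("the reselection variant re-runs selection on permuted labels", {
  withr::with_seed(11, {
    feats <- tibble::tibble(a = rnorm(10), b = rnorm(10))
    labels <- sample(rep(c(TRUE, FALSE), 5))
  })
  m <- forward_select(feats, labels, grid = grid_spec(-1, 1, 1))
  pt <- permutation_test(m, n_perm = 5, seed = 8, reselect = TRUE)
  expect_true(pt$reselect)
  expect_length(pt$perm_accuracies, 5)
})

test_that("Bonferroni correction is strict at alpha over the model count", {
  out <- bonferroni(c(0.01, 0.0125, 0.04), n_models = 4)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(unique(out$alpha_adjusted), 0.0125)
  expect_equal(bonferroni(0.04, n_models = 1)$significant, TRUE)
})

test_that("ROC curves span both corners with trapezoid AUC matching pROC", {
  perfect <- roc_curve(c(-2, -1, 1, 2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perfect$auc, 1)
  reversed <- roc_curve(c(2, 1, -1, -2), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(reversed$auc, 0)
  withr::with_seed(12, {
    dv <- rnorm(40)
    y <- sample(rep(c(TRUE, FALSE), 20))
  })
  r <- roc_curve(dv, y)
  pts <- r$points
  expect_true(any(pts$sensitivity == 1 & pts$specificity == 0))
  expect_true(any(pts$sensitivity == 0 & pts$specificity == 1))
  expect_true(all(pts$sensitivity >= 0 & pts$sensitivity <= 1))
  ref <- pROC::auc(pROC::roc(response = y, predictor = dv,
                             levels = c(FALSE, TRUE), direction = "<",
                             quiet = TRUE))
  expect_equal(r$auc, as.numeric(ref))
  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("random scores give near-chance AUC", {
  aucs <- vapply(1:40, function(s) {
    withr::with_seed(600 + s, {
      dv <- rnorm(60)
      y <- sample(rep(c(TRUE, FALSE), 30))
    })
    roc_curve(dv, y)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("SVM LOOCV predictions agree with an independent kernlab fit", {
  sep <- make_separable(n_per_class = 7, n_noise = 1, seed = 13)
  x <- scale(as.matrix(sep$features))
  fit <- train_svm(x, sep$labels, C = 2, gamma = 0.5)
  kl <- kernlab::ksvm(x, factor(ifelse(sep$labels, "responder", "nonresponder"),
                                levels = c("nonresponder", "responder")),
                      type = "C-svc", kernel = "rbfdot",
                      kpar = list(sigma = 0.5), C = 2, scaled = FALSE)
  expect_equal(as.character(predict(fit, x)),
               as.character(kernlab::predict(kl, x)))
})

test_that("benchmark sweeps re-optimize per fraction and stress the principal model", {
  withr::with_seed(14, {
    n <- 16
    feats <- tibble::tibble(sig = rnorm(n), noise = rnorm(n))
    deltas <- tibble::tibble(subject_id = sprintf("s%02d", 1:n),
                             drug = "atomoxetine",
                             # responder signal rides on `sig`
                             delta_ssrt_ms = 12 + 18 * feats$sig + rnorm(n, 0, 2))
  })
  sw <- benchmark_sweep(feats, deltas, deficit = 40,
                        fractions = c(0.1, 0.3, 0.5), principal = 0.3,
                        grid = grid_spec(-2, 2, 2))
  expect_equal(nrow(sw$results), 3)
  expect_true(all(diff(sw$results$n_responders) <= 0))
  expect_false(any(is.na(sw$results$robustness_accuracy)))
  expect_equal(sw$results$optimized_accuracy[sw$results$fraction == 0.3],
               sw$principal_model$cv_accuracy)
  # single-fraction sweep reduces to the principal analysis
  solo <- benchmark_sweep(feats, deltas, deficit = 40, fractions = 0.3,
                          principal = 0.3, grid = grid_spec(-2, 2, 2))
  expect_equal(nrow(solo$results), 1)
  expect_equal(solo$results$optimized_accuracy, solo$principal_model$cv_accuracy)
})

test_that("a fraction with single-class labels is marked undefined, not fatal", {
  withr::with_seed(15, {
    feats <- tibble::tibble(sig = rnorm(12))
    deltas <- tibble::tibble(subject_id = sprintf("s%02d", 1:12),
                             drug = "citalopram",
                             delta_ssrt_ms = 10 + 8 * feats$sig)
  })
  # at fraction 0.5 x deficit 60 = 30 ms no patient qualifies
  sw <- benchmark_sweep(feats, deltas, deficit = 60,
                        fractions = c(0.1, 0.5), principal = 0.1,
                        grid = grid_spec(-2, 2, 2))
  row <- sw$results[sw$results$fraction == 0.5, ]
  expect_true(is.na(row$optimized_accuracy))
  expect_true(is.na(row$robustness_accuracy))
  expect_equal(row$n_responders, 0)
})
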