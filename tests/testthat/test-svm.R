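test_that("the RBF kernel matches its closed form and is a valid kernel", {
  expect_equal(rbf_kernel(c(1, 2), c(1, 2), gamma = 5), 1)
  expect_equal(rbf_kernel(0, 1, gamma = 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(0.5, 0), gamma = 2^3), exp(-2))
  expect_error(rbf_kernel(c(1, 2), 1, gamma = 1), "length")
  expect_error(rbf_kernel(1, 2, gamma = 0), "gamma")
  withr::with_seed(1, {
    for (i in 1:20) {
      x <- rnorm(4); y <- rnorm(4); g <- runif(1, 0.01, 10)
      k <- rbf_kernel(x, y, g)
      expect_equal(k, rbf_kernel(y, x, g))  # symmetric
      expect_true(k > 0 && k <= 1)
      expect_lt(rbf_kernel(x, x + 1e-3, g), 1)  # 1 iff equal
    }
  })
})

test_that("well-separated clusters are classified perfectly at mid-grid parameters", {
  sep <- make_separable(n_per_class = 6)
  x <- scale(as.matrix(sep$features))
  fit <- train_svm(x, sep$labels, C = 1, gamma = 1)
  expect_equal(as.character(predict(fit, x)),
               ifelse(sep$labels, "responder", "nonresponder"))
  dv <- predict(fit, x, type = "decision")
  expect_true(all(dv[sep$labels] > 0))  # positive decision = responder
  expect_true(all(dv[!sep$labels] < 0))
  expect_equal(loocv_accuracy(sep$features, sep$labels, C = 1, gamma = 1), 1)
})

test_that("a single-class training set falls back to a constant majority predictor", {
  x <- matrix(rnorm(6), ncol = 1)
  expect_warning(fit <- train_svm(x, rep(TRUE, 6), C = 1, gamma = 1),
                 "single-class")
  expect_equal(as.character(predict(fit, x)), rep("responder", 6))
  # all labels identical -> every LOOCV fold is single-class -> accuracy 1
  expect_equal(loocv_accuracy(tibble::tibble(f = rnorm(5)), rep(TRUE, 5),
                              C = 1, gamma = 1), 1)
})

test_that("duplicating every training point leaves the decision function unchanged", {
  sep <- make_separable(n_per_class = 5)
  x <- scale(as.matrix(sep$features))
  test_pts <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  fit1 <- train_svm(x, sep$labels, C = 100, gamma = 1)
  fit2 <- train_svm(rbind(x, x), rep(sep$labels, 2), C = 100, gamma = 1)
  expect_equal(predict(fit1, test_pts, type = "decision"),
               predict(fit2, test_pts, type = "decision"), tolerance = 1e-4)
})

test_that("LOOCV needs three subjects and matches an explicit fold trace", {
  expect_error(loocv_accuracy(tibble::tibble(f = c(1, 2)), c(TRUE, FALSE),
                              C = 1, gamma = 1), "n >= 3")
  sep <- make_separable(n_per_class = 4)
  preds <- loocv_predictions(sep$features, sep$labels, C = 1, gamma = 1)
  # manual fold: train without row 1, predict row 1 with fold standardization
  x <- as.matrix(sep$features)
  mu <- colMeans(x[-1, , drop = FALSE])
  sd <- apply(x[-1, , drop = FALSE], 2, sd)
  fit <- train_svm(scale(x[-1, , drop = FALSE], mu, sd), sep$labels[-1],
                   C = 1, gamma = 1)
  manual <- predict(fit, scale(x[1, , drop = FALSE], mu, sd))
  expect_equal(preds$prediction[1], manual)
})

test_that("no information leaks from held-out rows or extra columns", {
  withr::with_seed(7, {
    feats <- tibble::tibble(noise1 = rnorm(24), noise2 = rnorm(24))
    labels <- sample(rep(c(TRUE, FALSE), 12))
  })
  base <- loocv_accuracy(feats, labels, C = 1, gamma = 1,
                         feature_subset = c("noise1", "noise2"))
  # a canary column equal to the label would make accuracy ~1 if any fold
  # leaked it; excluded via feature_subset it must change nothing
  with_canary <- dplyr::mutate(feats, canary = as.numeric(labels))
  leaked <- loocv_accuracy(with_canary, labels, C = 1, gamma = 1,
                           feature_subset = c("noise1", "noise2"))
  expect_identical(base, leaked)
  expect_lt(leaked, 0.8)  # stays at chance-ish, nowhere near the canary's 1.0
  # permuting subject rows (features and labels together) permutes folds only
  perm <- withr::with_seed(8, sample(nrow(feats)))
  expect_equal(loocv_accuracy(feats[perm, ], labels[perm], C = 1, gamma = 1),
               base)
})
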