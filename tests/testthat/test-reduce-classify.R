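test_that("PCA recovers the axis of maximal variance and matches SVD", {
  withr::with_seed(1, {
    t <- runif(100, -5, 5)
    m <- cbind(t + rnorm(100, 0, 0.05), t - rnorm(100, 0, 0.05))
    pca <- fit_pca(m)
    expect_equal(abs(pca$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 0.01)
    # sign convention: dominant entry positive
    expect_true(all(apply(pca$loadings, 2, function(v) v[which.max(abs(v))] > 0)))

    # SVD oracle on a random 20 x 10 matrix
    m2 <- matrix(rnorm(200), 20, 10)
    pca2 <- fit_pca(m2, n_components = 10)
    centered <- scale(m2, scale = FALSE)
    sv <- svd(centered)
    expect_equal(pca2$eigenvalues, sv$d^2 / (20 - 1), tolerance = 1e-8)
    proj <- project(pca2, m2, n_components = 10)
    oracle_scores <- sv$u %*% diag(sv$d)
    for (j in 1:10) {
      s <- sign(sum(proj[, j] * oracle_scores[, j]))
      expect_equal(unname(proj[, j]), s * oracle_scores[, j], tolerance = 1e-8)
    }
    # full-rank projection preserves pairwise distances
    expect_equal(as.matrix(dist(proj)), as.matrix(dist(centered)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # reconstruction with all components is exact
    recon <- proj %*% t(pca2$loadings) +
      matrix(pca2$mean, 20, 10, byrow = TRUE)
    expect_equal(recon, m2, tolerance = 1e-8, ignore_attr = TRUE)
    # eigenvalues sorted, non-negative
    expect_true(all(diff(pca2$eigenvalues) <= 1e-12))
    expect_true(all(pca2$eigenvalues >= 0))

    # projecting the training mean lands at the origin
    expect_equal(unname(project(pca2, colMeans(m2))), matrix(0, 1, 10),
                 tolerance = 1e-10)
    expect_error(project(pca2, matrix(0, 2, 3)), "column count")
  })
})

test_that("train/test splits honor fraction, minimum, disjointness, determinism", {
  meta <- tibble::tibble(
    spectrum_id = sprintf("s%02d", 1:48),
    tissue_class = rep(tissue_classes(), times = c(14, 15, 19)),
    patient_id = rep(sprintf("p%d", 1:8), length.out = 48)
  )
  sp <- split_train_test(meta, split_plan(0.30, 5), seed = 9)
  tr_cls <- meta$tissue_class[match(sp$train, meta$spectrum_id)]
  expect_equal(as.integer(table(tr_cls)[tissue_classes()]), c(5L, 5L, 6L))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), meta$spectrum_id)
  expect_identical(sp, split_train_test(meta, split_plan(0.30, 5), seed = 9))
  expect_false(identical(sp, split_train_test(meta, split_plan(0.30, 5), seed = 10)))

  # infeasible minimum names the class
  small <- dplyr::filter(meta, tissue_class != "normal" | spectrum_id %in% sprintf("s%02d", 1:4))
  expect_error(split_train_test(small, split_plan(0.30, 5), 1), "normal")

  # one patient holding a whole class makes the grouped split infeasible
  meta1 <- dplyr::mutate(meta, patient_id = ifelse(tissue_class == "normal", "p1", patient_id))
  expect_error(split_train_test(meta1, split_plan(0.30, 5, group_by_patient = TRUE), 1),
               "patient")

  # grouped mode keeps each patient on one side
  sp_g <- split_train_test(meta, split_plan(0.30, 2, group_by_patient = TRUE), seed = 3)
  pats_train <- unique(meta$patient_id[match(sp_g$train, meta$spectrum_id)])
  pats_test <- unique(meta$patient_id[match(sp_g$test, meta$spectrum_id)])
  expect_length(intersect(pats_train, pats_test), 0)
})

test_that("the RBF-SVM separates, is duplication-invariant, and beats linear on XOR", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
    y <- rep(c("normal", "edge"), each = 20)
    fit <- train_svm(x, y)
    expect_equal(predict_svm(fit, x), y)

    # duplicating every training row leaves the decision function unchanged
    fit2 <- train_svm(rbind(x, x), c(y, y))
    grid <- as.matrix(expand.grid(seq(-3, 11, 1), seq(-3, 11, 1)))
    expect_equal(predict_svm(fit, grid), predict_svm(fit2, grid))

    # XOR layout: RBF solves it, a linear classifier cannot
    centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
    xx <- do.call(rbind, lapply(1:4, function(i) {
      sweep(matrix(rnorm(30, 0, 0.3), 15, 2), 2, centers[i, ], "+")
    }))
    yy <- rep(c("normal", "normal", "edge", "edge"), each = 15)
    rbf <- train_svm(xx, yy)
    expect_equal(mean(predict_svm(rbf, xx) == yy), 1)
    lin <- e1071::svm(xx, factor(yy), kernel = "linear", scale = FALSE)
    expect_lte(mean(as.character(predict(lin, xx)) == yy), 0.75)

    expect_error(train_svm(x, rep("edge", 40)), "single class")
  })
})

test_that("evaluation metrics follow the contingency definitions exactly", {
  # perfect predictions
  truth <- rep(tissue_classes(), times = c(9, 10, 13))
  perfect <- report_from_predictions(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  expect_equal(sum(perfect$confusion), 32)

  # everything called malignant: sensitivity 1, specificity 0
  all_mal <- report_from_predictions(truth, rep("center", 32))
  expect_equal(all_mal$sensitivity, 1)
  expect_equal(all_mal$specificity, 0)
  expect_equal(all_mal$accuracy, 23 / 32)

  # constructed confusion TP=20 FN=3 TN=8 FP=1
  truth2 <- c(rep("normal", 9), rep("edge", 11), rep("center", 12))
  pred2 <- c(rep("normal", 8), "edge",            # 8 TN, 1 FP
             rep("normal", 2), rep("edge", 9),    # edge: 2 FN
             "normal", rep("center", 11))         # center: 1 FN
  r2 <- report_from_predictions(truth2, pred2)
  expect_equal(r2$sensitivity, 20 / 23, tolerance = 1e-12)
  expect_equal(round(r2$sensitivity, 3), 0.870)
  expect_equal(round(r2$specificity, 3), 0.889)
  expect_equal(r2$accuracy, 0.875)

  expect_error(report_from_predictions(c("normal", "weird"), c("normal", "normal")),
               "unseen|level")
})

test_that("accuracy decomposes into sensitivity and specificity on random reports", {
  withr::with_seed(7, {
    for (i in 1:200) {
      n <- sample(10:60, 1)
      truth <- sample(tissue_classes(), n, replace = TRUE, prob = c(0.3, 0.3, 0.4))
      if (dplyr::n_distinct(truth) < 3) next
      pred <- sample(tissue_classes(), n, replace = TRUE)
      r <- report_from_predictions(truth, pred)
      P <- sum(truth != "normal")
      N <- sum(truth == "normal")
      expect_equal(r$accuracy, (r$sensitivity * P + r$specificity * N) / (P + N),
                   tolerance = 1e-12)
    }
  })
})

test_that("repeated evaluation with one repeat equals a single run", {
  withr::with_seed(3, {
    labs <- rep(tissue_classes(), times = c(14, 15, 19))
    m <- matrix(rnorm(48 * 20), 48, 20,
                dimnames = list(sprintf("s%02d", 1:48), NULL))
    m[labs == "normal", 1] <- m[labs == "normal", 1] + 4
    gm <- ramanbiopsy:::new_grouped_matrix(m, labs, 1:20)
    cmp <- repeated_evaluation(gm, "pca_only", n_repeats = 1, base_seed = 50)
    meta <- tibble::tibble(spectrum_id = rownames(m), tissue_class = labs,
                           patient_id = rownames(m))
    sp <- split_train_test(meta, split_plan(), seed = 51)
    single <- run_variant(gm, "pca_only", sp, seed = 51)
    expect_equal(cmp$results$accuracy, single$accuracy)
    expect_equal(cmp$results$sensitivity, single$sensitivity)
    expect_equal(cmp$results$specificity, single$specificity)
  })
})
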