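# brute-force AUC oracle: tie-adjusted concordant-pair probability
pair_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (a in pos) total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  total / (length(pos) * length(neg))
}

test_that("spectrum-mode splits are stratified, sized and reproducible", {
  set.seed(1)
  grid <- seq(400, 420, by = 10)
  n <- 1000
  labels <- rep(c("a", "b"), each = n / 2)
  d <- spectral_dataset(grid, matrix(rnorm(n * 3), n, 3), labels,
                        paste0("cell", rep(1:40, each = 25)),
                        class_order = c("a", "b"))
  sp <- split_spec(test_fraction = 0.3, mode = "spectrum", seed = 7)
  parts <- split_dataset(d, sp)
  expect_equal(n_spectra(parts$test), 300L)
  expect_equal(sum(parts$test$labels == "a"), 150L)
  expect_equal(n_spectra(parts$train) + n_spectra(parts$test), n)

  again <- split_dataset(d, sp)
  expect_identical(rownames(again$test$intensities),
                   rownames(parts$test$intensities))
  expect_error(split_spec(test_fraction = 1.2), "0, 1")
})

test_that("cell-mode splits never share a cell between sides", {
  d <- simulate_dataset(small_sim_config(seed = 2L,
                                         cells = c(HPaSC = 4, iCAF = 4,
                                                   myCAF = 4), pixels = 5L))
  parts <- split_dataset(d, split_spec(mode = "cell", seed = 3))
  expect_length(intersect(unique(parts$train$cell_ids),
                          unique(parts$test$cell_ids)), 0)

  single <- subset_rows(d, d$cell_ids %in% c("HPaSC_c01", "iCAF_c01",
                                             "iCAF_c02", "myCAF_c01",
                                             "myCAF_c02"))
  expect_error(split_dataset(single, split_spec(mode = "cell")),
               "fewer than 2 cells")
})

test_that("confusion matrices count and conserve", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unname(cm$counts), rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(sum(cm$counts), 3L)

  perfect <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5),
                              c("A", "B"))
  expect_true(all(perfect$counts[upper.tri(perfect$counts)] == 0))
  expect_true(all(perfect$counts[lower.tri(perfect$counts)] == 0))
  expect_error(confusion_matrix("A", c("A", "B"), c("A", "B")),
               "lengths differ")
})

test_that("precision/recall/F1/accuracy follow their definitions", {
  cm <- confusion_matrix(rep(c("a", "b", "c"), each = 10),
                         rep(c("a", "b", "c"), each = 10), c("a", "b", "c"))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$by_class$precision == 1))
  expect_true(all(m$by_class$f1 == 1))

  cm2 <- confusion_matrix(c("a", "a", "a", "b"), c("a", "a", "b", "b"),
                          c("a", "b"))
  m2 <- classification_metrics(cm2)
  expect_equal(m2$by_class$precision, c(1, 1 / 2))
  expect_equal(m2$by_class$recall, c(2 / 3, 1))
  expect_equal(m2$by_class$f1, c(0.8, 2 / 3))
  expect_equal(m2$accuracy, 3 / 4)

  # never-predicted class: precision reported as 0 and flagged
  cm3 <- confusion_matrix(c("a", "b"), c("a", "a"), c("a", "b"))
  m3 <- classification_metrics(cm3)
  expect_equal(m3$by_class$precision[2], 0)
  expect_identical(m3$undefined_precision, "b")
})

test_that("micro-averaged recall equals accuracy on random matrices", {
  set.seed(31)
  for (r in 1:20) {
    K <- sample(2:4, 1)
    truth <- sample(letters[1:K], 60, replace = TRUE)
    pred <- sample(letters[1:K], 60, replace = TRUE)
    cm <- confusion_matrix(truth, pred, letters[1:K])
    m <- classification_metrics(cm)
    micro_recall <- sum(diag(cm$counts)) / sum(cm$counts)
    expect_equal(m$accuracy, micro_recall)
    expect_equal(sum(cm$counts), 60L)
  }
})

test_that("ROC handles the canonical fixtures", {
  r1 <- roc_ovr(cbind(c(0.9, 0.8, 0.7, 0.1)), c("p", "p", "n", "n"),
                c("p"))
  expect_equal(unname(r1$auc["p"]), 1)

  r2 <- roc_ovr(cbind(rep(0.5, 6)), rep(c("p", "n"), 3), "p")
  expect_equal(unname(r2$auc["p"]), 0.5)

  # 3 of 4 concordant pairs
  r3 <- roc_ovr(cbind(c(0.9, 0.4, 0.6, 0.1)), c("p", "p", "n", "n"), "p")
  expect_equal(unname(r3$auc["p"]), 0.75)

  # curves are monotone in both coordinates
  curve <- r3$curves$p
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$tpr) >= 0))
})

test_that("trapezoidal AUC equals exhaustive pair counting, with ties", {
  set.seed(32)
  for (r in 1:30) {
    m <- sample(6:50, 1)
    scores <- round(rnorm(m), sample(0:2, 1))   # coarse rounding forces ties
    truth <- sample(c("p", "n"), m, replace = TRUE)
    if (length(unique(truth)) < 2) next
    auc <- roc_ovr(cbind(scores), truth, "p")$auc[["p"]]
    expect_equal(auc, pair_auc(scores, truth == "p"), tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an independent ROC implementation", {
  set.seed(35)
  scores <- rnorm(40)
  truth <- sample(c("p", "n"), 40, replace = TRUE)
  ours <- roc_ovr(cbind(scores), truth, "p")$auc[["p"]]
  ref <- as.numeric(pROC::auc(pROC::roc(truth == "p", scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("a class absent from truth yields a missing AUC, not zero", {
  r <- roc_ovr(cbind(a = c(1, 0), b = c(0, 1), c = c(0, 0)),
               c("a", "b"), c("a", "b", "c"))
  expect_true(is.na(r$auc[["c"]]))
  expect_false(is.na(r$macro_auc))
})

test_that("cross-validation folds partition the data and reproduce", {
  d <- simulate_dataset(small_sim_config(seed = 6L,
                                         cells = c(HPaSC = 5, iCAF = 5,
                                                   myCAF = 5), pixels = 4L))
  p <- preprocess_dataset(d)
  cv <- cross_validate(p, k = 5, ncomp = 2, seed = 17)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), n_spectra(p))
  expect_equal(tabulate(cv$folds), rep(12L, 5))
  cv2 <- cross_validate(p, k = 5, ncomp = 2, seed = 17)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$accuracy, cv2$accuracy)

  cvc <- cross_validate(p, k = 3, ncomp = 2, mode = "cell", seed = 5)
  for (f in 1:3) {
    in_fold <- unique(p$cell_ids[cvc$folds == f])
    out_fold <- unique(p$cell_ids[cvc$folds != f])
    expect_length(intersect(in_fold, out_fold), 0)
  }
  expect_error(cross_validate(p, k = 7, mode = "cell"), "fewer than k")
})

test_that("noise-free separable classes cross-validate perfectly", {
  grid <- seq(400, 500, by = 10)
  n <- 60
  labels <- rep(c("a", "b", "c"), each = n / 3)
  # each class elevates its own band block: linearly independent class means
  mat <- matrix(rnorm(n * length(grid), sd = 1e-3), n)
  mat[labels == "a", 1:3] <- mat[labels == "a", 1:3] + 5
  mat[labels == "b", 4:6] <- mat[labels == "b", 4:6] + 5
  mat[labels == "c", 7:9] <- mat[labels == "c", 7:9] + 5
  d <- spectral_dataset(grid, mat, labels,
                        paste0(labels, rep(1:10, 6)),
                        class_order = c("a", "b", "c"))
  cv <- cross_validate(d, k = 5, ncomp = 2, seed = 2)
  expect_equal(cv$mean_accuracy, 1)
})

test_that("band statistics reproduce the hand-computed t-test", {
  grid <- seq(1000, 1080, by = 10)
  mat <- matrix(rep(c(1, 2, 3, 4, 5, 6), length(grid)), 6, length(grid))
  d <- spectral_dataset(grid, mat, rep(c("A", "B"), each = 3),
                        paste0("c", 1:6), class_order = c("A", "B"))
  bs <- band_statistics(d, 1040, 2)
  expect_equal(bs$by_class$mean, c(2, 5))
  expect_equal(bs$by_class$sd, c(1, 1))
  expect_equal(bs$tests$t, -3.674, tolerance = 1e-3)
  expect_equal(bs$tests$df, 4)
  expect_equal(bs$tests$p, 0.0213, tolerance = 1e-3)

  same <- spectral_dataset(grid, mat[c(1:3, 1:3), ],
                           rep(c("A", "B"), each = 3), paste0("c", 1:6),
                           class_order = c("A", "B"))
  bs2 <- band_statistics(same, 1040, 2)
  expect_equal(bs2$tests$t, 0)
  expect_equal(bs2$tests$p, 1)

  flat <- spectral_dataset(grid, matrix(5, 6, length(grid)),
                           rep(c("A", "B"), each = 3), paste0("c", 1:6),
                           class_order = c("A", "B"))
  bs3 <- band_statistics(flat, 1040, 2)
  expect_true(bs3$tests$degenerate)
  expect_true(is.na(bs3$tests$p))
})

test_that("count reconstruction inverts a known confusion matrix", {
  counts <- rbind(c(90, 10, 0), c(5, 80, 15), c(0, 5, 95))
  cm <- structure(list(counts = counts, class_order = c("a", "b", "c")),
                  class = "confusion_matrix")
  m <- classification_metrics(cm)
  rec <- reconstruct_test_counts(diag(counts), m$by_class$precision,
                                 m$by_class$recall, c("a", "b", "c"))
  expect_equal(rec$by_class$truth_total, rowSums(counts))
  expect_equal(rec$by_class$predicted_total, colSums(counts))
  expect_equal(rec$total_truth, sum(counts))
  expect_equal(rec$accuracy, m$accuracy)
})
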