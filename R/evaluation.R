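#' Train/test split specification
#'
#' @param test_fraction Fraction of units held out (default 0.3).
#' @param mode `"spectrum"` splits individual spectra stratified by class
#'   (the published protocol; an optimistic upper bound, since pixels of one
#'   cell can land on both sides); `"cell"` assigns whole cells to one side
#'   only and is the honest generalization estimate.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratified Logical; stratify by class (default `TRUE`).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(test_fraction = 0.3, mode = c("spectrum", "cell"),
                       seed = 1L, stratified = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must lie in (0, 1)", call. = FALSE)
  }
  structure(list(test_fraction = test_fraction, mode = mode,
                 seed = as.integer(seed), stratified = stratified),
            class = "split_spec")
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Split a dataset into training and test sets
#'
#' Spectrum mode samples rows within each class (test size rounded to the
#' nearest integer per class); cell mode samples whole cells within each
#' class, so no cell id appears on both sides.
#'
#' @param dataset A [spectral_dataset()].
#' @param spec A [split_spec()].
#' @return List with elements `train` and `test`, both `spectral_dataset`s.
#' @export
split_dataset <- function(dataset, spec = split_spec()) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(spec, "split_spec"))
  with_seed(spec$seed, {
    test_idx <- integer(0)
    groups <- if (spec$stratified) dataset$class_order else "all"
    for (g in groups) {
      rows <- if (spec$stratified) which(dataset$labels == g)
              else seq_len(n_spectra(dataset))
      if (spec$mode == "spectrum") {
        n_test <- round(length(rows) * spec$test_fraction)
        test_idx <- c(test_idx, sample(rows, n_test))
      } else {
        cells <- unique(dataset$cell_ids[rows])
        if (length(cells) < 2L) {
          stop("split error: class '", g,
               "' has fewer than 2 cells for cell-mode splitting",
               call. = FALSE)
        }
        n_test <- max(1L, round(length(cells) * spec$test_fraction))
        test_cells <- sample(cells, n_test)
        test_idx <- c(test_idx, rows[dataset$cell_ids[rows] %in% test_cells])
      }
    }
    test_idx <- sort(test_idx)
    list(train = subset_rows(dataset, setdiff(seq_len(n_spectra(dataset)),
                                              test_idx)),
         test = subset_rows(dataset, test_idx))
  })
}

#' Confusion matrix
#'
#' @param truth,predicted Equal-length label vectors.
#' @param class_order Ordered class set covering every label.
#' @return An object of class `confusion_matrix`: integer `K x K` counts,
#'   rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, class_order) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted lengths differ", call. = FALSE)
  }
  bad <- setdiff(unique(c(truth, predicted)), class_order)
  if (length(bad)) {
    stop("labels not in class_order: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(truth, levels = class_order),
                  factor(predicted, levels = class_order))
  counts <- matrix(as.integer(counts), nrow = length(class_order),
                   dimnames = list(truth = class_order,
                                   predicted = class_order))
  structure(list(counts = counts, class_order = class_order),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = truth, columns = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' Per-class precision, recall, F1 and overall accuracy
#'
#' `precision_k = diag_k / colsum_k`, `recall_k = diag_k / rowsum_k`,
#' `F1_k = 2PR/(P+R)`, `accuracy = trace / total`. A class never predicted
#' (zero column sum) gets precision 0 and is flagged in
#' `undefined_precision`.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `class_metrics` with a per-class data.frame
#'   (`by_class`) and `accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  counts <- cm$counts
  if (sum(counts) == 0) stop("empty confusion matrix", call. = FALSE)
  d <- diag(counts)
  colsum <- colSums(counts); rowsum <- rowSums(counts)
  precision <- ifelse(colsum > 0, d / colsum, 0)
  recall <- ifelse(rowsum > 0, d / rowsum, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    by_class = data.frame(class = cm$class_order, precision = precision,
                          recall = recall, f1 = f1, row.names = NULL),
    accuracy = sum(d) / sum(counts),
    undefined_precision = cm$class_order[colsum == 0]
  ), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat("<class_metrics> accuracy =", format(x$accuracy, digits = 4), "\n")
  print(x$by_class, digits = 4)
  invisible(x)
}

# single one-vs-rest ROC curve: returns fpr/tpr step points and trapezoidal
# AUC (tie-grouped, so equal scores contribute diagonal segments and the
# trapezoid equals the tie-adjusted Mann-Whitney probability)
roc_curve_binary <- function(scores, positive) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  # group ties: one ROC vertex per distinct score
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  P <- sum(positive); N <- sum(!positive)
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, the continuous response column for that class scores the
#' class-vs-rest problem; AUC is computed by the trapezoidal rule on the
#' tie-grouped ROC curve, which equals the tie-adjusted Mann-Whitney
#' concordance probability. Classes absent from `truth` get no curve and a
#' missing AUC (excluded from the macro average).
#'
#' @param scores Numeric `m x K` continuous score matrix (columns in
#'   `class_order`), e.g. from [predict_response()].
#' @param truth Length-`m` label vector.
#' @param class_order Ordered class set.
#' @return An object of class `roc_result`: per-class `curves`
#'   (fpr/tpr data.frames), per-class `auc`, and `macro_auc` (unweighted
#'   mean over classes present in truth).
#' @export
roc_ovr <- function(scores, truth, class_order) {
  scores <- as.matrix(scores)
  truth <- as.character(truth)
  if (nrow(scores) != length(truth)) {
    stop("scores rows and truth length differ", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (ncol(scores) != length(class_order)) {
    stop("scores must have one column per class", call. = FALSE)
  }
  curves <- list(); auc <- stats::setNames(rep(NA_real_, length(class_order)),
                                           class_order)
  for (k in seq_along(class_order)) {
    pos <- truth == class_order[k]
    if (!any(pos) || all(pos)) next   # class absent: AUC undefined
    rc <- roc_curve_binary(scores[, k], pos)
    curves[[class_order[k]]] <- data.frame(fpr = rc$fpr, tpr = rc$tpr)
    auc[k] <- rc$auc
  }
  structure(list(curves = curves, auc = auc,
                 macro_auc = mean(auc, na.rm = TRUE)),
            class = "roc_result")
}

#' Stratified k-fold cross-validation of the PLS-DA pipeline
#'
#' Partitions the dataset into `k` disjoint folds (stratified by class;
#' spectrum or cell mode as in [split_dataset()]), fits a PLS-DA model on
#' each training remainder and evaluates on the held-out fold.
#'
#' @param dataset A preprocessed [spectral_dataset()].
#' @param k Number of folds (default 5).
#' @param ncomp PLS components (default 2).
#' @param mode `"spectrum"` or `"cell"` fold assignment.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_report`: `fold_metrics` (list of
#'   [classification_metrics()] results), `accuracy` per fold,
#'   `mean_accuracy`, `sd_accuracy`, and the fold assignment `folds`.
#' @export
cross_validate <- function(dataset, k = 5, ncomp = 2,
                           mode = c("spectrum", "cell"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  n <- n_spectra(dataset)
  folds <- integer(n)
  with_seed(seed, {
    for (g in dataset$class_order) {
      rows <- which(dataset$labels == g)
      if (mode == "spectrum") {
        if (length(rows) < k) {
          stop("class '", g, "' has fewer than k spectra", call. = FALSE)
        }
        folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
      } else {
        cells <- unique(dataset$cell_ids[rows])
        if (length(cells) < k) {
          stop("class '", g, "' has fewer than k cells", call. = FALSE)
        }
        cell_fold <- stats::setNames(sample(rep_len(seq_len(k),
                                                    length(cells))), cells)
        folds[rows] <- cell_fold[dataset$cell_ids[rows]]
      }
    }
  })
  fold_metrics <- vector("list", k)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    train <- subset_rows(dataset, folds != f)
    test <- subset_rows(dataset, folds == f)
    model <- fit_plsda_dataset(train, ncomp = ncomp)
    pred <- classify(model, test)
    m <- classification_metrics(
      confusion_matrix(test$labels, pred, dataset$class_order))
    fold_metrics[[f]] <- m
    acc[f] <- m$accuracy
  }
  structure(list(k = k, folds = folds, fold_metrics = fold_metrics,
                 accuracy = acc, mean_accuracy = mean(acc),
                 sd_accuracy = stats::sd(acc)),
            class = "cv_report")
}

#' Per-band class statistics with pairwise two-sample t-tests
#'
#' Computes each spectrum's mean intensity over the closed band
#' `center +/- half_width`, then per-class mean, SD and n, plus pairwise
#' independent two-sample t-tests (equal-variance Student's by default,
#' Welch via `welch = TRUE`), two-sided. Pairs in which both groups have
#' zero variance are reported as degenerate (`NA` statistics), not as
#' p = 0.
#'
#' @param dataset A preprocessed [spectral_dataset()].
#' @param center Band center in cm^-1.
#' @param half_width Band half-width in cm^-1 (default 2).
#' @param welch Use Welch's unequal-variance t-test (default `FALSE`).
#' @return An object of class `band_stats`: `center`, `half_width`,
#'   `by_class` (mean/sd/n per class) and `tests` (pairwise t, df, p).
#' @export
band_statistics <- function(dataset, center, half_width = 2, welch = FALSE) {
  v <- band_values(dataset, center, half_width)
  cls <- dataset$class_order
  by_class <- data.frame(
    class = cls,
    mean = vapply(cls, function(k) mean(v[dataset$labels == k]), numeric(1)),
    sd = vapply(cls, function(k) stats::sd(v[dataset$labels == k]), numeric(1)),
    n = vapply(cls, function(k) sum(dataset$labels == k), integer(1)),
    row.names = NULL
  )
  if (any(by_class$n < 2)) {
    stop("every class needs n >= 2 spectra for band statistics", call. = FALSE)
  }
  pairs <- utils::combn(cls, 2)
  tests <- data.frame(class_a = pairs[1, ], class_b = pairs[2, ],
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      degenerate = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- v[dataset$labels == pairs[1, i]]
    b <- v[dataset$labels == pairs[2, i]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tests$degenerate[i] <- TRUE
      next
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    tests$t[i] <- unname(tt$statistic)
    tests$df[i] <- unname(tt$parameter)
    tests$p[i] <- tt$p.value
  }
  structure(list(center = center, half_width = half_width,
                 by_class = by_class, tests = tests, welch = welch),
            class = "band_stats")
}

#' Reconstruct test-set class totals from published precision/recall
#'
#' Given per-class correct prediction counts together with the rounded
#' precision and recall of a confusion matrix, recovers the implied per-class
#' truth totals (`correct / recall`), predicted totals
#' (`correct / precision`), the grand total and the overall accuracy. Useful
#' as an internal-consistency check of a reported classification table when
#' the per-class test sizes themselves are not printed.
#'
#' @param correct Integer vector of per-class correct (diagonal) counts.
#' @param precision,recall Numeric vectors of per-class precision and recall.
#' @param classes Optional class names.
#' @return List with `by_class` (truth/predicted totals per class),
#'   `total_truth`, `total_predicted` (each the rounded column sum),
#'   `accuracy` (= sum(correct) / total_truth) and recomputed `f1`.
#' @export
reconstruct_test_counts <- function(correct, precision, recall,
                                    classes = NULL) {
  stopifnot(length(correct) == length(precision),
            length(correct) == length(recall),
            all(precision > 0), all(recall > 0))
  truth_totals <- round(correct / recall)
  pred_totals <- round(correct / precision)
  f1 <- 2 * precision * recall / (precision + recall)
  list(
    by_class = data.frame(
      class = if (is.null(classes)) seq_along(correct) else classes,
      correct = correct, truth_total = truth_totals,
      predicted_total = pred_totals, f1 = f1, row.names = NULL),
    total_truth = sum(truth_totals),
    total_predicted = sum(pred_totals),
    accuracy = sum(correct) / sum(truth_totals),
    f1 = f1
  )
}
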