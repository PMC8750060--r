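#' Confusion-matrix metrics for binary EEG classification
#'
#' The positive class is MDD (label 1): sensitivity = TP/(TP+FN) is the true
#' positive rate among MDD segments, specificity = TN/(TN+FP) among healthy
#' segments, accuracy = (TP+TN)/total.
#'
#' @param y_true,y_pred Equal-length 0/1 vectors.
#' @return List with `tp`, `fp`, `tn`, `fn`, `accuracy`, `sensitivity`,
#'   `specificity`. A metric whose denominator is zero (single-class
#'   `y_true`) is returned as `NA` with a warning.
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("`y_true` and `y_pred` must have equal length", call. = FALSE)
  }
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  sens <- if (tp + fn == 0) {
    warning("no positive cases in y_true; sensitivity undefined", call. = FALSE)
    NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative cases in y_true; specificity undefined", call. = FALSE)
    NA_real_
  } else tn / (tn + fp)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       accuracy = (tp + tn) / length(y_true),
       sensitivity = sens, specificity = spec)
}

#' ROC curve and AUC
#'
#' AUC is the probability that a random positive outscores a random negative,
#' ties counting one half (the Mann-Whitney statistic). Computed through
#' pROC with a fixed direction (higher score = positive class), so inverted
#' labels give AUC 0, not 0.5.
#'
#' @param y_true 0/1 labels (both classes present).
#' @param scores Numeric classifier scores.
#' @return List with `auc` and `curve` (data.frame of fpr, tpr from (0,0)
#'   to (1,1)).
#' @export
roc_auc <- function(y_true, scores) {
  if (length(unique(y_true)) < 2L) {
    stop("both classes must be present in `y_true`", call. = FALSE)
  }
  if (max(scores) == min(scores)) {
    warning("constant scores; AUC is 0.5 by convention", call. = FALSE)
    return(list(auc = 0.5,
                curve = data.frame(fpr = c(0, 1), tpr = c(0, 1))))
  }
  r <- pROC::roc(response = y_true, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  list(auc = as.numeric(r$auc), curve = curve)
}

segment_labels <- function(segments) {
  vapply(segments, function(s) s$class_label, integer(1))
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Segments of the training subjects are assigned to `k` stratified folds
#' (class balance preserved per fold, deterministic given `seed`). Each fold
#' is held out once while a model is trained on the rest; per-fold accuracy,
#' sensitivity and specificity are recorded. A final model trained on the
#' full training set is then evaluated once on the held-out test subjects.
#'
#' @param split A `dataset_split` from [split_by_subject()].
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param k Number of folds (>= 2, default 5).
#' @param seed Seed for fold assignment.
#' @param input_shape Passed to [build_model()].
#' @return An object of class `performance_report`: per-fold metric lists,
#'   mean and SD of each metric, the final test-set metrics, confusion
#'   counts, and AUC on the test set.
#' @export
cross_validate <- function(split, model_cfg = model_config(),
                           train_cfg = train_config(), k = 5L, seed = 1L,
                           input_shape = c(20L, 32L, 32L)) {
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  segs <- split$train
  y <- segment_labels(segs)
  if (min(table(y)) < k) {
    stop("not enough samples per class for the requested folds", call. = FALSE)
  }
  fold <- integer(length(segs))
  for (cl in unique(y)) {
    ids <- which(y == cl)
    ids <- with_seed(derive_seed(seed, 100L + cl), sample(ids))
    fold[ids] <- rep(seq_len(k), length.out = length(ids))
  }
  per_fold <- data.frame(fold = seq_len(k), accuracy = NA_real_,
                         sensitivity = NA_real_, specificity = NA_real_)
  for (f in seq_len(k)) {
    tr <- segs[fold != f]
    va <- segs[fold == f]
    m <- build_model(model_cfg, input_shape)
    m <- train_model(m, structure(list(train = tr, test = va),
                                  class = "dataset_split"), train_cfg)
    pred <- predict(m, va)
    cm <- confusion_metrics(pred$class_label, pred$label)
    per_fold$accuracy[f] <- cm$accuracy
    per_fold$sensitivity[f] <- cm$sensitivity
    per_fold$specificity[f] <- cm$specificity
  }
  final <- build_model(model_cfg, input_shape)
  final <- train_model(final, split, train_cfg)
  pred_test <- predict(final, split$test)
  cm <- confusion_metrics(pred_test$class_label, pred_test$label)
  auc <- roc_auc(pred_test$class_label, pred_test$probability)$auc
  structure(
    list(
      per_fold = per_fold,
      accuracy = mean(per_fold$accuracy), accuracy_sd = stats::sd(per_fold$accuracy),
      sensitivity = mean(per_fold$sensitivity),
      sensitivity_sd = stats::sd(per_fold$sensitivity),
      specificity = mean(per_fold$specificity),
      specificity_sd = stats::sd(per_fold$specificity),
      test = cm, test_auc = auc, model = final
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    paste0("<performance_report> %d folds\n",
           "  accuracy    %.4f (SD %.4f)\n",
           "  sensitivity %.4f (SD %.4f)\n",
           "  specificity %.4f (SD %.4f)\n",
           "  test: accuracy %.4f, AUC %.4f\n"),
    nrow(x$per_fold), x$accuracy, x$accuracy_sd, x$sensitivity,
    x$sensitivity_sd, x$specificity, x$specificity_sd,
    x$test$accuracy, x$test_auc
  ))
  invisible(x)
}

#' Pairwise Welch t-test p-value matrix
#'
#' Welch (unequal-variance) two-sample t-tests between every pair of
#' approaches on a per-fold metric. The matrix is symmetric; the diagonal is
#' `NA` (a self-comparison carries no information). If both samples have
#' zero variance, p is 1 when the means agree and 0 otherwise, by
#' convention.
#'
#' @param metric_lists Named list: approach -> numeric vector of per-fold
#'   metric values (each of length >= 2).
#' @param metric Label of the metric being compared (metadata only).
#' @return An object of class `pvalue_matrix` containing the symmetric
#'   matrix and approach labels.
#' @export
pvalue_matrix <- function(metric_lists, metric = "accuracy") {
  if (length(metric_lists) < 2L) {
    stop("need at least two approaches", call. = FALSE)
  }
  if (any(lengths(metric_lists) < 2L)) {
    stop("each approach needs >= 2 fold values", call. = FALSE)
  }
  k <- length(metric_lists)
  labs <- names(metric_lists)
  if (is.null(labs)) labs <- paste0("approach", seq_len(k))
  m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      a <- metric_lists[[i]]; b <- metric_lists[[j]]
      p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        stats::t.test(a, b, var.equal = FALSE)$p.value
      }
      m[i, j] <- p
      m[j, i] <- p
    }
  }
  structure(list(approaches = labs, matrix = m, metric = metric),
            class = "pvalue_matrix")
}

#' @export
print.pvalue_matrix <- function(x, ...) {
  cat(sprintf("<pvalue_matrix> metric: %s\n", x$metric))
  print(round(x$matrix, 4))
  invisible(x)
}
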