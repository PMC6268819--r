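# Confusion-matrix metrics (potent = positive class) and the repeated
# tenfold cross-validation harness shared by the three classifiers.

#' Classification metrics from confusion counts
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), rate of correct
#' classification (tp+tn)/total, and the complementary type I
#' (1 - specificity) and type II (1 - sensitivity) error rates. A zero
#' denominator yields NA for the affected metric.
#'
#' @param tp,fp,tn,fn non-negative confusion counts; potent is positive.
#' @return named numeric vector with `sensitivity`, `specificity`,
#'   `correct`, `type_i_error`, `type_ii_error`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(sensitivity = sens, specificity = spec,
    correct = (tp + tn) / (tp + fp + tn + fn),
    type_i_error = 1 - spec, type_ii_error = 1 - sens)
}

#' Confusion counts from predicted and true labels
#' @param predicted,truth vectors of `"P"`/`"W"`.
#' @return named integer vector `c(tp, fp, tn, fn)`.
#' @export
confusion_counts <- function(predicted, truth) {
  c(tp = sum(predicted == "P" & truth == "P"),
    fp = sum(predicted == "P" & truth == "W"),
    tn = sum(predicted == "W" & truth == "W"),
    fn = sum(predicted == "W" & truth == "P"))
}

#' Repeated k-fold cross-validation
#'
#' Randomly partitions the compounds into `k` folds (unstratified by
#' default, matching a plain random division; optionally stratified by
#' class), then for each fold trains on the remaining 9/10ths from scratch
#' and evaluates both the training (split) fit and the held-out fold. No
#' information is carried between folds or repeats. If a training fold
#' loses a class entirely the partition is redrawn once, then it is an
#' error.
#'
#' @param x feature object passed to the trainer (matrix or data.frame,
#'   rows = compounds).
#' @param labels `"P"`/`"W"` per row.
#' @param trainer `function(x_train, labels_train)` returning a model.
#' @param predictor `function(model, x_new)` returning `"P"`/`"W"` calls.
#' @param k number of folds.
#' @param repeats number of independent random partitions.
#' @param seed RNG seed (full determinism for deterministic trainers).
#' @param stratified preserve class proportions across folds?
#' @return list of class `"cv_report"`: `split` and `heldout`, each a list
#'   with `mean` and `sd` of the metric vector over all folds x repeats,
#'   plus `per_fold` data.frame.
#' @export
kfold_cv <- function(x, labels, trainer, predictor, k = 10, repeats = 1,
                     seed = 1, stratified = FALSE) {
  labels <- .check_labels(labels)
  n <- nrow(x)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- NULL
    for (attempt in 1:2) {
      fold_try <- if (stratified) {
        f <- integer(n)
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          f[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        f
      } else {
        sample(rep_len(seq_len(k), n))
      }
      ok <- all(vapply(seq_len(k), function(j)
        nlevels(droplevels(labels[fold_try != j])) == 2, TRUE))
      if (ok) {
        fold <- fold_try
        break
      }
    }
    if (is.null(fold)) stop("a training fold lost a class even after ",
                            "resampling; use stratified = TRUE")
    for (j in seq_len(k)) {
      train_idx <- which(fold != j)
      test_idx <- which(fold == j)
      model <- trainer(x[train_idx, , drop = FALSE], labels[train_idx])
      pred_train <- predictor(model, x[train_idx, , drop = FALSE])
      pred_test <- predictor(model, x[test_idx, , drop = FALSE])
      m_train <- confusion_metrics2(pred_train, labels[train_idx])
      m_test <- confusion_metrics2(pred_test, labels[test_idx])
      rows[[length(rows) + 1]] <- data.frame(
        repeat_i = rep_i, fold = j, scope = c("split", "heldout"),
        rbind(m_train, m_test), row.names = NULL)
    }
  }
  per_fold <- do.call(rbind, rows)
  summarize <- function(scope) {
    sub <- per_fold[per_fold$scope == scope,
                    c("sensitivity", "specificity", "correct",
                      "type_i_error", "type_ii_error")]
    list(mean = colMeans(sub, na.rm = TRUE),
         sd = apply(sub, 2, stats::sd, na.rm = TRUE))
  }
  structure(list(split = summarize("split"),
                 heldout = summarize("heldout"),
                 per_fold = per_fold, k = k, repeats = repeats,
                 seed = seed, stratified = stratified),
            class = "cv_report")
}

# metrics from label vectors (NA-safe for single-class held-out folds)
confusion_metrics2 <- function(predicted, truth) {
  cc <- confusion_counts(predicted, truth)
  confusion_metrics(cc[["tp"]], cc[["fp"]], cc[["tn"]], cc[["fn"]])
}
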