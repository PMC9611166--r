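# Classification metrics: confusion counts, recall/precision/accuracy and
# rank-based AUC (Mann-Whitney with tied scores contributing 1/2).

#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic:
#' average ranks are used, so tied scores contribute 1/2. Equals 1 for
#' perfectly separated scores and 0.5 when every score is identical.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, same length.
#' @return AUC in [0, 1], or NA if only one class is present.
#' @export
auc_rank <- function(labels, scores) {
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics at a probability cutoff
#'
#' Counts the confusion matrix at \code{threshold} and reports recall
#' (TP / (TP + FN)), precision (TP / (TP + FP)), accuracy
#' ((TP + TN) / total) and rank-based AUC. A metric whose denominator is
#' zero is reported as NA rather than 0.
#'
#' @param labels 0/1 vector of observed labels.
#' @param probs Predicted probabilities.
#' @param threshold Cutoff; predictions \code{>= threshold} are positive.
#' @return A \code{gcn_metrics} list: \code{tp, fp, tn, fn, recall,
#'   precision, acc, auc, threshold, n}.
#' @export
classification_metrics <- function(labels, probs, threshold = 0.5) {
  stopifnot(length(labels) == length(probs), length(labels) > 0L)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    acc = (tp + tn) / length(labels),
    auc = auc_rank(labels, probs),
    threshold = threshold, n = length(labels)
  ), class = "gcn_metrics")
}

#' @export
print.gcn_metrics <- function(x, ...) {
  cat(sprintf("n=%d  TP=%d FP=%d TN=%d FN=%d\n", x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  Acc %.4f  Precision %s  Recall %s  AUC %s\n",
              x$acc,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              ifelse(is.na(x$recall), "NA", sprintf("%.4f", x$recall)),
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Evaluate a fitted model on a labeled pair dataset
#'
#' @param object A fitted \code{cocrystal_gcn}.
#' @param ds A \code{pair_dataset}.
#' @param threshold Classification cutoff (default 0.5).
#' @return A \code{gcn_metrics} list (see [classification_metrics()]).
#' @export
evaluate_model <- function(object, ds, threshold = 0.5) {
  if (nrow(ds) == 0L) stop_ccg("empty evaluation set")
  probs <- predict(object, ds)
  classification_metrics(ds$label, probs, threshold)
}

#' Cross-validate CocrystalGCN with repeated random resplits
#'
#' Runs \code{k} independent train/validation/test resplits (8:1:1 by
#' default), trains a model on each training set with best-validation-AUC
#' checkpointing, and reports per-fold and mean metrics on the validation
#' and test sets.
#'
#' @param ds A labeled \code{pair_dataset}.
#' @param k Number of folds.
#' @param control A [gcn_control()].
#' @param seed Master seed; per-fold seeds are derived from it.
#' @param threshold Classification cutoff.
#' @param verbose Print per-fold progress.
#' @return A \code{gcn_cv} object: data frame \code{folds} (one row per
#'   fold, AUC/Acc/Precision/Recall for validation and test) and the
#'   \code{mean} row.
#' @export
cross_validate <- function(ds, k = 10L, control = gcn_control(), seed = 1L,
                           threshold = 0.5, verbose = FALSE) {
  splits <- kfold_splits(ds, k, seed = seed)
  rows <- lapply(seq_len(k), function(i) {
    sp <- splits[[i]]
    fit <- cocrystal_gcn(sp$train, sp$val, control = control,
                         seed = derive_seed(seed, 500L + i))
    mv <- evaluate_model(fit, sp$val, threshold)
    mt <- evaluate_model(fit, sp$test, threshold)
    if (verbose) {
      message(sprintf("fold %d: val AUC %.3f, test AUC %.3f", i, mv$auc, mt$auc))
    }
    data.frame(fold = i,
               val_auc = mv$auc, val_acc = mv$acc,
               val_precision = mv$precision, val_recall = mv$recall,
               test_auc = mt$auc, test_acc = mt$acc,
               test_precision = mt$precision, test_recall = mt$recall)
  })
  folds <- do.call(rbind, rows)
  mean_row <- colMeans(folds[, -1, drop = FALSE], na.rm = TRUE)
  structure(list(folds = folds, mean = mean_row, k = k, control = control),
            class = "gcn_cv")
}

#' @export
print.gcn_cv <- function(x, ...) {
  cat("CocrystalGCN ", x$k, "-fold cross-validation\n", sep = "")
  print(round(x$folds, 4), row.names = FALSE)
  cat("mean:\n")
  print(round(x$mean, 4))
  invisible(x)
}

#' Write a cross-validation report to CSV
#'
#' One row per fold plus a final \code{mean} row, with AUC, accuracy,
#' precision and recall for the validation and test sets.
#'
#' @param cv A \code{gcn_cv} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  df <- cv$folds
  mean_df <- data.frame(fold = "mean", t(cv$mean))
  df$fold <- as.character(df$fold)
  write.csv(rbind(df, mean_df), path, row.names = FALSE)
  invisible(path)
}
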