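#' Confusion-matrix counts with malignant as the positive class
#'
#' @param truth,pred character vectors of `"benign"` / `"malignant"`.
#' @return named integer vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  c(TP = sum(truth == "malignant" & pred == "malignant"),
    FP = sum(truth == "benign" & pred == "malignant"),
    TN = sum(truth == "benign" & pred == "benign"),
    FN = sum(truth == "malignant" & pred == "benign"))
}

#' Area under the ROC curve of the malignant score
#'
#' Trapezoidal area under the ROC built from the unique score thresholds;
#' ties are handled by grouping equal scores, which makes the result equal
#' the Mann-Whitney statistic with ties counted one half.
#'
#' @param score numeric malignant scores.
#' @param truth character labels.
#' @return AUC in \[0, 1\], or `NA` (with a warning) when a class is absent.
#' @export
auc_roc <- function(score, truth) {
  pos <- truth == "malignant"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]; p <- pos[ord]
  # group tied scores so that each threshold adds one ROC vertex
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

f1_one_class <- function(tp, fp, fn) {
  den <- 2 * tp + fp + fn
  if (den == 0) return(NA_real_)
  2 * tp / den
}

#' Metric suite for one prediction set
#'
#' Accuracy, sensitivity (malignant recall), specificity (benign recall),
#' macro F1 (unweighted mean of the per-class F1 scores) and AUC of the
#' malignant score, plus the confusion counts. Metrics with a zero
#' denominator are reported as `NA` with a warning rather than 0.
#'
#' @param predictions data.frame with columns `truth`, `pred` and `score`
#'   (malignant probability in \[0, 1\]); one row per test sample.
#' @return a `metrics_report` list.
#' @export
compute_metrics <- function(predictions) {
  stopifnot(is.data.frame(predictions), nrow(predictions) > 0,
            all(c("truth", "pred", "score") %in% names(predictions)))
  if (any(predictions$score < 0 | predictions$score > 1)) {
    stop_data("scores must lie in [0, 1]")
  }
  cm <- confusion_counts(predictions$truth, predictions$pred)
  tp <- cm[["TP"]]; fp <- cm[["FP"]]; tn <- cm[["TN"]]; fn <- cm[["FN"]]
  n <- tp + fp + tn + fn
  sn <- if (tp + fn == 0) {
    warning("sensitivity undefined: no malignant samples"); NA_real_
  } else tp / (tp + fn)
  sp <- if (tn + fp == 0) {
    warning("specificity undefined: no benign samples"); NA_real_
  } else tn / (tn + fp)
  f1m <- mean(c(f1_one_class(tp, fp, fn),       # malignant
                f1_one_class(tn, fn, fp)))      # benign
  auc <- suppressWarnings(auc_roc(predictions$score, predictions$truth))
  if (is.na(auc)) warning("AUC undefined: only one class present")
  structure(list(acc = (tp + tn) / n, f1_macro = f1m, sn = sn, sp = sp,
                 auc = auc, confusion = cm, n = n,
                 predictions = predictions),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  F1 %.2f%%  SN %.2f%%  SP %.2f%%  AUC %.3f  (n = %d)\n",
              100 * x$acc, 100 * x$f1_macro, 100 * x$sn, 100 * x$sp,
              x$auc, x$n))
  invisible(x)
}

#' Aggregate per-fold metric reports
#'
#' Two aggregation modes are emitted side by side: `mean` (unweighted mean of
#' the per-fold metrics, undefined folds excluded with a count) and `pooled`
#' (all test predictions concatenated, metrics computed once).
#'
#' @param reports list of `metrics_report` objects.
#' @return list with `mean`, `pooled` and `n_excluded` (per-metric count of
#'   folds excluded from the mean).
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(length(reports) >= 1)
  metrics <- c("acc", "f1_macro", "sn", "sp", "auc")
  vals <- sapply(metrics, function(m) {
    vapply(reports, function(r) r[[m]], 0)
  })
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  mean_mode <- colMeans(vals, na.rm = TRUE)
  n_excl <- colSums(is.na(vals))
  pooled_preds <- do.call(rbind, lapply(reports, `[[`, "predictions"))
  pooled <- suppressWarnings(compute_metrics(pooled_preds))
  list(mean = as.list(mean_mode), pooled = pooled,
       n_excluded = as.list(n_excl))
}
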