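# Evaluation metrics: confusion-matrix summaries and the rank-sum AUC.

#' Confusion-matrix metrics
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 from binary
#' labels and predictions. Empty denominators yield 0 and set the
#' `degenerate` flag.
#'
#' @param labels binary ground-truth vector.
#' @param predictions binary predicted vector of the same length.
#' @return list of class `MetricsReport` with counts and fractions.
#' @export
confusion_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stopf("labels (%d) and predictions (%d) differ in length",
          length(labels), length(predictions))
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stopf("labels and predictions must be binary")
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  degenerate <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      return(0)
    }
    num / den
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = safe_div(tp + tn, tp + tn + fp + fn),
                 precision = precision, recall = recall,
                 specificity = safe_div(tn, tn + fp),
                 f1 = safe_div(2 * precision * recall, precision + recall),
                 degenerate = degenerate),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("<MetricsReport> TP=%d TN=%d FP=%d FN=%d\n", x$tp, x$tn, x$fp,
              x$fn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  specificity %.4f  F1 %.4f%s\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1,
              if (!is.null(x$auc) && !is.na(x$auc))
                sprintf("  AUC %.4f", x$auc) else ""))
  invisible(x)
}

#' Rank-sum AUC
#'
#' Area under the ROC curve via the rank-sum identity
#' `AUC = (sum of positive ranks - P(P+1)/2) / (P * N)` with average ranks for
#' ties; equals the pairwise concordance probability with ties counted 1/2.
#'
#' @param scores numeric score vector.
#' @param labels binary label vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stopf("AUC undefined: need at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}
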