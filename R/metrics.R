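# Sequence-level evaluation: confusion counts, the four headline metrics
# and ROC/AUC. Malignant is the positive class throughout.

#' Confusion counts for benign/malignant labels
#'
#' @param truth,predicted Character vectors of `"benign"`/`"malignant"`
#'   labels of equal, nonzero length. Malignant is the positive class.
#' @return A list with integer fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) == 0L) stop("empty label vectors", call. = FALSE)
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have equal length", call. = FALSE)
  }
  truth <- normalize_label(truth)
  predicted <- normalize_label(predicted)
  list(
    tp = sum(truth == "malignant" & predicted == "malignant"),
    tn = sum(truth == "benign" & predicted == "benign"),
    fp = sum(truth == "benign" & predicted == "malignant"),
    fn = sum(truth == "malignant" & predicted == "benign")
  )
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' recall = TP/(TP+FN); F1 = TP/(TP + (FP+FN)/2). A metric whose
#' denominator is zero is reported as `NA` with its `*_defined` flag set to
#' FALSE rather than silently coerced to 0.
#'
#' @param counts A list with fields `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return One-row tibble with the four metrics and their `_defined` flags.
#' @export
classification_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp + tn + fp + fn >= 1)
  safe_div <- function(num, den) {
    if (den == 0) list(value = NA_real_, defined = FALSE)
    else list(value = num / den, defined = TRUE)
  }
  acc <- safe_div(tp + tn, tp + tn + fp + fn)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1s <- safe_div(tp, tp + 0.5 * (fp + fn))
  tibble::tibble(
    accuracy = acc$value, precision = prec$value,
    recall = rec$value, f1 = f1s$value,
    accuracy_defined = acc$defined, precision_defined = prec$defined,
    recall_defined = rec$defined, f1_defined = f1s$defined
  )
}

#' Area under the ROC curve
#'
#' Computed as the normalized Wilcoxon rank-sum statistic: the probability
#' that a randomly chosen malignant sequence scores higher than a randomly
#' chosen benign one, with ties contributing 1/2. This equals trapezoidal
#' integration of the ROC curve over all thresholds.
#'
#' @param scores Numeric malignancy scores.
#' @param truth Character labels (`"benign"`/`"malignant"`); both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  truth <- normalize_label(truth)
  if (length(scores) != length(truth)) {
    stop("`scores` and `truth` must have equal length", call. = FALSE)
  }
  pos <- truth == "malignant"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a set of scored sequences
#'
#' @param results Data frame with columns `label` (truth),
#'   `predicted_label` and `pooled_score` — e.g. row-bound
#'   [glance.malignancy_result()] outputs.
#' @return One-row tibble with confusion counts, the four metrics, their
#'   defined-ness flags, `auc` and `n`.
#' @export
evaluate_sequences <- function(results) {
  stopifnot(all(c("label", "predicted_label", "pooled_score") %in% names(results)))
  counts <- confusion_counts(results$label, results$predicted_label)
  metrics <- classification_metrics(counts)
  auc <- if (length(unique(normalize_label(results$label))) == 2L) {
    roc_auc(results$pooled_score, results$label)
  } else {
    NA_real_
  }
  dplyr::bind_cols(
    tibble::tibble(
      n = nrow(results),
      tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn
    ),
    metrics,
    tibble::tibble(auc = auc)
  )
}
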