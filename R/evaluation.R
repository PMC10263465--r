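# Classification metrics used to compare immunogenicity predictors:
# sensitivity and F1 at a probability threshold, the TopK positive
# proportion, and rank-based ROC/AUC.

check_scores_labels <- function(scores, labels) {
  stopifnot(is.numeric(scores), length(scores) == length(labels),
            length(scores) > 0)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (anyNA(scores)) stop("scores contain NA")
  invisible(TRUE)
}

#' Sensitivity (true-positive rate) at a threshold
#'
#' Scores at or above `threshold` are called positive; returns
#' TP / (TP + FN).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 truth labels, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return Value in `[0, 1]`.
#' @export
sensitivity <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels)
  if (sum(labels == 1) == 0) stop("sensitivity: no positive labels")
  pred <- scores >= threshold
  sum(pred & labels == 1) / sum(labels == 1)
}

#' F1 score at a threshold
#'
#' Harmonic mean of precision and recall; by convention 0 when there are
#' no true positives (covers the degenerate no-predicted-positive and
#' no-positive cases).
#'
#' @inheritParams sensitivity
#' @return Value in `[0, 1]`.
#' @export
f1 <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1)
  if (tp == 0) return(0)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  2 * tp / (2 * tp + fp + fn)
}

#' TopK positive proportion
#'
#' Proportion of true positives among the `k` highest-scoring instances.
#' The sort is stable: tied scores keep input order.
#'
#' @inheritParams sensitivity
#' @param k Number of top instances, `1 <= k <= length(scores)`.
#' @return Value in `[0, 1]`.
#' @export
topk <- function(scores, labels, k) {
  check_scores_labels(scores, labels)
  if (k < 1 || k > length(scores)) stop("topk: k out of range")
  ord <- order(-scores)  # order() is stable: ties keep input order
  mean(labels[ord[seq_len(k)]] == 1)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney concordance probability: the chance a random positive
#' outscores a random negative, with ties counted one half.
#'
#' @inheritParams sensitivity
#' @return Value in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("roc_auc: both classes required")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' False/true-positive rates over all score thresholds (each distinct
#' score, descending), suitable for CSV export or plotting.
#'
#' @inheritParams sensitivity
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  check_scores_labels(scores, labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("roc_points: both classes required")
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & labels == 0) / nneg,
               tpr = sum(pred & labels == 1) / npos)
  }))
}

#' Compute the full metric panel
#'
#' @inheritParams sensitivity
#' @param k Vector of K values for the TopK metric (entries above the
#'   sample size are skipped).
#' @return One-row data frame: `auc`, `sensitivity`, `f1` and one
#'   `topk_<K>` column per usable K.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5,
                            k = c(20, 50, 100)) {
  out <- data.frame(auc = roc_auc(scores, labels),
                    sensitivity = sensitivity(scores, labels, threshold),
                    f1 = f1(scores, labels, threshold))
  for (kk in k[k <= length(scores)])
    out[[paste0("topk_", kk)]] <- topk(scores, labels, kk)
  out
}
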