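#' Area under the ROC curve by the rank statistic
#'
#' AUROC equals the probability a random positive outscores a random
#' negative, computed from mid-ranks (ties get half credit) — the normalized
#' Mann-Whitney U statistic.
#'
#' @param y_true 0/1 vector.
#' @param y_score Numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0)
    abort("AUROC undefined: y_true has a single class",
          class = "oncosepsis_validation_error")
  r <- rank(y_score, ties.method = "average")
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve by step integration
#'
#' Precision-recall pairs are computed at every distinct score threshold
#' (descending) and integrated as a right-continuous step function:
#' `sum (recall_i - recall_{i-1}) * precision_i`, the average-precision
#' convention.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(y_true, y_score) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1)
  if (n_pos == 0 || all(y_true == 1))
    abort("AUPRC undefined: y_true has a single class",
          class = "oncosepsis_validation_error")
  ord <- order(y_score, decreasing = TRUE)
  y <- y_true[ord]; s <- y_score[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(s, fromLast = TRUE) # threshold boundaries (tie groups)
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Classification metrics for one fold
#'
#' Scores are binarized at `threshold` for accuracy, precision, recall and
#' F1; AUROC and AUPRC are threshold-free. Precision (and F1) fall back to 0
#' when no positive is predicted; recall to 0 when there is no positive.
#'
#' @param y_true 0/1 vector.
#' @param y_score Numeric scores in \[0, 1\].
#' @param threshold Binarization threshold, default 0.5.
#' @return One-row tibble: `accuracy`, `auroc`, `auprc`, `precision`,
#'   `recall`, `f1`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1))
compute_metrics <- function(y_true, y_score, threshold = 0.5) {
  y_true <- as.integer(y_true)
  pred <- as.integer(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  tn <- sum(pred == 0 & y_true == 0)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(
    accuracy = (tp + tn) / length(y_true),
    auroc = auroc(y_true, y_score),
    auprc = auprc(y_true, y_score),
    precision = precision, recall = recall, f1 = f1
  )
}
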