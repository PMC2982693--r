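#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with ties counted 1/2 (the
#' normalized Mann-Whitney U statistic). Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param scores numeric vector of prediction scores.
#' @param labels binary vector (0/1 or logical) of the same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  lab <- check_labels(scores, labels)
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  r <- rank(scores)              # midranks handle ties
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation `sum_k (R_k - R_{k-1}) * P_k` over descending score
#' thresholds (no trapezoids), with tied scores entering the curve as a
#' single threshold. Preferred over ROC AUC when positives are rare, as in
#' sparse interaction networks.
#'
#' @inheritParams roc_auc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
  lab <- check_labels(scores, labels)
  # sweep unique thresholds from high to low
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- lab[o]
  tp <- cumsum(l)
  fp <- cumsum(!l)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[last_of_tie]
  fp <- fp[last_of_tie]
  recall <- tp / sum(lab)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix rates at a top-k cutoff
#'
#' Marks the k highest-scoring pairs as predicted positives and computes
#' sensitivity `TP / (TP + FN)`, specificity `TN / (TN + FP)` and positive
#' predictive value `TP / (TP + FP)`. Two cutoff rules are supported:
#'
#' * `"test_size"` -- k equals the number of positives in the test set, so
#'   the predictor is asked to recover exactly as many pairs as are truly
#'   positive (sensitivity and PPV then coincide).
#' * `"top_percentile"` -- k = `ceiling(percentile / 100 * n)`, the
#'   high-confidence regime used when only the very top of the ranking is
#'   actionable (default: top one percentile).
#'
#' Boundary ties are resolved by original position (stable order), the
#' same deterministic tie-break used everywhere a ranking is materialized.
#'
#' @inheritParams roc_auc
#' @param cutoff_rule `"test_size"` or `"top_percentile"`.
#' @param percentile percentile of pairs kept under `"top_percentile"`.
#' @return tibble with columns `sensitivity`, `specificity`, `ppv`,
#'   `cutoff_rule`, `k`.
#' @export
threshold_metrics <- function(scores, labels,
                              cutoff_rule = c("test_size", "top_percentile"),
                              percentile = 1) {
  lab <- check_labels(scores, labels)
  cutoff_rule <- match.arg(cutoff_rule)
  n <- length(scores)
  k <- switch(cutoff_rule,
    test_size = sum(lab),
    top_percentile = ceiling(percentile / 100 * n)
  )
  if (k < 1) abort_validation("cutoff selects zero pairs")
  pred_pos <- rep(FALSE, n)
  pred_pos[order(-scores, seq_len(n))[seq_len(k)]] <- TRUE
  tp <- sum(pred_pos & lab)
  fp <- sum(pred_pos & !lab)
  fn <- sum(!pred_pos & lab)
  tn <- sum(!pred_pos & !lab)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = tp / (tp + fp),
    cutoff_rule = cutoff_rule,
    k = k
  )
}

check_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort_validation("scores and labels must have equal length")
  }
  if (any(!is.finite(scores))) {
    abort_validation("scores must be finite")
  }
  lab <- as.logical(labels)
  if (anyNA(lab) && !all(labels %in% c(0, 1))) {
    abort_validation("labels must be binary")
  }
  if (is.numeric(labels) && !all(labels %in% c(0, 1))) {
    abort_validation("labels must be binary")
  }
  if (all(lab) || !any(lab)) {
    abort_validation("labels must contain at least one positive and one negative")
  }
  lab
}

# One MetricsReport row from pooled scores/labels.
metrics_row <- function(scores, labels, cutoff_rule, percentile) {
  thr <- threshold_metrics(scores, labels, cutoff_rule, percentile)
  tibble::tibble(
    auc = roc_auc(scores, labels),
    aupr = aupr(scores, labels),
    sensitivity = thr$sensitivity,
    specificity = thr$specificity,
    ppv = thr$ppv,
    cutoff_rule = thr$cutoff_rule,
    k = thr$k,
    n_test = length(scores),
    n_pos_test = sum(as.logical(labels))
  )
}
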