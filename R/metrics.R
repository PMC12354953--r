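# Evaluation metrics and mean +/- sd aggregation across tasks and repeats.

#' Area under the ROC curve
#'
#' Computed exactly as the probability that a uniformly random positive
#' outranks a uniformly random negative, with ties counted 1/2 (the rank /
#' Mann-Whitney statistic, equivalent to trapezoidal ROC integration with
#' mid-rank ties).
#'
#' @param scores numeric score per example (higher = more positive).
#' @param labels `{0, 1}` label per example; both classes must be present.
#' @return a value in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 0, 1, 0)) # 0.875
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("undefined-metric error: AUROC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Standard step-wise (non-interpolated) construction: examples are swept in
#' decreasing score order, tied scores as one block, and the area accumulates
#' `precision * delta(recall)` at each step.
#'
#' @inheritParams auroc
#' @return a value in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("undefined-metric error: PR-AUC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # collapse tied-score blocks
  blk <- cumsum(!duplicated(s))
  tp_b <- tapply(y, blk, sum)
  n_b <- tapply(y, blk, length)
  tp <- cumsum(tp_b)
  n_seen <- cumsum(n_b)
  precision <- tp / n_seen
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; returns 0 by
#' convention when any factor of the denominator is zero.
#'
#' @param predictions `{0, 1}` predicted class per example.
#' @param labels `{0, 1}` true label per example.
#' @return a value in `[-1, 1]`.
#' @export
mcc <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), length(labels) > 0,
            all(predictions %in% c(0, 1)), all(labels %in% c(0, 1)))
  tp <- sum(predictions == 1 & labels == 1)
  tn <- sum(predictions == 0 & labels == 0)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Aggregate a metric table into mean and standard deviation
#'
#' @param rows data frame with columns `task`, `repeat_idx`, `metric`,
#'   `value` (one row per task x repeat x metric cell).
#' @param by_task_first if `TRUE`, average repeats within each task first and
#'   aggregate over task means; default pools all task x repeat cells.
#' @return data frame with columns `metric`, `mean`, `sd`, `n_cells`; `sd` is
#'   the sample (n-1) standard deviation, 0 when a single cell is present.
#' @export
aggregate_metrics <- function(rows, by_task_first = FALSE) {
  stopifnot(nrow(rows) > 0,
            all(c("task", "repeat_idx", "metric", "value") %in% names(rows)))
  if (by_task_first) {
    rows <- stats::aggregate(value ~ task + metric, rows, mean)
  }
  agg <- lapply(split(rows, rows$metric), function(df) {
    data.frame(metric = df$metric[1],
               mean = mean(df$value),
               sd = if (nrow(df) > 1) stats::sd(df$value) else 0,
               n_cells = nrow(df))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
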