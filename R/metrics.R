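#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive is scored above a
#' randomly chosen negative, with ties counted 1/2 — i.e. the Mann-Whitney
#' U statistic normalised by `n_pos * n_neg`, computed from midranks.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1), same length.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_score(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("auc_score: length mismatch")
  if (!all(labels %in% c(0, 1))) abort("auc_score: labels must be 0 or 1")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("auc_score: needs at least one positive and one negative label")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Average precision score
#'
#' Summarises the precision-recall curve as the weighted mean of the
#' precisions achieved at each score threshold, weighted by the increase in
#' recall from the previous threshold:
#' `AP = sum_n (R_n - R_{n-1}) * P_n`, thresholds taken at each distinct
#' score in descending order.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (0/1), same length; at least one positive.
#' @return Average precision in `[0, 1]`.
#' @examples
#' aps_score(c(0.2, 0.9), c(1, 0))  # 0.5: the one positive ranks last
#' @export
aps_score <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("aps_score: length mismatch")
  if (!all(labels %in% c(0, 1))) abort("aps_score: labels must be 0 or 1")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort("aps_score: needs at least one positive label")
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # thresholds sit at the last element of each tie group
  thr <- which(diff(s) != 0)
  thr <- c(thr, length(s))
  precision <- tp[thr] / (tp[thr] + fp[thr])
  recall <- tp[thr] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Evaluate a fitted classifier on one split of a dataset
#'
#' @param fit A `bigru_fit` from [fit_bigru()].
#' @param data A labelled dataset tibble; if it has a `split` column, only
#'   the requested split is scored.
#' @param split Which split to score (default `"test"`); ignored when
#'   `data` has no `split` column.
#' @return A one-row tibble with `split`, `n`, `auc`, `aps`.
#' @export
evaluate_model <- function(fit, data, split = "test") {
  stopifnot(inherits(fit, "bigru_fit"))
  validate_dataset(data)
  if ("split" %in% names(data)) {
    data <- data[data$split == split, , drop = FALSE]
  } else {
    split <- "all"
  }
  if (nrow(data) == 0) abort(paste0("no records in split '", split, "'"))
  scored <- predict(fit, data)
  tibble::tibble(
    split = split, n = nrow(data),
    auc = auc_score(scored$.pred, scored$label),
    aps = aps_score(scored$.pred, scored$label)
  )
}
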