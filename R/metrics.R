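#' Confusion counts from predicted interactions and labeled pairs
#'
#' Evaluation is restricted to the labeled pairs: a truth-positive pair
#' counts as TP if predicted interacting, FN otherwise; a truth-negative
#' pair counts as FP if predicted interacting, TN otherwise. Pairs are
#' matched without regard to direction unless `directed = TRUE`.
#'
#' @param predicted A `ppi_set` (see [predict_all()]) or a two-column
#'   data.frame / matrix of predicted (query_id, target_id) pairs.
#' @param truth data.frame with columns `id_a`, `id_b`, `label`.
#' @param directed If `TRUE`, (a,b) in the truth is matched only by the
#'   directed prediction (a,b); default matches either orientation.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion <- function(predicted, truth, directed = FALSE) {
  if (inherits(predicted, "ppi_set")) predicted <- predicted$relations
  predicted <- as.data.frame(predicted, stringsAsFactors = FALSE)
  pred_keys <- if (nrow(predicted)) {
    paste0(predicted[[1L]], "\r", predicted[[2L]])
  } else character()
  key_fwd <- paste0(truth$id_a, "\r", truth$id_b)
  hit <- key_fwd %in% pred_keys
  if (!directed) {
    key_rev <- paste0(truth$id_b, "\r", truth$id_a)
    hit <- hit | key_rev %in% pred_keys
  }
  pos <- truth$label == 1L
  c(TP = sum(pos & hit), FP = sum(!pos & hit),
    FN = sum(pos & !hit), TN = sum(!pos & !hit))
}

#' Confusion-matrix evaluation metrics
#'
#' Computes precision, recall (= sensitivity), F1, specificity, accuracy and
#' the Matthews correlation coefficient from TP/FP/FN/TN counts. Any metric
#' whose denominator is zero is reported as 0 (including MCC).
#'
#' @param counts Named vector or list with elements `TP`, `FP`, `FN`, `TN`
#'   (as produced by [confusion()]), or the four counts in that order.
#' @return Named numeric vector with elements `precision`, `recall`, `f1`,
#'   `specificity`, `accuracy`, `mcc`.
#' @export
ppi_metrics <- function(counts) {
  counts <- unlist(counts)
  if (is.null(names(counts)) || !all(c("TP", "FP", "FN", "TN") %in% names(counts))) {
    names(counts) <- c("TP", "FP", "FN", "TN")
  }
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  fn <- as.numeric(counts[["FN"]]); tn <- as.numeric(counts[["TN"]])
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn >= 1)
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  specificity <- safe_div(tn, tn + fp)
  accuracy <- safe_div(tp + tn, tp + fp + fn + tn)
  # products kept in double to avoid integer overflow on large pair counts
  mcc_den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- safe_div(tp * tn - fp * fn, mcc_den)
  c(precision = precision, recall = recall, f1 = f1,
    specificity = specificity, accuracy = accuracy, mcc = mcc)
}

#' Harmonic-mean F1 from precision and recall
#'
#' @param precision,recall Values in \[0,1\].
#' @return `2 * p * r / (p + r)`, or 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}
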