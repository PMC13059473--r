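#' Spearman rank correlation coefficient
#'
#' Computed as the Pearson correlation of average ranks, which equals the
#' classical `1 - 6 sum(d^2) / (n (n^2 - 1))` formula when there are no
#' ties and stays well-defined under ties.
#'
#' @param x,y numeric vectors of equal length `>= 2`
#' @return correlation in [-1, 1]; `NaN` (with a warning) for constant input
#' @export
srcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("srcc undefined for constant input; returning NaN")
    return(NaN)
  }
  stats::cor(rank(x), rank(y))
}

#' Pearson correlation coefficient
#' @inheritParams srcc
#' @export
pcc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("pcc undefined for constant input; returning NaN")
    return(NaN)
  }
  stats::cor(x, y)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) formulation: the probability that a random
#' positive scores above a random negative, ties counted one half.
#'
#' @param labels 0/1 vector
#' @param scores numeric scores, higher = more positive
#' @return AUROC in [0, 1]; `NaN` with a warning when one class is absent
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("auroc undefined with a single class; returning NaN")
    return(NaN)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification accuracy
#' @param labels,predicted_labels 0/1 vectors of equal length
#' @export
acc <- function(labels, predicted_labels) {
  stopifnot(length(labels) == length(predicted_labels))
  mean(as.integer(labels) == as.integer(predicted_labels))
}

#' Full metric report for predicted affinities
#'
#' Regression metrics (SRCC, PCC) are computed on normalized affinities;
#' classification metrics (AUROC, ACC) on the 500 nM binder labels, with
#' the predicted affinity thresholded at `normalize_ic50(500)` for ACC.
#'
#' @param predicted predicted affinities in [0, 1]
#' @param truth data.frame with `affinity` and `label` columns (as from
#'   [read_affinity_table()]), or a numeric vector of true affinities
#' @return object of class `cmhs_metrics`: srcc, pcc, auroc, acc, n
#' @export
metric_report <- function(predicted, truth) {
  if (is.numeric(truth)) {
    truth <- data.frame(affinity = truth,
                        label = as.integer(truth > normalize_ic50(500)))
  }
  stopifnot(length(predicted) == nrow(truth))
  thr <- normalize_ic50(500)
  out <- list(
    srcc = srcc(predicted, truth$affinity),
    pcc = pcc(predicted, truth$affinity),
    auroc = auroc(truth$label, predicted),
    acc = acc(truth$label, as.integer(predicted > thr)),
    n = length(predicted)
  )
  class(out) <- "cmhs_metrics"
  out
}

#' @export
print.cmhs_metrics <- function(x, ...) {
  cat(sprintf("pMHC metrics (n = %d)\n", x$n))
  cat(sprintf("  SRCC  %.4f\n  PCC   %.4f\n  AUROC %.4f\n  ACC   %.4f\n",
              x$srcc, x$pcc, x$auroc, x$acc))
  invisible(x)
}

#' Serialize a metric report to JSON
#' @param report `cmhs_metrics` object
#' @param path output file; when `NULL`, the JSON string is returned
#' @export
write_metric_report <- function(report, path = NULL) {
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
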