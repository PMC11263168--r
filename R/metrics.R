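.check_masks <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("mask shapes differ", call. = FALSE)
  if (!all(pred %in% c(0L, 1L)) || !all(gt %in% c(0L, 1L)))
    stop("masks must contain only 0/1 labels", call. = FALSE)
}

#' Jaccard similarity coefficient of two binary masks
#'
#' `|P intersect G| / |P union G|` over the foreground pixels. Two empty
#' masks agree perfectly and score 1.
#'
#' @param pred,gt 0/1 matrices of the same shape.
#' @return value in \[0, 1\].
#' @export
jaccard <- function(pred, gt) {
  .check_masks(pred, gt)
  inter <- sum(pred == 1L & gt == 1L)
  uni <- sum(pred == 1L | gt == 1L)
  if (uni == 0L) 1 else inter / uni
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |P intersect G| / (|P| + |G|)`; equals `2 J / (1 + J)` for the
#' Jaccard coefficient `J` of the same masks. Two empty masks score 1.
#'
#' @inheritParams jaccard
#' @return value in \[0, 1\].
#' @export
dice <- function(pred, gt) {
  .check_masks(pred, gt)
  inter <- sum(pred == 1L & gt == 1L)
  tot <- sum(pred == 1L) + sum(gt == 1L)
  if (tot == 0L) 1 else 2 * inter / tot
}

#' Pixel accuracy of a per-pixel labelling
#'
#' Fraction of correctly classified pixels,
#' `sum_i pixel_ii / sum_ij pixel_ij` over the `K x K` pixel confusion
#' matrix.
#'
#' @param pred,gt per-pixel class maps (integer labels in `0..K-1`), same
#'   shape.
#' @param n_classes class count `K`; inferred from the data when missing.
#' @return value in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, gt, n_classes = NULL) {
  if (!all(dim(pred) == dim(gt)))
    stop("label map shapes differ", call. = FALSE)
  if (is.null(n_classes)) n_classes <- max(pred, gt) + 1L
  if (any(pred >= n_classes) || any(gt >= n_classes) ||
      any(pred < 0) || any(gt < 0))
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  mean(pred == gt)
}

#' Segmentation agreement report for one mask pair
#'
#' @inheritParams jaccard
#' @return list with `jsc`, `dsc` and `pa` (binary pixel accuracy).
#' @export
segmentation_metrics <- function(pred, gt) {
  list(jsc = jaccard(pred, gt), dsc = dice(pred, gt),
       pa = pixel_accuracy(pred, gt, 2L))
}

#' Classification metrics from true and predicted labels
#'
#' Computes accuracy (micro, percent of correct predictions), sensitivity
#' `TP / (TP + FN) * 100` and specificity `TN / (TN + FP) * 100` from
#' one-vs-rest confusion counts. For two classes the larger label is the
#' positive class (the usual binary convention); for more classes
#' sensitivity and specificity are macro-averaged across the one-vs-rest
#' problems, since a single summary number requires an averaging rule.
#' A zero denominator defines the affected metric as 0 and raises the
#' `degenerate` flag.
#'
#' @param truth,pred equal-length label vectors (factors or integers in
#'   `0..K-1`).
#' @param n_classes class count; inferred when missing.
#' @return object of class `"metric_report"`: list with `accuracy`,
#'   `sensitivity`, `specificity` (percentages), `per_class` data frame of
#'   one-vs-rest counts and rates, `n`, and `degenerate`.
#' @examples
#' truth <- c(rep(1, 10), rep(0, 10))
#' pred <- c(rep(1, 9), 0, rep(0, 8), 1, 1)
#' classification_metrics(truth, pred) # sensitivity 90, specificity 80
#' @export
classification_metrics <- function(truth, pred, n_classes = NULL) {
  if (length(truth) != length(pred))
    stop("`truth` and `pred` must have equal length", call. = FALSE)
  if (is.factor(truth) || is.factor(pred)) {
    levs <- union(levels(as.factor(truth)), levels(as.factor(pred)))
    truth <- as.integer(factor(truth, levels = levs)) - 1L
    pred <- as.integer(factor(pred, levels = levs)) - 1L
  }
  if (is.null(n_classes)) n_classes <- max(truth, pred) + 1L
  if (any(truth >= n_classes) || any(pred >= n_classes) ||
      any(truth < 0) || any(pred < 0))
    stop("labels must lie in [0, n_classes)", call. = FALSE)
  n <- length(truth)
  per <- do.call(rbind, lapply(seq_len(n_classes) - 1L, function(k) {
    tp <- sum(truth == k & pred == k)
    fn <- sum(truth == k & pred != k)
    fp <- sum(truth != k & pred == k)
    tn <- sum(truth != k & pred != k)
    data.frame(class = k, tp = tp, tn = tn, fp = fp, fn = fn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) * 100 else 0,
               specificity = if (tn + fp > 0) tn / (tn + fp) * 100 else 0)
  }))
  degenerate <- any(per$tp + per$fn == 0) || any(per$tn + per$fp == 0)
  if (degenerate)
    warning("zero denominator in a one-vs-rest confusion; affected ",
            "metrics reported as 0", call. = FALSE)
  if (n_classes == 2L) {
    sens <- per$sensitivity[2]
    spec <- per$specificity[2]
  } else {
    sens <- mean(per$sensitivity)
    spec <- mean(per$specificity)
  }
  structure(list(accuracy = mean(truth == pred) * 100,
                 sensitivity = sens, specificity = spec,
                 per_class = per, n = n, degenerate = degenerate),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  cat(sprintf("  accuracy:    %.*f%%\n", digits, x$accuracy))
  cat(sprintf("  sensitivity: %.*f%%\n", digits, x$sensitivity))
  cat(sprintf("  specificity: %.*f%%\n", digits, x$specificity))
  if (x$degenerate) cat("  (degenerate one-vs-rest counts present)\n")
  invisible(x)
}
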