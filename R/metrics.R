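#' Pixel-wise confusion counts between two masks
#'
#' Tallies true positives, false positives, false negatives and true
#' negatives between a predicted and a ground-truth mask; the four counts
#' sum to the total pixel count.
#'
#' @param pred,truth Logical mask matrices of the same shape.
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `FP`, `FN`, `TN`.
#' @export
confusion <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 FN = sum(!p & t), TN = sum(!p & !t)),
            class = "confusion_counts")
}

#' Intersection-over-union (Jaccard index)
#'
#' `TP / (TP + FP + FN)`, in `[0, 1]`. When both masks are empty the
#' overlap is perfect by convention and the value is 1.
#'
#' @param counts A [confusion()] result.
#' @return Numeric scalar in `[0, 1]`.
#' @export
iou <- function(counts) {
  den <- counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  counts$TP / den
}

#' Dice similarity coefficient
#'
#' `2 TP / (2 TP + FP + FN)`, in `[0, 1]`; both-empty masks score 1.
#' Related to IoU by `Dice = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice <- function(counts) {
  den <- 2 * counts$TP + counts$FP + counts$FN
  if (den == 0) return(1)
  2 * counts$TP / den
}

#' Pixel accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @inheritParams iou
#' @return Numeric scalar in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("empty confusion counts")
  (counts$TP + counts$TN) / total
}

#' Precision (positive predictive value)
#'
#' `TP / (TP + FP)`. Undefined (returned as `NA` with a warning) when no
#' positives were predicted.
#'
#' @inheritParams iou
#' @return Numeric scalar in `[0, 1]`, or `NA`.
#' @export
precision <- function(counts) {
  den <- counts$TP + counts$FP
  if (den == 0) {
    warning("precision undefined: no predicted positives")
    return(NA_real_)
  }
  counts$TP / den
}

#' Sensitivity (recall, true-positive rate)
#'
#' `TP / (TP + FN)`.
#'
#' @inheritParams iou
#' @return Numeric scalar in `[0, 1]`, or `NA` when the truth has no
#'   positives.
#' @export
sensitivity <- function(counts) {
  den <- counts$TP + counts$FN
  if (den == 0) {
    warning("sensitivity undefined: no true positives in ground truth")
    return(NA_real_)
  }
  counts$TP / den
}

#' Specificity (true-negative rate)
#'
#' `TN / (TN + FP)`.
#'
#' @inheritParams iou
#' @return Numeric scalar in `[0, 1]`, or `NA` when the truth has no
#'   negatives.
#' @export
specificity <- function(counts) {
  den <- counts$TN + counts$FP
  if (den == 0) {
    warning("specificity undefined: no true negatives in ground truth")
    return(NA_real_)
  }
  counts$TN / den
}

#' All segmentation metrics for one mask pair
#'
#' @param pred,truth Logical masks of the same shape.
#' @return Named list with `dice`, `iou`, `accuracy`, `precision`,
#'   `sensitivity`, `specificity` and the `counts`.
#' @export
segmentation_metrics <- function(pred, truth) {
  cc <- confusion(pred, truth)
  list(dice = dice(cc), iou = iou(cc), accuracy = accuracy(cc),
       precision = suppressWarnings(precision(cc)),
       sensitivity = suppressWarnings(sensitivity(cc)),
       specificity = suppressWarnings(specificity(cc)),
       counts = cc)
}

#' Per-case metrics table and summary
#'
#' Evaluates a list of predictions against ground truth and writes (if
#' paths are given) a per-case CSV and a JSON summary with mean, median
#' and quartiles of each metric.
#'
#' @param preds,truths Lists of logical masks.
#' @param case_ids Optional case labels.
#' @param csv_path,json_path Optional output paths.
#' @return Data frame of per-case metrics (invisibly also written out).
#' @export
evaluate_cases <- function(preds, truths, case_ids = seq_along(preds),
                           csv_path = NULL, json_path = NULL) {
  stopifnot(length(preds) == length(truths))
  rows <- lapply(seq_along(preds), function(i) {
    m <- segmentation_metrics(preds[[i]], truths[[i]])
    data.frame(case = as.character(case_ids[i]), dice = m$dice, iou = m$iou,
               accuracy = m$accuracy, precision = m$precision,
               sensitivity = m$sensitivity, specificity = m$specificity)
  })
  df <- do.call(rbind, rows)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(df[-1L], function(v) {
      v <- v[is.finite(v)]
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      list(mean = mean(v), q1 = q[1], median = q[2], q3 = q[3])
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  }
  df
}
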