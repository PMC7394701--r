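# Pixelwise segmentation metrics: Jaccard, accuracy, precision, recall,
# F-score, Dice, from a TP/FP/FN/TN confusion table.

#' Binarize a probability map
#'
#' Foreground where `prob > threshold`, strictly: a pixel exactly at the
#' threshold is background.  The default threshold is the 8-bit constant 127
#' interpreted on [0, 1] probabilities as 127/255.
#'
#' @param prob numeric array/matrix with values in [0, 1].
#' @param threshold scalar in [0, 1).
#' @return logical array of the same shape.
#' @export
binarizeProb <- function(prob, threshold = 127 / 255) {
  stopifnot(min(prob) >= -1e-9, max(prob) <= 1 + 1e-9)
  prob > threshold
}

#' Confusion counts between a binary prediction and truth
#'
#' @param pred,truth logical (or 0/1) arrays of identical shape.
#' @return `list(TP =, FP =, FN =, TN =)`; the four counts sum to the number
#'   of evaluated pixels.
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) ||
      length(pred) != length(truth))
    stop("pred and truth shapes differ")
  p <- as.logical(pred); t <- as.logical(truth)
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  list(TP = tp, FP = fp, FN = fn, TN = length(p) - tp - fp - fn)
}

#' Metric report from confusion counts
#'
#' Jaccard = TP/(TP+FP+FN), Accuracy = (TP+TN)/total,
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' Dice = 2TP/(2TP+FP+FN), F-score = harmonic mean of precision and recall.
#' A ratio with zero denominator is reported as 0 and flagged in
#' `undefined`.
#'
#' @param counts a list from [confusionCounts()].
#' @return `list(jaccard, accuracy, precision, recall, dice, fscore,
#'   undefined)`.
#' @export
metricReport <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN; tn <- counts$TN
  total <- tp + fp + fn + tn
  stopifnot(total > 0)
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  jac <- ratio(tp, tp + fp + fn, "jaccard")
  acc <- (tp + tn) / total
  prec <- ratio(tp, tp + fp, "precision")
  rec <- ratio(tp, tp + fn, "recall")
  dice <- ratio(2 * tp, 2 * tp + fp + fn, "dice")
  fs <- if (prec + rec == 0) { undef <- c(undef, "fscore"); 0 } else
    2 * prec * rec / (prec + rec)
  list(jaccard = jac, accuracy = acc, precision = prec, recall = rec,
       dice = dice, fscore = fs, undefined = undef)
}

#' Evaluate a probability map against a binary truth
#'
#' Convenience wrapper: binarize, count, report.  Counts are pooled over
#' the whole array; set `perSlice = TRUE` to get one report per z-slice of
#' a 3D input.
#'
#' @param prob probability array in [0, 1].
#' @param truth binary array, same shape.
#' @param threshold binarization threshold.
#' @param perSlice report per z-slice instead of pooled.
#' @return a metric report list, or a list of them when `perSlice`.
#' @export
evaluateSegmentation <- function(prob, truth, threshold = 127 / 255,
                                 perSlice = FALSE) {
  if (perSlice && length(dim(prob)) == 3L) {
    return(lapply(seq_len(dim(prob)[1]), function(z)
      metricReport(confusionCounts(binarizeProb(prob[z, , ], threshold),
                                   truth[z, , ]))))
  }
  metricReport(confusionCounts(binarizeProb(prob, threshold), truth))
}
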