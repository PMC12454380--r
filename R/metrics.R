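# Semantic (Acc/Pre/Rec/mIoU) and instance (Pre/Rec/F1/iIoU) segmentation
# metrics. Precision and recall are reported for the seedling class (the
# positive, minority class); mIoU averages the per-class IoU over both
# classes; instance counts are pooled (micro-averaged) over ground-truth
# plants. All results are percentages in [0, 100].

.safeRatio <- function(num, den) if (den == 0) 0 else num / den

#' Semantic metrics from confusion counts
#'
#' Acc = (TP+TN)/(TP+FP+TN+FN), Pre = TP/(TP+FP), Rec = TP/(TP+FN),
#' IoU_c = TP_c/(TP_c+FP_c+FN_c) per class, mIoU = mean over the two classes.
#' A zero denominator yields 0 and the metric name is listed in the
#' `"undefined"` attribute.
#'
#' @param tp,fp,tn,fn confusion counts for the positive (seedling) class.
#' @return A list with elements `acc`, `pre`, `rec`, `miou`, `iou` (per-class
#'   vector, background first), all in percent.
#' @examples
#' metricsFromCounts(tp = 40, fp = 10, tn = 30, fn = 20)
#' @export
metricsFromCounts <- function(tp, fp, tn, fn) {
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty input: all counts are zero")
  undef <- character(0)
  if (tp + fp == 0) undef <- c(undef, "pre")
  if (tp + fn == 0) undef <- c(undef, "rec")
  iou1 <- .safeRatio(tp, tp + fp + fn)
  iou0 <- .safeRatio(tn, tn + fn + fp)   # background: FP/FN roles swap
  out <- list(acc = 100 * (tp + tn) / total,
              pre = 100 * .safeRatio(tp, tp + fp),
              rec = 100 * .safeRatio(tp, tp + fn),
              miou = 100 * mean(c(iou0, iou1)),
              iou = 100 * c(background = iou0, seedling = iou1))
  attr(out, "undefined") <- undef
  out
}

#' Semantic segmentation metrics from label vectors
#'
#' @param pred,truth equal-length integer vectors over \{0, 1\}.
#' @return As [metricsFromCounts()].
#' @export
semanticMetrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  if (!length(pred)) stop("empty input")
  if (!all(pred %in% 0:1) || !all(truth %in% 0:1))
    stop("labels must be 0 or 1")
  metricsFromCounts(tp = sum(pred == 1 & truth == 1),
                    fp = sum(pred == 1 & truth == 0),
                    tn = sum(pred == 0 & truth == 0),
                    fn = sum(pred == 0 & truth == 1))
}

#' Instance segmentation metrics
#'
#' For each matched (prediction, truth) pair, TP is the shared point count,
#' FP the prediction-only points and FN the truth-only points. Counts are
#' pooled over all ground-truth instances (unmatched truth instances
#' contribute their size to FN; unmatched predicted clusters contribute
#' theirs to FP; noise points belong to no prediction and hence count as FN
#' for their truth instance). iIoU is the mean IoU over the M ground-truth
#' instances, 0 for unmatched ones.
#'
#' @param pred an \linkS4class{InstanceAssignment} or integer label vector
#'   (-1 noise, 0..K-1 clusters).
#' @param truth integer ground-truth instances (0 = background, 1..M).
#' @param matching optional result of [matchInstances()]; computed when
#'   missing.
#' @return A list with `pre`, `rec`, `f1`, `iiou` (percent) and
#'   `perInstanceIoU` (percent, named by truth instance).
#' @export
instanceMetrics <- function(pred, truth, matching = NULL) {
  if (is(pred, "InstanceAssignment")) pred <- pred@labels
  stopifnot(length(pred) == length(truth))
  if (is.null(matching)) matching <- matchInstances(pred, truth)
  tid <- sort(unique(truth[truth > 0L]))
  pid <- sort(unique(pred[pred >= 0L]))
  TP <- 0; FP <- 0; FN <- 0
  perIoU <- stats::setNames(numeric(length(tid)), tid)
  matchedPred <- integer(0)
  for (j in seq_along(tid)) {
    t <- tid[j]
    sizeT <- sum(truth == t)
    row <- matching[matching$truth == t, , drop = FALSE]
    if (nrow(row)) {
      cpred <- row$pred[1]
      matchedPred <- c(matchedPred, cpred)
      inter <- sum(pred == cpred & truth == t)
      sizeP <- sum(pred == cpred)
      TP <- TP + inter
      FN <- FN + (sizeT - inter)
      FP <- FP + (sizeP - inter)
      perIoU[j] <- inter / (sizeT + sizeP - inter)
    } else {
      FN <- FN + sizeT
    }
  }
  for (c in setdiff(pid, matchedPred)) FP <- FP + sum(pred == c)
  pre <- .safeRatio(TP, TP + FP)
  rec <- .safeRatio(TP, TP + FN)
  f1 <- if (pre + rec == 0) 0 else 2 * pre * rec / (pre + rec)
  list(pre = 100 * pre, rec = 100 * rec, f1 = 100 * f1,
       iiou = if (length(tid)) 100 * mean(perIoU) else 0,
       perInstanceIoU = 100 * perIoU)
}

#' Full metrics report for one scene
#'
#' Convenience wrapper combining [semanticMetrics()] and [instanceMetrics()].
#'
#' @param semPred,semTruth semantic label vectors (or NULL to skip).
#' @param instPred,instTruth instance labels as in [instanceMetrics()]
#'   (or NULL to skip).
#' @return A list with components `semantic` and `instance`.
#' @export
metricsReport <- function(semPred = NULL, semTruth = NULL,
                          instPred = NULL, instTruth = NULL) {
  list(semantic = if (!is.null(semPred)) semanticMetrics(semPred, semTruth),
       instance = if (!is.null(instPred)) instanceMetrics(instPred, instTruth))
}
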