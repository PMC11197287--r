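# Segmentation evaluation under the wound-as-positive convention:
# pixelwise confusion counts, DSC / ACC / IoU / PRE / REC / SPE, rank-based
# ROC-AUC, and per-image macro-averaging.

#' Pixelwise confusion counts (positive class = wound)
#'
#' True positives are pixels correctly predicted as wound (value 0 in both
#' masks); true negatives are pixels correctly predicted as cells (value 1
#' in both).
#'
#' @param pred,gt binary masks of identical shape (1 = cell, 0 = wound).
#' @return named list `tp`, `tn`, `fp`, `fn`; counts sum to the pixel total.
#' @export
confusionCounts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("pred and gt must have identical shapes")
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("confusionCounts expects binary {0,1} masks")
  list(tp = sum(pred == 0 & gt == 0),
       tn = sum(pred == 1 & gt == 1),
       fp = sum(pred == 0 & gt == 1),
       fn = sum(pred == 1 & gt == 0))
}

# Zero-denominator convention: when a denominator vanishes the metric is 1
# if the counts force agreement (the relevant class is absent from both
# masks), otherwise the quantity is undefined and an error is raised.
.safeRatio <- function(num, den, forced, what) {
  if (den > 0) return(num / den)
  if (forced) return(1)
  stop(sprintf("%s undefined: zero denominator with disagreeing masks", what))
}

#' Segmentation metrics from confusion counts
#'
#' Computes, with the wound as the positive class:
#' \deqn{DSC = 2TP / (FP + 2TP + FN)}
#' \deqn{ACC = (TP + TN) / (TP + TN + FP + FN)}
#' \deqn{IoU = TP / (TP + FP + FN)}
#' \deqn{PRE = TP / (TP + FP)}
#' \deqn{REC = TP / (TP + FN)}
#' \deqn{SPE = TN / (TN + FP)}
#'
#' @param counts output of [confusionCounts()].
#' @return one-row data.frame with columns dsc, acc, iou, pre, rec, spe.
#' @examples
#' cc <- confusionCounts(matrix(0, 2, 2), matrix(0, 2, 2))
#' metricsFromCounts(cc)  # all 1
#' @export
metricsFromCounts <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("empty mask: no pixels to evaluate")
  data.frame(
    dsc = .safeRatio(2 * tp, fp + 2 * tp + fn, tp + fp + fn == 0, "DSC"),
    acc = (tp + tn) / total,
    iou = .safeRatio(tp, tp + fp + fn, tp + fp + fn == 0, "IoU"),
    pre = .safeRatio(tp, tp + fp, fn == 0, "precision"),
    rec = .safeRatio(tp, tp + fn, fp == 0, "recall"),
    spe = .safeRatio(tn, tn + fp, fn == 0, "specificity")
  )
}

#' Rank-based ROC-AUC of the wound score
#'
#' The network emits cell probabilities (white ROI convention), so the
#' wound score is `1 - p`; the AUC is the Mann-Whitney rank statistic of
#' wound scores against the ground-truth wound labels, with average ranks
#' on ties (a constant map scores 0.5). `onBinarized = TRUE` first
#' thresholds the probabilities and ranks the resulting {0,1} scores — an
#' alternative some tools use, provided as an explicit option.
#'
#' @param probabilities cell-probability raster in `[0, 1]`.
#' @param gt binary ground-truth mask of identical shape.
#' @param onBinarized rank binarized scores instead of probabilities.
#' @param threshold threshold used when `onBinarized = TRUE`.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(probabilities, gt, onBinarized = FALSE, threshold = 0.5) {
  if (!identical(dim(probabilities), dim(gt)))
    stop("probabilities and gt must have identical shapes")
  if (!all(gt %in% c(0, 1))) stop("gt must be binary")
  score <- if (onBinarized) 1 - binarize(probabilities, threshold)
           else 1 - probabilities
  pos <- gt == 0                       # wound pixels
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0L || nNeg == 0L)
    stop("ROC-AUC undefined for a single-class ground truth")
  r <- rank(as.vector(score))          # average ranks on ties
  (sum(r[as.vector(pos)]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Per-image segmentation report
#'
#' One row of all metrics for a predicted/ground-truth mask pair, with
#' ROC-AUC when a probability map is supplied.
#'
#' @param pred,gt binary masks (1 = cell, 0 = wound).
#' @param probabilities optional cell-probability map for ROC-AUC.
#' @return one-row data.frame: dsc, acc, iou, pre, rec, spe, roc_auc.
#' @export
segMetrics <- function(pred, gt, probabilities = NULL) {
  rep <- metricsFromCounts(confusionCounts(pred, gt))
  rep$roc_auc <- if (is.null(probabilities)) NA_real_
                 else rocAuc(probabilities, gt)
  rep
}

#' Macro-average metric reports over images
#'
#' The arithmetic mean of each metric across per-image reports (per-image
#' macro-averaging, i.e. the mean DSC of the evaluated images — not the
#' pooled-count metric, which weights images by pixel counts).
#'
#' @param reports data.frame of per-image rows, as stacked [segMetrics()]
#'   output, or a list of such rows.
#' @return one-row data.frame of means.
#' @export
aggregateMetrics <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  if (is.null(reports) || nrow(reports) == 0L)
    stop("cannot aggregate an empty report list")
  num <- vapply(reports, is.numeric, logical(1))
  out <- as.data.frame(as.list(colMeans(reports[, num, drop = FALSE],
                                        na.rm = TRUE)))
  out
}
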