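# Wound quantification: probability thresholding, quadrant-merged mask
# prediction, pixel-count wound areas and signed percentage errors.

#' Binarize a probability map
#'
#' Values strictly greater than the threshold map to 1 (cell), all others —
#' including the threshold value itself — map to 0 (wound).
#'
#' @param probabilities numeric raster in `[0, 1]`.
#' @param threshold scalar strictly inside (0, 1); default 0.5.
#' @return binary raster of the same shape.
#' @examples
#' binarize(matrix(c(0.4, 0.5, 0.51), 1, 3))  # 0 0 1
#' @export
binarize <- function(probabilities, threshold = 0.5) {
  if (length(threshold) != 1L || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly in (0, 1)")
  (probabilities > threshold) * 1
}

#' Predict a full-image binary mask via quadrant split/merge
#'
#' The working-resolution image is split into its four quadrants, each
#' quadrant is passed through the model, the probability patches are
#' binarized, and the binary patches are merged back — the mirror image of
#' the tiling augmentation used in training. Because thresholding is
#' pixel-local, binarize-then-merge and merge-then-binarize commute.
#'
#' @param model a [SegmentationModel-class], or (for testing and external
#'   comparison) any function mapping a list of image patches to a list of
#'   probability matrices.
#' @param image `(height, width, channels)` array at working resolution;
#'   spatial dims must be even and each quadrant must match the model's
#'   configured input size.
#' @param threshold binarization threshold (strict, default 0.5).
#' @return binary `(height, width)` mask (1 = cell, 0 = wound).
#' @export
predictMask <- function(model, image, threshold = 0.5) {
  qs <- splitQuadrants(image)
  probs <- if (is.function(model)) model(qs@patches)
           else predictProb(model, qs@patches)
  mergeQuadrants(lapply(probs, binarize, threshold = threshold))
}

#' Wound area of a binary mask
#'
#' The pixel count of the cell-free region: the number of mask pixels with
#' value 0 (black, the wound convention).
#'
#' @param mask binary raster (values 0/1 only; anything else is an error).
#' @return integer pixel count in `[0, M * N]`.
#' @examples
#' woundArea(matrix(c(0, 1, 1, 1), 2, 2))  # 1
#' @export
woundArea <- function(mask) {
  if (!all(mask %in% c(0, 1)))
    stop("woundArea expects a binary {0,1} mask")
  sum(mask == 0)
}

#' Signed percentage error of a predicted wound area
#'
#' `(waPred - waGt) / waGt * 100`; the sign is kept so that over- and
#' under-segmentation are distinguishable, and the absolute value is
#' reported alongside. A fully closed ground-truth wound (`waGt = 0`)
#' leaves the ratio undefined and raises an error.
#'
#' @param waPred,waGt predicted and ground-truth wound areas in pixels.
#' @return one-row data.frame: `wa_pred`, `wa_gt`, `pe_signed`, `pe_abs`.
#' @examples
#' percentageError(110, 100)  # +10
#' percentageError(90, 100)   # -10
#' @export
percentageError <- function(waPred, waGt) {
  if (waPred < 0 || waGt < 0) stop("areas must be nonnegative")
  if (waGt == 0)
    stop("percentage error is undefined for a fully closed ground truth (wa_gt = 0)")
  pe <- (waPred - waGt) / waGt * 100
  data.frame(wa_pred = waPred, wa_gt = waGt, pe_signed = pe, pe_abs = abs(pe))
}

#' Wound-area report over paired mask lists
#'
#' Accepts masks from any source — model predictions or imported exports of
#' external tools — enabling like-for-like area comparisons. Any resolution
#' mismatch within a pair is an error, never an implicit resample.
#'
#' @param predMasks,gtMasks equal-length lists of binary masks.
#' @param ids optional sample identifiers.
#' @param source tag recorded in the report (e.g. model or tool name).
#' @return list with `reports` (one row per pair: sample_id, wa_pred,
#'   wa_gt, pe_signed, pe_abs, source) and `meanAbsPE`.
#' @export
batchAreaReport <- function(predMasks, gtMasks, ids = NULL,
                            source = "model") {
  if (length(predMasks) != length(gtMasks))
    stop("predMasks and gtMasks must have equal length")
  if (is.null(ids)) ids <- seq_along(predMasks)
  rows <- lapply(seq_along(predMasks), function(i) {
    if (!identical(dim(predMasks[[i]]), dim(gtMasks[[i]])))
      stop(sprintf("resolution mismatch in pair %s", ids[i]))
    pe <- percentageError(woundArea(predMasks[[i]]), woundArea(gtMasks[[i]]))
    cbind(data.frame(sample_id = ids[i]), pe, data.frame(source = source))
  })
  reports <- do.call(rbind, rows)
  list(reports = reports, meanAbsPE = mean(reports$pe_abs))
}

#' Import an externally produced binary mask
#'
#' Reads a lossless mask export (e.g. from an external analysis tool),
#' scales to `[0, 1]` and re-binarizes at 0.5. No resampling is performed.
#'
#' @param path PNG or TIFF file.
#' @return binary matrix.
#' @export
readMask <- function(path) {
  m <- .readRaster(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- toWorkingPrecision(m)
  (m > 0.5) * 1
}
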