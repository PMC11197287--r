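# Quadrant tiling augmentation: each preprocessed image and mask is split
# into four equal spatial parts (top-left, top-right, bottom-left,
# bottom-right), quadrupling the dataset and sharpening edge learning;
# mergeQuadrants() is the exact inverse applied after prediction.

#' Split a raster into four equal quadrants
#'
#' @param raster a matrix or array whose first two dims are spatial; both
#'   spatial dims must be even.
#' @return a [QuadrantSet-class] with patches in TL, TR, BL, BR order
#'   (row-major, origin at the top-left).
#' @examples
#' qs <- splitQuadrants(matrix(1:16, 4, 4))
#' identical(mergeQuadrants(qs), matrix(1:16, 4, 4))
#' @export
splitQuadrants <- function(raster) {
  d <- dim(raster)
  if (is.null(d) || length(d) < 2L)
    stop("splitQuadrants expects a matrix or array")
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop(sprintf("spatial dimensions must be even, got %dx%d", d[1], d[2]))
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  sub <- function(ri, ci) {
    if (length(d) == 2L) raster[ri, ci, drop = FALSE]
    else raster[ri, ci, , drop = FALSE]
  }
  top <- seq_len(h2); bot <- (h2 + 1L):d[1]
  left <- seq_len(w2); right <- (w2 + 1L):d[2]
  new("QuadrantSet",
      patches = list(sub(top, left), sub(top, right),
                     sub(bot, left), sub(bot, right)),
      sourceSize = as.integer(d[1:2]))
}

#' Merge four quadrants back into the source raster
#'
#' Exact inverse of [splitQuadrants()]: `mergeQuadrants(splitQuadrants(x))`
#' is bitwise identical to `x`.
#'
#' @param qs a [QuadrantSet-class], or a plain list of four patches in
#'   TL, TR, BL, BR order.
#' @return the reassembled raster.
#' @export
mergeQuadrants <- function(qs) {
  ps <- if (is(qs, "QuadrantSet")) qs@patches else qs
  if (length(ps) != 4L) stop("mergeQuadrants expects four patches")
  dims <- lapply(ps, dim)
  if (!all(vapply(dims, function(dd) identical(dd, dims[[1]]), logical(1))))
    stop("all four patches must have identical shapes")
  d <- dims[[1]]
  h2 <- d[1]; w2 <- d[2]
  outdim <- c(2L * h2, 2L * w2, if (length(d) > 2L) d[-(1:2)])
  out <- array(ps[[1]][1] * 0, outdim)    # preserve numeric type
  top <- seq_len(h2); bot <- h2 + seq_len(h2)
  left <- seq_len(w2); right <- w2 + seq_len(w2)
  if (length(d) == 2L) {
    out <- matrix(out, 2L * h2, 2L * w2)
    out[top, left] <- ps[[1]]; out[top, right] <- ps[[2]]
    out[bot, left] <- ps[[3]]; out[bot, right] <- ps[[4]]
  } else {
    out[top, left, ] <- ps[[1]]; out[top, right, ] <- ps[[2]]
    out[bot, left, ] <- ps[[3]]; out[bot, right, ] <- ps[[4]]
  }
  out
}

#' Report mask patches that contain a single class
#'
#' The augmentation aims for every quadrant to contain both wound and cell
#' pixels; near-closed wounds legitimately produce single-class patches, so
#' these are flagged (warn-and-keep), never dropped.
#'
#' @param maskPatches a [QuadrantSet-class] of binary masks or a list of
#'   binary matrices.
#' @param warn emit a warning when patches are single-class.
#' @return a data.frame with one row per patch: pixel counts per class and a
#'   `singleClass` flag.
#' @export
checkPatchCoverage <- function(maskPatches, warn = TRUE) {
  ps <- if (is(maskPatches, "QuadrantSet")) maskPatches@patches else maskPatches
  rep <- data.frame(
    patch = seq_along(ps),
    nWound = vapply(ps, function(p) sum(p == 0), numeric(1)),
    nCell = vapply(ps, function(p) sum(p == 1), numeric(1))
  )
  rep$singleClass <- rep$nWound == 0 | rep$nCell == 0
  if (warn && any(rep$singleClass))
    warning(sprintf("%d patch(es) contain a single class (kept)",
                    sum(rep$singleClass)))
  rep
}
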