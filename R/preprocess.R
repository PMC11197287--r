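# Preprocessing: CLAHE contrast equalization, area-based downscaling to the
# working resolution, numeric conversion, and the composed pipeline.

# Contrast-limited adaptive histogram equalization of one channel.
#
# Standard tile-based CLAHE: per-tile histograms are clipped at
# clip * (tile pixel count), the clipped excess is redistributed uniformly,
# and per-tile CDF mappings are bilinearly interpolated between tile centres.
# A zero-contrast tile (all pixels in one histogram bin) keeps the identity
# mapping, so a constant image is an exact fixed point.
.claheChannel <- function(ch, rows, cols, clip, nbins) {
  h <- nrow(ch); w <- ncol(ch)
  ch <- pmin(pmax(ch, 0), 1)
  bin <- pmin(floor(ch * nbins), nbins - 1L)  # integer bin per pixel

  rb <- round(seq(0L, h, length.out = rows + 1L))
  cb <- round(seq(0L, w, length.out = cols + 1L))
  lut <- array(0, c(rows, cols, nbins))
  ident <- matrix(FALSE, rows, cols)
  for (i in seq_len(rows)) {
    for (j in seq_len(cols)) {
      tb <- bin[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]]
      npx <- length(tb)
      hist <- tabulate(tb + 1L, nbins)
      if (sum(hist > 0L) <= 1L) {        # degenerate tile: no contrast
        ident[i, j] <- TRUE
        lut[i, j, ] <- (seq_len(nbins) - 0.5) / nbins
        next
      }
      clipval <- max(clip * npx, 1)
      clipped <- pmin(hist, clipval)
      excess <- npx - sum(clipped)
      clipped <- clipped + excess / nbins  # uniform redistribution
      lut[i, j, ] <- cumsum(clipped) / npx
    }
  }

  # Bilinear interpolation between the four surrounding tile mappings,
  # clamped at the borders (standard CLAHE border handling).
  centers_r <- (rb[-length(rb)] + rb[-1]) / 2 + 0.5
  centers_c <- (cb[-length(cb)] + cb[-1]) / 2 + 0.5
  interp1 <- function(pos, centers) {
    k <- length(centers)
    i0 <- findInterval(pos, centers)
    i0c <- pmin(pmax(i0, 1L), k)
    i1c <- pmin(i0 + 1L, k)
    wgt <- ifelse(i1c > i0c & i0 >= 1L,
                  (pos - centers[i0c]) / (centers[i1c] - centers[i0c]), 0)
    wgt[i0 < 1L] <- 0
    list(lo = i0c, hi = pmax(i1c, 1L), w = pmin(pmax(wgt, 0), 1))
  }
  ri <- interp1(seq_len(h), centers_r)
  ci <- interp1(seq_len(w), centers_c)

  ti_lo <- matrix(ri$lo, h, w); ti_hi <- matrix(ri$hi, h, w)
  tj_lo <- matrix(ci$lo, h, w, byrow = TRUE); tj_hi <- matrix(ci$hi, h, w, byrow = TRUE)
  wy <- matrix(ri$w, h, w); wx <- matrix(ci$w, h, w, byrow = TRUE)

  if (all(ident)) return(ch)   # zero-contrast everywhere: exact identity

  b1 <- as.vector(bin) + 1L
  look <- function(ti, tj) {
    m <- lut[cbind(as.vector(ti), as.vector(tj), b1)]
    idv <- ident[cbind(as.vector(ti), as.vector(tj))]
    m[idv] <- as.vector(ch)[idv]        # identity tiles map exactly
    m
  }
  out <- (1 - wy) * (1 - wx) * look(ti_lo, tj_lo) +
         (1 - wy) * wx       * look(ti_lo, tj_hi) +
         wy       * (1 - wx) * look(ti_hi, tj_lo) +
         wy       * wx       * look(ti_hi, tj_hi)
  matrix(pmin(pmax(out, 0), 1), h, w)
}

#' CLAHE histogram equalization of an RGB image
#'
#' Contrast-limited adaptive histogram equalization with the clip limit
#' interpreted as a fraction of the per-tile pixel count (so `clipLimit =
#' 0.005` clips each histogram bin at 0.5% of the tile's pixels). In the
#' default `"luminance"` colour mode the Rec.601 luminance channel is
#' equalized and the RGB channels are rescaled by the luminance ratio, which
#' preserves hue; `"perchannel"` equalizes R, G and B independently.
#'
#' Zero-contrast tiles keep the identity mapping, so a constant image passes
#' through unchanged.
#'
#' @param image numeric `(height, width, 3)` array with values in `[0, 1]`.
#' @param config a [PreprocessConfig-class]; only the CLAHE fields are used.
#' @return an array of the same shape with values in `[0, 1]`.
#' @examples
#' img <- sceneImage(generateScene(sceneParams(width = 64L, height = 48L)))
#' eq <- claheEqualize(img, preprocessConfig(tileGrid = c(4L, 4L)))
#' @export
claheEqualize <- function(image, config = preprocessConfig()) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("claheEqualize expects an RGB (height, width, 3) array")
  rows <- config@tileGrid[1]; cols <- config@tileGrid[2]
  if (d[1] < rows || d[2] < cols)
    stop("image smaller than the CLAHE tile grid")
  if (config@colorMode == "perchannel") {
    out <- image
    for (k in 1:3)
      out[, , k] <- .claheChannel(image[, , k], rows, cols,
                                  config@clipLimit, config@bins)
    return(out)
  }
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  yn <- .claheChannel(y, rows, cols, config@clipLimit, config@bins)
  ratio <- yn / pmax(y, 1e-6)
  out <- image * as.vector(ratio)   # recycled over channels
  pmin(pmax(out, 0), 1)
}

# 1-D area-overlap weights: row k of the returned (nout x nin) matrix holds
# the fractional coverage of input pixels by output pixel k; rows sum to 1.
.areaWeights <- function(nin, nout) {
  s <- nin / nout
  w <- matrix(0, nout, nin)
  for (k in seq_len(nout)) {
    a <- (k - 1) * s; b <- k * s
    i0 <- floor(a) + 1L; i1 <- ceiling(b)
    for (i in i0:min(i1, nin)) {
      ov <- min(b, i) - max(a, i - 1)
      if (ov > 0) w[k, i] <- ov / s
    }
  }
  w
}

#' Area-based image downscaling
#'
#' Each output pixel is the area-weighted average of the source pixels it
#' covers (pixel-area relation resampling, the INTER_AREA rule). Total image
#' brightness is preserved, and the operation is exact for integer
#' downscaling factors (block means). Upscaling is out of scope and raises
#' an error.
#'
#' @param image a `(height, width)` matrix or `(height, width, channels)`
#'   array.
#' @param targetSize integer `(width, height)` of the output.
#' @return the downscaled raster of the same arity as the input.
#' @examples
#' downscaleArea(matrix(c(0, 0, 1, 1), 2, 2), c(1L, 1L))  # 0.5
#' @export
downscaleArea <- function(image, targetSize) {
  tw <- as.integer(targetSize[1]); th <- as.integer(targetSize[2])
  d <- dim(image)
  if (th > d[1] || tw > d[2])
    stop("downscaleArea only downscales; target exceeds source size")
  A <- .areaWeights(d[1], th)           # rows
  B <- .areaWeights(d[2], tw)           # cols
  if (length(d) == 2L) return(A %*% image %*% t(B))
  out <- array(0, c(th, tw, d[3]))
  for (k in seq_len(d[3])) out[, , k] <- A %*% image[, , k] %*% t(B)
  out
}

#' Nearest-neighbour mask downscaling with re-binarization
#'
#' Masks are never interpolated: area averaging would create non-binary
#' values along the wound boundary. Each output pixel takes the nearest
#' source pixel, then the result is re-binarized at 0.5.
#'
#' @param mask binary `(height, width)` matrix.
#' @param targetSize integer `(width, height)`.
#' @return binary matrix of size `(height, width) = rev(targetSize)`.
#' @export
downscaleMask <- function(mask, targetSize) {
  tw <- as.integer(targetSize[1]); th <- as.integer(targetSize[2])
  d <- dim(mask)
  if (th > d[1] || tw > d[2])
    stop("downscaleMask only downscales; target exceeds source size")
  ri <- pmin(pmax(ceiling((seq_len(th) - 0.5) * d[1] / th), 1L), d[1])
  ci <- pmin(pmax(ceiling((seq_len(tw) - 0.5) * d[2] / tw), 1L), d[2])
  out <- mask[ri, ci, drop = FALSE]
  (out > 0.5) * 1
}

#' Convert a raster to working precision
#'
#' Integer-valued 8-bit rasters (values in 0..255) are scaled by 1/255 to
#' the continuous unit interval; rasters already in `[0, 1]` pass through
#' unchanged. Downstream arithmetic runs in floating point on this scale.
#'
#' @param image numeric matrix or array.
#' @return raster with values in `[0, 1]`.
#' @examples
#' toWorkingPrecision(matrix(c(0, 128, 255), 1, 3))
#' @export
toWorkingPrecision <- function(image) {
  if (is.integer(image) || max(image, na.rm = TRUE) > 1) {
    out <- image / 255
    storage.mode(out) <- "numeric"
    return(out)
  }
  storage.mode(image) <- "numeric"
  image
}

#' Full preprocessing pipeline
#'
#' Composition, in order, of [claheEqualize()], [downscaleArea()] to the
#' configured working resolution, and [toWorkingPrecision()]. 8-bit inputs
#' are normalized to `[0, 1]` before equalization.
#'
#' @param image RGB `(height, width, 3)` raster, 8-bit or `[0, 1]`.
#' @param config a [PreprocessConfig-class].
#' @return `(targetHeight, targetWidth, 3)` array with values in `[0, 1]`.
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  x <- toWorkingPrecision(image)
  x <- claheEqualize(x, config)
  x <- downscaleArea(x, config@targetSize)
  toWorkingPrecision(x)
}
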