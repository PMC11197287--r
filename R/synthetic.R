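# Synthetic scratch-assay scenes with exact ground truth.
#
# The generative model is a band-plus-roughness geometry: a confluent,
# procedurally textured cell sheet is crossed by a low-texture wound band
# whose edges deviate from a straight line by a smooth pseudo-periodic
# offset. Closure erodes the band inward from both edges; spindle-shaped
# cells (elongated rotated ellipses, labelled as cells) migrate into the
# band. Multiplicative radial shading emulates vignetting and additive
# Gaussian noise emulates sensor noise. Every scene is a pure function of
# (SceneParams, seed).

# Smooth pseudo-periodic offset profile in [-amp, amp], length n.
.roughProfile <- function(n, amp, freq) {
  if (amp <= 0 || freq <= 0) return(numeric(n))
  t <- seq_len(n) / n
  r <- numeric(n)
  for (k in 1:3) {
    f <- freq * stats::runif(1, 0.5, 1.5) * k / 2
    r <- r + stats::runif(1, 0.5, 1) * sin(2 * pi * (f * t + stats::runif(1)))
  }
  amp * r / max(abs(r))
}

# Stamp an elongated elliptical sprite (value 1 = cell) into a logical mask.
.stampSpindle <- function(cellMask, cy, cx, a, b, theta) {
  h <- nrow(cellMask); w <- ncol(cellMask)
  r <- ceiling(a)
  ys <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cellMask[ys, xs] <- cellMask[ys, xs] | inside
  cellMask
}

#' Generate one synthetic scratch-assay scene
#'
#' Deterministic given its parameters: two calls with the same
#' [SceneParams-class] return bitwise-identical images and masks. The mask
#' follows the labelling convention 1 = cell (white), 0 = wound (black).
#'
#' Geometry: the fresh wound band spans `woundWidthFrac` of the image; at
#' closure fraction c both edges have moved inward so the band width is
#' `(1 - c)` times the fresh width, and edge roughness shrinks with the
#' band, which makes bands at increasing closure strictly nested (wound area
#' is nonincreasing in c, and zero at c = 1). With zero roughness and no
#' migrating cells the band area equals the analytic band area to the pixel.
#'
#' @param params a [SceneParams-class].
#' @return a [LabeledImage-class] with provenance metadata.
#' @examples
#' scene <- generateScene(sceneParams(width = 100L, height = 60L,
#'                                    edgeRoughnessAmp = 0,
#'                                    nMigratingCells = 0L))
#' woundArea(sceneMask(scene))  # exactly 25 * 60
#' @export
generateScene <- function(params) {
  validObject(params)
  withr::with_seed(params@seed, .generateSceneImpl(params))
}

.generateSceneImpl <- function(params) {
  # Work in the vertical-wound frame; transpose at the end if horizontal.
  vert <- params@woundAxis == "vertical"
  w <- if (vert) params@width else params@height
  h <- if (vert) params@height else params@width
  cfr <- params@closureFrac

  w0 <- params@woundWidthFrac * w        # fresh band width, pixels
  cx <- w / 2
  rl <- .roughProfile(h, params@edgeRoughnessAmp, params@edgeRoughnessFreq)
  rr <- .roughProfile(h, params@edgeRoughnessAmp, params@edgeRoughnessFreq)
  left <- cx - (1 - cfr) * (w0 / 2 + rl)   # per-row band bounds
  right <- cx + (1 - cfr) * (w0 / 2 + rr)

  centers <- seq_len(w) - 0.5
  wound <- outer(left, centers, function(l, x) x > l) &
           outer(right, centers, function(r, x) x <= r)   # h x w logical
  if (cfr >= 1) wound[] <- FALSE

  # Migrating spindle cells inside the band (mask label 1 = cell).
  cellSprites <- matrix(FALSE, h, w)
  if (params@nMigratingCells > 0L && any(wound)) {
    span <- min(h, w)
    for (k in seq_len(params@nMigratingCells)) {
      cy <- stats::runif(1, 1, h)
      row <- pmin(pmax(round(cy), 1L), h)
      if (right[row] - left[row] < 2) next   # band locally closed
      cx_k <- stats::runif(1, left[row] + 1, right[row] - 1)
      a <- stats::runif(1, 0.04, 0.09) * span   # semi-major (spindle length)
      b <- stats::runif(1, 0.02, 0.035) * span  # semi-minor
      theta <- stats::runif(1, 0, pi)
      cellSprites <- .stampSpindle(cellSprites, cy, cx_k, a, max(b, 1), theta)
    }
  }

  mask <- matrix(1, h, w)
  mask[wound & !cellSprites] <- 0

  # Intensity model: flat bright band, textured cell regions. The blur
  # kernel (2*ceiling(3*sigma)+1 wide) must fit the canvas, so the texture
  # scale is clamped on very small scenes.
  sigma <- min(params@cellTextureScale,
               max(0.5, (floor((min(h, w) - 1) / 2) - 1) / 3))
  tex <- matrix(stats::rnorm(h * w), h, w)
  tex <- EBImage::imageData(EBImage::gblur(tex, sigma = sigma))
  tex <- tex / max(stats::sd(as.vector(tex)), 1e-8)
  img <- matrix(params@woundIntensityMean, h, w)
  cells <- mask == 1
  img[cells] <- params@cellIntensityMean + 0.14 * tex[cells]

  # Radial vignetting (multiplicative), then sensor noise (additive).
  yy <- (seq_len(h) - (h + 1) / 2) / (h / 2)
  xx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
  r2 <- outer(yy^2, rep(1, w)) + outer(rep(1, h), xx^2)
  img <- img * (1 - params@shadingStrength * r2 / 2)
  img <- img + matrix(stats::rnorm(h * w, 0, params@noiseSd), h, w)
  img <- pmin(pmax(img, 0), 1)

  if (!vert) {
    img <- t(img)
    mask <- t(mask)
  }
  # Slight warm tint so the three RGB channels are not identical.
  rgb <- array(0, c(nrow(img), ncol(img), 3L))
  rgb[, , 1] <- img
  rgb[, , 2] <- pmin(pmax(img * 0.97, 0), 1)
  rgb[, , 3] <- pmin(pmax(img * 0.92, 0), 1)

  labeledImage(rgb, mask, meta = list(
    params = params, seed = params@seed, closureFrac = params@closureFrac))
}

#' Generate a wound-closure time series
#'
#' One scene per closure fraction, all from the same seed, emulating a field
#' of view imaged at successive time points: texture, edge roughness and
#' cell placement are shared across frames while the wound band erodes
#' inward, so wound area is nonincreasing along the series.
#'
#' @param params a [SceneParams-class]; its `closureFrac` is ignored.
#' @param closureFracs nondecreasing vector of closure fractions in `[0, 1]`.
#' @return list of [LabeledImage-class], one per time point.
#' @export
generateTimeseries <- function(params, closureFracs) {
  if (any(closureFracs < 0 | closureFracs > 1))
    stop("closure fractions must lie in [0, 1]")
  if (is.unsorted(closureFracs))
    stop("closure fractions must be nondecreasing (wounds do not reopen)")
  lapply(closureFracs, function(cf) {
    p <- params
    p@closureFrac <- as.numeric(cf)
    generateScene(p)
  })
}

#' Write a labelled dataset to disk
#'
#' Images and masks are written as lossless 8-bit PNG (or TIFF); images are
#' quantized to 8 bits so that reading back reproduces the files' rasters
#' exactly, and masks are stored as {0, 255} single-channel rasters mapped
#' back to {0, 1} on read. A CSV manifest lists the pairs with their
#' provenance.
#'
#' @param scenes list of [LabeledImage-class].
#' @param directory output directory (created if missing).
#' @param format `"png"` (default) or `"tiff"`; lossy formats are refused.
#' @param stems optional file stems, default `img_0001`, ...
#' @return the manifest data.frame (also written to `manifest.csv`), with
#'   columns image_path, mask_path, seed, closure_frac, magnification_tag.
#' @export
writeDataset <- function(scenes, directory, format = c("png", "tiff"),
                         stems = NULL) {
  if (is.character(format) && length(format) == 1L &&
      tolower(format) %in% c("jpg", "jpeg"))
    stop("lossy formats are not allowed for masks; use png or tiff")
  format <- match.arg(format)
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (is.null(stems)) stems <- sprintf("img_%04d", seq_along(scenes))
  writeOne <- function(x, path) {
    if (format == "png") png::writePNG(x, path) else tiff::writeTIFF(x, path)
  }
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    img8 <- round(sc@image * 255) / 255   # 8-bit quantization, explicit
    ip <- file.path(directory, paste0(stems[i], ".", format))
    mp <- file.path(directory, paste0(stems[i], "_mask.", format))
    writeOne(img8, ip)
    writeOne(sc@mask, mp)
    data.frame(image_path = basename(ip), mask_path = basename(mp),
               seed = sc@meta$seed %||% NA_integer_,
               closure_frac = sc@meta$closureFrac %||% NA_real_,
               magnification_tag = sc@meta$magnification %||% "synthetic")
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a dataset written by [writeDataset()]
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return list of [LabeledImage-class] in manifest order.
#' @export
readDataset <- function(directory) {
  mf <- utils::read.csv(file.path(directory, "manifest.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    img <- .readRaster(file.path(directory, mf$image_path[i]))
    msk <- .readRaster(file.path(directory, mf$mask_path[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    labeledImage(.asRGB(img), (msk > 0.5) * 1, meta = list(
      seed = mf$seed[i], closureFrac = mf$closure_frac[i],
      magnification = mf$magnification_tag[i],
      image_path = mf$image_path[i], mask_path = mf$mask_path[i]))
  })
}

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported raster format: ", ext)
}

.asRGB <- function(img) {
  d <- dim(img)
  if (length(d) == 2L) return(array(img, c(d, 3L)))
  if (d[3] >= 3L) return(img[, , 1:3, drop = FALSE])
  array(img[, , 1], c(d[1:2], 3L))
}
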