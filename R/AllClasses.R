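#' @import methods
#' @importFrom stats rnorm runif
NULL

# ---------------------------------------------------------------------------
# Parameter / configuration classes
# ---------------------------------------------------------------------------

#' Scene parameters for the synthetic scratch-assay generator
#'
#' Describes one synthetic brightfield-style scratch-assay scene: a textured
#' confluent cell sheet crossed by a low-texture wound band with rough edges,
#' optionally populated by spindle-shaped cells migrating into the wound,
#' under multiplicative vignetting and additive Gaussian noise.
#'
#' @slot width,height canvas size in pixels.
#' @slot woundAxis `"vertical"` (band runs top to bottom) or `"horizontal"`.
#' @slot woundWidthFrac fraction of the image span occupied by the fresh
#'   wound band, in (0, 1).
#' @slot edgeRoughnessAmp maximum deviation (pixels) of the wound edge from a
#'   straight line.
#' @slot edgeRoughnessFreq roughness frequency in cycles per image height.
#' @slot closureFrac wound closure in `[0, 1]`: 0 is a fresh scratch, 1 a
#'   fully closed wound.
#' @slot nMigratingCells number of spindle-shaped cells stamped inside the
#'   wound band (labelled as cells, i.e. mask value 1).
#' @slot cellTextureScale correlation length (pixels) of the cell-sheet
#'   texture field.
#' @slot cellIntensityMean,woundIntensityMean mean intensities in `[0, 1]` of
#'   the cell sheet and the cell-free band.
#' @slot shadingStrength strength in `[0, 1]` of the radial vignetting.
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise.
#' @slot seed integer seed; the generated scene is a pure function of
#'   (parameters, seed).
#' @seealso [sceneParams()], [generateScene()]
#' @exportClass SceneParams
setClass("SceneParams", representation(
  width = "integer", height = "integer", woundAxis = "character",
  woundWidthFrac = "numeric", edgeRoughnessAmp = "numeric",
  edgeRoughnessFreq = "numeric", closureFrac = "numeric",
  nMigratingCells = "integer", cellTextureScale = "numeric",
  cellIntensityMean = "numeric", woundIntensityMean = "numeric",
  shadingStrength = "numeric", noiseSd = "numeric", seed = "integer"
))

setValidity("SceneParams", function(object) {
  msg <- character()
  if (object@width < 4L || object@height < 4L)
    msg <- c(msg, "width and height must be at least 4 pixels")
  if (!object@woundAxis %in% c("vertical", "horizontal"))
    msg <- c(msg, "woundAxis must be 'vertical' or 'horizontal'")
  if (object@woundWidthFrac <= 0 || object@woundWidthFrac >= 1)
    msg <- c(msg, "woundWidthFrac must lie strictly in (0, 1)")
  if (object@closureFrac < 0 || object@closureFrac > 1)
    msg <- c(msg, "closureFrac must lie in [0, 1]")
  if (object@edgeRoughnessAmp < 0) msg <- c(msg, "edgeRoughnessAmp must be >= 0")
  if (object@edgeRoughnessFreq < 0) msg <- c(msg, "edgeRoughnessFreq must be >= 0")
  if (object@nMigratingCells < 0L) msg <- c(msg, "nMigratingCells must be >= 0")
  if (object@cellTextureScale <= 0) msg <- c(msg, "cellTextureScale must be > 0")
  rng01 <- function(x) x >= 0 && x <= 1
  if (!rng01(object@cellIntensityMean) || !rng01(object@woundIntensityMean))
    msg <- c(msg, "intensity means must lie in [0, 1]")
  if (!rng01(object@shadingStrength)) msg <- c(msg, "shadingStrength must lie in [0, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct scene parameters
#'
#' Defaults describe a desk-scale scene at the working resolution used by the
#' rest of the pipeline: a quarter-width vertical wound with moderately rough
#' edges, a handful of migrating spindle cells, mild vignetting and noise.
#'
#' @param width,height canvas size in pixels (default 1024 x 768, the
#'   pipeline's working resolution).
#' @param woundAxis `"vertical"` or `"horizontal"`.
#' @param woundWidthFrac fraction of the span covered by the fresh wound.
#' @param edgeRoughnessAmp edge roughness amplitude in pixels.
#' @param edgeRoughnessFreq roughness frequency in cycles per image.
#' @param closureFrac wound closure fraction in `[0, 1]`.
#' @param nMigratingCells spindle cells stamped inside the wound band.
#' @param cellTextureScale texture correlation length in pixels.
#' @param cellIntensityMean,woundIntensityMean mean intensities in `[0, 1]`.
#' @param shadingStrength radial vignetting strength in `[0, 1]`.
#' @param noiseSd additive Gaussian noise standard deviation.
#' @param seed integer seed.
#' @return A validated [SceneParams-class] object.
#' @examples
#' p <- sceneParams(width = 128L, height = 96L, seed = 7L)
#' scene <- generateScene(p)
#' @export
sceneParams <- function(width = 1024L, height = 768L,
                        woundAxis = c("vertical", "horizontal"),
                        woundWidthFrac = 0.25,
                        edgeRoughnessAmp = 0.03 * width,
                        edgeRoughnessFreq = 3,
                        closureFrac = 0,
                        nMigratingCells = 6L,
                        cellTextureScale = 2.5,
                        cellIntensityMean = 0.42,
                        woundIntensityMean = 0.66,
                        shadingStrength = 0.15,
                        noiseSd = 0.015,
                        seed = 1L) {
  woundAxis <- match.arg(woundAxis)
  new("SceneParams",
      width = as.integer(width), height = as.integer(height),
      woundAxis = woundAxis, woundWidthFrac = as.numeric(woundWidthFrac),
      edgeRoughnessAmp = as.numeric(edgeRoughnessAmp),
      edgeRoughnessFreq = as.numeric(edgeRoughnessFreq),
      closureFrac = as.numeric(closureFrac),
      nMigratingCells = as.integer(nMigratingCells),
      cellTextureScale = as.numeric(cellTextureScale),
      cellIntensityMean = as.numeric(cellIntensityMean),
      woundIntensityMean = as.numeric(woundIntensityMean),
      shadingStrength = as.numeric(shadingStrength),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Preprocessing configuration
#'
#' @slot clipLimit CLAHE clip limit, interpreted as the fraction of the tile
#'   pixel count at which histogram bins are clipped (the normalized-fraction
#'   convention; 0.005 by default).
#' @slot tileGrid integer `(rows, cols)` CLAHE tile grid.
#' @slot bins number of histogram bins.
#' @slot targetSize integer `(width, height)` working resolution.
#' @slot colorMode `"luminance"` applies CLAHE to the luminance channel and
#'   rescales chroma multiplicatively; `"perchannel"` equalizes each RGB
#'   channel independently.
#' @exportClass PreprocessConfig
setClass("PreprocessConfig", representation(
  clipLimit = "numeric", tileGrid = "integer", bins = "integer",
  targetSize = "integer", colorMode = "character"
))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@clipLimit <= 0) msg <- c(msg, "clipLimit must be > 0")
  if (length(object@tileGrid) != 2L || any(object@tileGrid < 1L))
    msg <- c(msg, "tileGrid must be two positive integers")
  if (object@bins < 2L) msg <- c(msg, "bins must be >= 2")
  if (length(object@targetSize) != 2L || any(object@targetSize < 2L))
    msg <- c(msg, "targetSize must be two positive integers")
  if (any(object@targetSize %% 2L != 0L))
    msg <- c(msg, "target dimensions must be even (required by quadrant tiling)")
  if (!object@colorMode %in% c("luminance", "perchannel"))
    msg <- c(msg, "colorMode must be 'luminance' or 'perchannel'")
  if (length(msg)) msg else TRUE
})

#' Construct a preprocessing configuration
#'
#' @param clipLimit CLAHE clip limit as a fraction of tile pixel count.
#' @param tileGrid `(rows, cols)` of the CLAHE tile grid.
#' @param bins histogram bins for CLAHE.
#' @param targetSize `(width, height)` of the working resolution; both must
#'   be even so that quadrant tiling is exact.
#' @param colorMode `"luminance"` (default) or `"perchannel"`.
#' @return A validated [PreprocessConfig-class] object.
#' @export
preprocessConfig <- function(clipLimit = 0.005, tileGrid = c(8L, 8L),
                             bins = 256L, targetSize = c(1024L, 768L),
                             colorMode = c("luminance", "perchannel")) {
  colorMode <- match.arg(colorMode)
  new("PreprocessConfig", clipLimit = as.numeric(clipLimit),
      tileGrid = as.integer(tileGrid), bins = as.integer(bins),
      targetSize = as.integer(targetSize), colorMode = colorMode)
}

#' Architecture configuration shared by the three U-net variants
#'
#' A single hyperparameter surface from which the plain U-net, the
#' nested-skip U-net++ and the attention-gated U-net are built, so that the
#' three variants differ only in skip-path topology.
#'
#' @slot variant one of `"unet"`, `"unetpp"`, `"attention_unet"`.
#' @slot depth number of resolution levels (default 5).
#' @slot inputSize integer `(width, height, channels)`; spatial dims must be
#'   divisible by `2^(depth - 1)`.
#' @slot baseFilters filters at the first level, doubling per level.
#' @slot useBatchnorm logical; conv-BN-ReLU blocks when `TRUE`.
#' @slot upsampling `"transposed"` (learned 2x2 stride-2 deconvolution) or
#'   `"bilinear"` (fixed bilinear upsample followed by a 1x1 convolution).
#' @exportClass ArchitectureConfig
setClass("ArchitectureConfig", representation(
  variant = "character", depth = "integer", inputSize = "integer",
  baseFilters = "integer", useBatchnorm = "logical", upsampling = "character"
))

setValidity("ArchitectureConfig", function(object) {
  msg <- character()
  if (!object@variant %in% c("unet", "unetpp", "attention_unet"))
    msg <- c(msg, "variant must be one of 'unet', 'unetpp', 'attention_unet'")
  if (object@depth < 2L) msg <- c(msg, "depth must be >= 2")
  if (length(object@inputSize) != 3L || any(object@inputSize < 1L))
    msg <- c(msg, "inputSize must be (width, height, channels)")
  div <- 2L^(object@depth - 1L)
  if (length(object@inputSize) == 3L &&
      any(object@inputSize[1:2] %% div != 0L))
    msg <- c(msg, sprintf(
      "input spatial dims must be divisible by 2^(depth-1) = %d", div))
  if (object@baseFilters < 1L) msg <- c(msg, "baseFilters must be >= 1")
  if (!object@upsampling %in% c("transposed", "bilinear"))
    msg <- c(msg, "upsampling must be 'transposed' or 'bilinear'")
  if (length(msg)) msg else TRUE
})

#' Construct an architecture configuration
#'
#' @param variant `"unet"`, `"unetpp"` or `"attention_unet"`.
#' @param depth resolution levels; the default 5-level network halves the
#'   spatial dims four times via 2x2 max-pooling.
#' @param inputSize `(width, height, channels)`, default `(512, 384, 3)` —
#'   the quadrant patch size at the 1024x768 working resolution.
#' @param baseFilters filters at level 1 (doubling per level).
#' @param useBatchnorm use conv-BN-ReLU blocks (default `TRUE`).
#' @param upsampling decoder upsampling operator.
#' @return A validated [ArchitectureConfig-class] object.
#' @examples
#' cfg <- architectureConfig("unet", depth = 3L, inputSize = c(64L, 48L, 3L),
#'                           baseFilters = 8L)
#' @export
architectureConfig <- function(variant = c("unet", "unetpp", "attention_unet"),
                               depth = 5L, inputSize = c(512L, 384L, 3L),
                               baseFilters = 16L, useBatchnorm = TRUE,
                               upsampling = c("transposed", "bilinear")) {
  variant <- match.arg(variant)
  upsampling <- match.arg(upsampling)
  new("ArchitectureConfig", variant = variant, depth = as.integer(depth),
      inputSize = as.integer(inputSize), baseFilters = as.integer(baseFilters),
      useBatchnorm = isTRUE(useBatchnorm), upsampling = upsampling)
}

#' Training configuration
#'
#' Defaults mirror the reference protocol: Adam at learning rate 1e-3 with a
#' per-epoch exponential decay of 0.9, batch size 4, 50 epochs, soft dice
#' loss, and a strict 0.5 binarization threshold.
#'
#' @slot learningRate initial Adam learning rate.
#' @slot decayRate per-epoch exponential decay factor (`lr_e = lr0 * rate^e`).
#' @slot batchSize training batch size.
#' @slot epochs number of epochs (no early stopping).
#' @slot binarizationThreshold probability threshold; values strictly greater
#'   map to 1.
#' @slot smoothEps smoothing constant of the soft dice loss.
#' @slot seed integer seed controlling initialization order, shuffling.
#' @exportClass TrainingConfig
setClass("TrainingConfig", representation(
  learningRate = "numeric", decayRate = "numeric", batchSize = "integer",
  epochs = "integer", binarizationThreshold = "numeric",
  smoothEps = "numeric", seed = "integer"
))

setValidity("TrainingConfig", function(object) {
  msg <- character()
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@decayRate <= 0) msg <- c(msg, "decayRate must be > 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@binarizationThreshold <= 0 || object@binarizationThreshold >= 1)
    msg <- c(msg, "binarizationThreshold must lie strictly in (0, 1)")
  if (object@smoothEps <= 0) msg <- c(msg, "smoothEps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a training configuration
#'
#' @param learningRate initial Adam learning rate (default 1e-3).
#' @param decayRate per-epoch exponential decay factor (default 0.9).
#' @param batchSize batch size (default 4).
#' @param epochs number of epochs (default 50).
#' @param binarizationThreshold strict threshold for mask binarization.
#' @param smoothEps soft-dice smoothing constant.
#' @param seed integer seed.
#' @return A validated [TrainingConfig-class] object.
#' @export
trainingConfig <- function(learningRate = 1e-3, decayRate = 0.9,
                           batchSize = 4L, epochs = 50L,
                           binarizationThreshold = 0.5, smoothEps = 1e-6,
                           seed = 1L) {
  new("TrainingConfig", learningRate = as.numeric(learningRate),
      decayRate = as.numeric(decayRate), batchSize = as.integer(batchSize),
      epochs = as.integer(epochs),
      binarizationThreshold = as.numeric(binarizationThreshold),
      smoothEps = as.numeric(smoothEps), seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# Data classes
# ---------------------------------------------------------------------------

#' A microscopy image paired with its binary ground-truth mask
#'
#' The mask follows the assay labelling convention: value 1 (white) marks
#' cell-containing regions (ROIs), value 0 (black) marks the wound.
#'
#' @slot image numeric array `(height, width, 3)` with values in `[0, 1]`.
#' @slot mask numeric matrix `(height, width)` containing only 0 and 1.
#' @slot meta free-form provenance list (generator parameters, seed,
#'   closure fraction, file paths, ...).
#' @seealso [generateScene()], [sceneImage()], [sceneMask()]
#' @exportClass LabeledImage
setClass("LabeledImage", representation(
  image = "array", mask = "matrix", meta = "list"
))

setValidity("LabeledImage", function(object) {
  msg <- character()
  di <- dim(object@image)
  if (length(di) != 3L || di[3] != 3L)
    msg <- c(msg, "image must be a (height, width, 3) array")
  if (!identical(di[1:2], dim(object@mask)))
    msg <- c(msg, "image and mask spatial dimensions must be equal")
  if (!all(object@mask %in% c(0, 1)))
    msg <- c(msg, "mask must contain only values {0, 1}")
  if (length(msg)) msg else TRUE
})

#' @describeIn LabeledImage-class constructor.
#' @param image `(height, width, 3)` numeric array in `[0, 1]`.
#' @param mask `(height, width)` binary matrix (1 = cell, 0 = wound).
#' @param meta provenance list.
#' @export
labeledImage <- function(image, mask, meta = list()) {
  storage.mode(mask) <- "numeric"
  new("LabeledImage", image = image, mask = mask, meta = meta)
}

#' @describeIn LabeledImage-class the image raster.
#' @param x a `LabeledImage`.
#' @export
sceneImage <- function(x) x@image

#' @describeIn LabeledImage-class the binary ground-truth mask.
#' @export
sceneMask <- function(x) x@mask

#' @describeIn LabeledImage-class the provenance metadata list.
#' @export
sceneMeta <- function(x) x@meta

setMethod("show", "LabeledImage", function(object) {
  d <- dim(object@image)
  wa <- sum(object@mask == 0)
  cat(sprintf("LabeledImage %dx%d px | wound area %d px (%.1f%%)\n",
              d[2], d[1], wa, 100 * wa / prod(d[1:2])))
  if (!is.null(object@meta$closureFrac))
    cat(sprintf("  closure fraction %.2f, seed %s\n",
                object@meta$closureFrac,
                as.character(object@meta$seed %||% "?")))
})

#' Four spatial quadrants of a raster
#'
#' Patches are kept in the fixed order top-left, top-right, bottom-left,
#' bottom-right; [mergeQuadrants()] is the exact inverse of
#' [splitQuadrants()].
#'
#' @slot patches list of four rasters, each exactly half the source size in
#'   each spatial dimension.
#' @slot sourceSize integer `(height, width)` of the source raster.
#' @exportClass QuadrantSet
setClass("QuadrantSet", representation(
  patches = "list", sourceSize = "integer"
))

setValidity("QuadrantSet", function(object) {
  msg <- character()
  if (length(object@patches) != 4L)
    msg <- c(msg, "a QuadrantSet holds exactly four patches")
  half <- object@sourceSize %/% 2L
  ok <- vapply(object@patches, function(p) {
    dp <- dim(p)
    length(dp) >= 2L && all(dp[1:2] == half)
  }, logical(1))
  if (!all(ok))
    msg <- c(msg, "each patch must be exactly (height/2, width/2)")
  if (length(msg)) msg else TRUE
})

#' @describeIn QuadrantSet-class the list of patches (TL, TR, BL, BR).
#' @param x a `QuadrantSet`.
#' @export
patches <- function(x) x@patches

#' @describeIn QuadrantSet-class the `(height, width)` of the source raster.
#' @export
sourceSize <- function(x) x@sourceSize

setMethod("show", "QuadrantSet", function(object) {
  h <- object@sourceSize[1] %/% 2L
  w <- object@sourceSize[2] %/% 2L
  cat(sprintf("QuadrantSet: 4 patches of %dx%d px (source %dx%d)\n",
              w, h, object@sourceSize[2], object@sourceSize[1]))
})

#' A built segmentation model
#'
#' Wraps the architecture configuration together with the parameter and
#' batch-norm-state environments of the CNN engine. Parameters are owned by
#' the object; [trainModel()] works on a deep copy so that a model is never
#' mutated behind the caller's back.
#'
#' @slot config an [ArchitectureConfig-class].
#' @slot params environment mapping parameter names to numeric arrays.
#' @slot state environment of batch-norm running statistics.
#' @slot seed integer seed the parameters were initialized from.
#' @seealso [buildModel()], [parameterCount()], [predictProb()]
#' @exportClass SegmentationModel
setClass("SegmentationModel", representation(
  config = "ArchitectureConfig", params = "environment",
  state = "environment", seed = "integer"
))

setMethod("show", "SegmentationModel", function(object) {
  cfg <- object@config
  cat(sprintf("SegmentationModel <%s> depth %d, base filters %d\n",
              cfg@variant, cfg@depth, cfg@baseFilters))
  cat(sprintf("  input %dx%dx%d | %s upsampling | %s trainable parameters\n",
              cfg@inputSize[1], cfg@inputSize[2], cfg@inputSize[3],
              cfg@upsampling, format(parameterCount(object), big.mark = ",")))
})

#' Train/validation/test index partition
#'
#' Indices refer to whole source images; splitting happens before quadrant
#' tiling so the four patches of one image can never leak across sets.
#'
#' @slot test,train,val disjoint integer index vectors partitioning `1:n`.
#' @slot folds optional list of k disjoint validation-index vectors
#'   partitioning the non-test indices.
#' @exportClass SplitSpec
setClass("SplitSpec", representation(
  test = "integer", train = "integer", val = "integer", folds = "list"
))

setValidity("SplitSpec", function(object) {
  all_idx <- c(object@test, object@train, object@val)
  msg <- character()
  if (anyDuplicated(all_idx))
    msg <- c(msg, "test/train/val must be disjoint")
  if (!setequal(all_idx, seq_len(length(all_idx))))
    msg <- c(msg, "test/train/val must partition 1:n")
  if (length(object@folds)) {
    fi <- unlist(object@folds)
    if (anyDuplicated(fi) || !setequal(fi, c(object@train, object@val)))
      msg <- c(msg, "folds must partition the non-test indices")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplitSpec", function(object) {
  cat(sprintf("SplitSpec: %d test / %d train / %d val",
              length(object@test), length(object@train), length(object@val)))
  if (length(object@folds)) cat(sprintf(" | %d CV folds", length(object@folds)))
  cat("\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
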