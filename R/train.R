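# Training: soft dice loss, whole-image data splitting (before tiling, so
# quadrants never leak across sets), 5-fold cross-validation index
# management, and the Adam training loop with per-epoch exponential
# learning-rate decay.

#' Soft dice loss
#'
#' `1 - (2 * sum(a*b) + eps) / (sum(a) + sum(b) + eps)` where `a`, `b` are
#' the per-pixel scores of the positive class. The positive class defaults
#' to the wound (mask value 0, scored as `1 - p`), matching the
#' wound-as-positive convention of the evaluation metrics: on binarized
#' predictions `1 - diceLoss(pred, gt)` equals the DSC of
#' [metricsFromCounts()] up to the smoothing constant. `positive = "cell"`
#' scores the white ROI class instead.
#'
#' @param probabilities numeric raster in `[0, 1]` (cell probability, the
#'   network's native output convention).
#' @param mask binary raster of identical shape (1 = cell, 0 = wound).
#' @param smoothEps smoothing constant.
#' @param positive which class the overlap is computed on.
#' @return scalar loss in `[0, 1]`.
#' @examples
#' g <- matrix(c(1, 1, 0, 0), 2, 2)
#' diceLoss(g, g)                  # ~0
#' diceLoss(1 - g, g)              # ~1
#' @export
diceLoss <- function(probabilities, mask, smoothEps = 1e-6,
                     positive = c("wound", "cell")) {
  positive <- match.arg(positive)
  if (!identical(dim(probabilities), dim(mask)))
    stop("probabilities and mask must have identical shapes")
  if (positive == "wound") {
    a <- 1 - probabilities; b <- 1 - mask
  } else {
    a <- probabilities; b <- mask
  }
  1 - (2 * sum(a * b) + smoothEps) / (sum(a) + sum(b) + smoothEps)
}

# Tape node for the training soft dice loss, computed directly on the
# sigmoid cell-probability head against the (1,H,W,N) cell-mask tensor:
# 1 - (2 sum(p g) + eps) / (sum p + sum g + eps).
.tpDiceLoss <- function(tape, pred, target, smoothEps) {
  pv <- tapeValue(tape, pred)
  num <- 2 * sum(pv * target) + smoothEps
  den <- sum(pv) + sum(target) + smoothEps
  .pushNode(tape, 1 - num / den, pred, function(dy) {
    list(dy * (-(2 * target * den - num) / den^2))
  })
}

.roundHalfAway <- function(x) floor(x + 0.5)

#' Partition images into test / train / validation sets
#'
#' `round(testFrac * n)` images (round-half-away-from-zero) are drawn as the
#' test set; the remainder is split train:val at `(1 - valFrac):valFrac`
#' under the same rounding rule. Splitting is done at whole-image level so
#' that downstream quadrant tiling cannot leak patches of one image across
#' sets. Deterministic given `seed`.
#'
#' For n = 400 the rule yields 40 test, 324 train and 36 validation images.
#'
#' @param nImages number of images.
#' @param testFrac,valFrac split fractions in (0, 1).
#' @param seed integer seed.
#' @return a [SplitSpec-class].
#' @export
makeSplits <- function(nImages, testFrac = 0.1, valFrac = 0.1, seed = 1L) {
  if (testFrac <= 0 || testFrac >= 1 || valFrac <= 0 || valFrac >= 1)
    stop("fractions must lie strictly in (0, 1)")
  nTest <- .roundHalfAway(testFrac * nImages)
  nVal <- .roundHalfAway(valFrac * (nImages - nTest))
  nTrain <- nImages - nTest - nVal
  if (nTest < 1L || nVal < 1L || nTrain < 1L)
    stop("too few images for non-empty test/train/val splits")
  withr::with_seed(as.integer(seed), {
    test <- sort(sample.int(nImages, nTest))
    rest <- setdiff(seq_len(nImages), test)
    val <- sort(sample(rest, nVal))
  })
  train <- setdiff(rest, val)
  new("SplitSpec", test = as.integer(test), train = as.integer(train),
      val = as.integer(val), folds = list())
}

#' Manually inject a split
#'
#' Escape hatch to reproduce an externally published partition instead of
#' the rounding rule of [makeSplits()].
#'
#' @param test,train,val disjoint integer index vectors partitioning `1:n`.
#' @param folds optional list of validation-fold index vectors.
#' @return a validated [SplitSpec-class].
#' @export
splitSpec <- function(test, train, val, folds = list()) {
  new("SplitSpec", test = as.integer(test), train = as.integer(train),
      val = as.integer(val), folds = folds)
}

#' k-fold cross-validation folds over the non-test images
#'
#' Produces k disjoint validation-index folds covering `indices`, with
#' sizes differing by at most one, shuffled deterministically by `seed`.
#' Persist them with [saveSplits()] so that every model variant consumes
#' identical folds.
#'
#' @param indices integer vector (typically `c(train, val)` of a split).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return list of k integer vectors.
#' @export
makeCvFolds <- function(indices, k = 5L, seed = 1L) {
  n <- length(indices)
  if (k > n) stop("k exceeds the number of indices")
  withr::with_seed(as.integer(seed), {
    perm <- sample(indices)
  })
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}

#' Serialize split indices to JSON
#'
#' @param x a [SplitSpec-class] or a plain list of integer vectors (folds).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
saveSplits <- function(x, path) {
  obj <- if (is(x, "SplitSpec"))
    list(test = x@test, train = x@train, val = x@val, folds = x@folds)
  else x
  jsonlite::write_json(obj, path)
  invisible(path)
}

#' Read back indices written by [saveSplits()]
#'
#' @param path JSON file.
#' @return a [SplitSpec-class] if the file holds one, otherwise a list of
#'   integer vectors.
#' @export
loadSplits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asFolds <- function(f) {
    if (is.null(f) || length(f) == 0L) list()
    else if (is.matrix(f)) lapply(seq_len(nrow(f)), function(i) as.integer(f[i, ]))
    else lapply(f, as.integer)
  }
  if (is.list(obj) && all(c("test", "train", "val") %in% names(obj)))
    return(splitSpec(obj$test, obj$train, obj$val, folds = asFolds(obj$folds)))
  asFolds(obj)
}

.adamStep <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (n in names(grads)) {
    g <- grads[[n]]
    if (is.null(opt$m[[n]])) {
      opt$m[[n]] <- g * 0
      opt$v[[n]] <- g * 0
    }
    opt$m[[n]] <- b1 * opt$m[[n]] + (1 - b1) * g
    opt$v[[n]] <- b2 * opt$v[[n]] + (1 - b2) * g^2
    mhat <- opt$m[[n]] / (1 - b1^opt$t)
    vhat <- opt$v[[n]] / (1 - b2^opt$t)
    params[[n]] <- params[[n]] - lr * mhat / (sqrt(vhat) + eps)
  }
}

# Accumulated soft dice over a set, eval mode, batched; same class
# convention as the training loss (cell probabilities against cell masks).
.evalDice <- function(model, X, Y, batchSize, smoothEps) {
  n <- dim(X)[4]
  sab <- 0; sa <- 0; sb <- 0
  ops <- evalOps(model@params, model@state)
  for (ix in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    p <- .runGraph(ops, ops$input(X[, , , ix, drop = FALSE]), model@config)
    g <- Y[, , , ix, drop = FALSE]
    sab <- sab + sum(p * g); sa <- sa + sum(p); sb <- sb + sum(g)
  }
  (2 * sab + smoothEps) / (sa + sb + smoothEps)
}

#' Train a segmentation model with dice loss and Adam
#'
#' Runs exactly `config@epochs` epochs (no early stopping) of minibatch
#' Adam on the soft dice loss, with the learning rate decayed per epoch as
#' `lr0 * decayRate^(epoch - 1)`. Per-epoch training dice/loss are means
#' over batches; validation dice is computed in inference mode on soft
#' overlap sums accumulated over the whole validation set. The input model
#' is never mutated: training works on a deep copy.
#'
#' Fully deterministic given the model and `config@seed` (the engine is
#' pure R).
#'
#' @param model a [SegmentationModel-class].
#' @param trainImages,trainMasks lists of preprocessed `(H, W, C)` patches
#'   and matching binary `(H, W)` masks.
#' @param valImages,valMasks optional validation patches.
#' @param config a [TrainingConfig-class].
#' @param verbose print one line per epoch.
#' @return list with elements `model` (the trained copy) and `history`
#'   (data.frame: epoch, lr, train_dice, train_loss, val_dice, val_loss,
#'   elapsed).
#' @export
trainModel <- function(model, trainImages, trainMasks,
                       valImages = NULL, valMasks = NULL,
                       config = trainingConfig(), verbose = FALSE) {
  if (length(trainImages) == 0L) stop("empty training set")
  if (length(trainImages) != length(trainMasks))
    stop("trainImages and trainMasks lengths differ")
  out <- .cloneModel(model)
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_dice = numeric(), train_loss = numeric(),
                     val_dice = numeric(), val_loss = numeric(),
                     elapsed = numeric())
  if (config@epochs == 0L) return(list(model = out, history = hist))

  X <- imagesToTensor(trainImages)
  Y <- imagesToTensor(trainMasks)
  .checkBatchShape(out, X)
  hasVal <- !is.null(valImages) && length(valImages) > 0L
  if (hasVal) {
    VX <- imagesToTensor(valImages)
    VY <- imagesToTensor(valMasks)
  }
  n <- dim(X)[4]
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L; opt$m <- list(); opt$v <- list()

  withr::with_seed(config@seed, {
    for (epoch in seq_len(config@epochs)) {
      t0 <- proc.time()[["elapsed"]]
      lr <- config@learningRate * config@decayRate^(epoch - 1)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (ix in split(ord, ceiling(seq_along(ord) / config@batchSize))) {
        tape <- newTape(out@params)
        ops <- tapeOps(tape, out@state)
        x0 <- ops$input(X[, , , ix, drop = FALSE])
        pred <- .runGraph(ops, x0, out@config)
        lossId <- .tpDiceLoss(tape, pred, Y[, , , ix, drop = FALSE],
                              config@smoothEps)
        grads <- tapeBackward(tape, lossId)
        .adamStep(out@params, grads, opt, lr)
        losses <- c(losses, tapeValue(tape, lossId))
      }
      trLoss <- mean(losses)
      if (hasVal) {
        vd <- .evalDice(out, VX, VY, config@batchSize, config@smoothEps)
      } else vd <- NA_real_
      el <- proc.time()[["elapsed"]] - t0
      hist <- rbind(hist, data.frame(
        epoch = epoch, lr = lr, train_dice = 1 - trLoss, train_loss = trLoss,
        val_dice = vd, val_loss = 1 - vd, elapsed = el))
      if (verbose)
        message(sprintf(
          "epoch %3d | lr %.2e | train dice %.4f | val dice %s | %.1fs",
          epoch, lr, 1 - trLoss,
          ifelse(is.na(vd), "-", sprintf("%.4f", vd)), el))
    }
  })
  list(model = out, history = hist)
}
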