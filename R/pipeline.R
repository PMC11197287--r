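# End-to-end orchestration: each stage is a pure function of its inputs and
# configuration, reruns with identical seeds reproduce outputs, and every
# output directory carries its resolved configuration as JSON.

.writeResolvedConfig <- function(directory, config) {
  config$package_version <- as.character(utils::packageVersion("scratchseg"))
  jsonlite::write_json(config, file.path(directory, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.paramsList <- function(p) {
  sl <- methods::slotNames(class(p))
  stats::setNames(lapply(sl, function(s) methods::slot(p, s)), sl)
}

#' Simulate a labelled scratch-assay dataset on disk
#'
#' Draws per-image closure fractions and wound widths around the base
#' parameters (emulating assays at different stages of healing), generates
#' the scenes, and writes image/mask PNG pairs with a manifest and the
#' resolved configuration. Deterministic given `seed`.
#'
#' @param directory output directory.
#' @param n number of images.
#' @param baseParams a [SceneParams-class] template.
#' @param seed integer seed.
#' @param maxClosure upper bound of the sampled closure fractions; kept
#'   below 1 so every ground truth retains a nonempty wound (the
#'   percentage errors are undefined for fully closed wounds).
#' @return the manifest data.frame.
#' @export
simulateDataset <- function(directory, n, baseParams = sceneParams(),
                            seed = 1L, maxClosure = 0.6) {
  scenes <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      p <- baseParams
      p@closureFrac <- stats::runif(1, 0, maxClosure)
      p@woundWidthFrac <- min(max(
        baseParams@woundWidthFrac * stats::runif(1, 0.8, 1.25), 0.08), 0.45)
      p@seed <- as.integer(sample.int(.Machine$integer.max %/% 2L, 1))
      generateScene(p)
    })
  })
  manifest <- writeDataset(scenes, directory)
  .writeResolvedConfig(directory, list(
    stage = "simulate", n = n, seed = seed, maxClosure = maxClosure,
    baseParams = .paramsList(baseParams)))
  manifest
}

#' Preprocess a dataset directory
#'
#' Applies the full preprocessing pipeline (CLAHE, area downscaling,
#' working precision) to every image and nearest-neighbour downscaling with
#' re-binarization to every mask, writing a new dataset directory.
#'
#' @param inDir dataset directory with a `manifest.csv`.
#' @param outDir output directory.
#' @param config a [PreprocessConfig-class].
#' @return the output manifest.
#' @export
preprocessDataset <- function(inDir, outDir, config = preprocessConfig()) {
  scenes <- readDataset(inDir)
  out <- lapply(scenes, function(sc) {
    img <- preprocessImage(sc@image, config)
    msk <- if (all(dim(sc@mask) == rev(config@targetSize))) sc@mask
           else downscaleMask(sc@mask, config@targetSize)
    labeledImage(img, msk, meta = sc@meta)
  })
  stems <- sub("\\.[^.]+$", "", vapply(scenes, function(sc)
    sc@meta$image_path %||% "", character(1)))
  if (any(stems == "")) stems <- NULL
  manifest <- writeDataset(out, outDir, stems = stems)
  .writeResolvedConfig(outDir, list(
    stage = "preprocess", clipLimit = config@clipLimit,
    tileGrid = config@tileGrid, bins = config@bins,
    targetSize = config@targetSize, colorMode = config@colorMode,
    clipLimitInterpretation = "fraction of tile pixel count"))
  manifest
}

#' Quadrant-augment a dataset directory
#'
#' Splits every image and mask into its four quadrants (file naming
#' `<stem>_q0..3`), records the patch order and parent image in the
#' manifest, and reports (without dropping) single-class mask patches.
#'
#' @param inDir preprocessed dataset directory.
#' @param outDir output directory for patches.
#' @return the patch manifest data.frame with columns image_path,
#'   mask_path, parent, quadrant, singleClass.
#' @export
augmentDataset <- function(inDir, outDir) {
  scenes <- readDataset(inDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    stem <- sub("\\.[^.]+$", "", sc@meta$image_path %||% sprintf("img_%04d", i))
    qi <- splitQuadrants(sc@image)
    qm <- splitQuadrants(sc@mask)
    cov <- checkPatchCoverage(qm, warn = FALSE)
    for (q in 1:4) {
      ip <- file.path(outDir, sprintf("%s_q%d.png", stem, q - 1L))
      mp <- file.path(outDir, sprintf("%s_q%d_mask.png", stem, q - 1L))
      png::writePNG(round(qi@patches[[q]] * 255) / 255, ip)
      png::writePNG(qm@patches[[q]], mp)
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = basename(ip), mask_path = basename(mp),
        parent = i, quadrant = q - 1L,
        singleClass = cov$singleClass[q])
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  if (any(manifest$singleClass))
    warning(sprintf("%d patch(es) contain a single class (kept)",
                    sum(manifest$singleClass)))
  .writeResolvedConfig(outDir, list(stage = "augment",
                                    patch_order = c("TL", "TR", "BL", "BR")))
  manifest
}

.readPatchSet <- function(dir, manifest, parents) {
  sel <- manifest[manifest$parent %in% parents, ]
  imgs <- lapply(file.path(dir, sel$image_path),
                 function(p) .asRGB(.readRaster(p)))
  msks <- lapply(file.path(dir, sel$mask_path), function(p) {
    m <- .readRaster(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    (m > 0.5) * 1
  })
  list(images = imgs, masks = msks)
}

#' Train a variant on an augmented dataset directory
#'
#' Splits at whole-image (parent) level so that the four quadrants of one
#' source image never leak across sets, trains the requested variant, and
#' writes the checkpoint, the split JSON, the per-epoch history CSV and the
#' resolved configuration into `outDir`.
#'
#' @param dataDir augmented patch directory (output of [augmentDataset()]).
#' @param variant `"unet"`, `"unetpp"` or `"attention_unet"`.
#' @param archConfig optional [ArchitectureConfig-class]; by default one is
#'   derived from the patch size with the chosen variant.
#' @param trainConfig a [TrainingConfig-class].
#' @param outDir output directory.
#' @param split optional [SplitSpec-class] over parent images; by default
#'   [makeSplits()] with the training seed.
#' @return list: `model`, `history`, `split`, `checkpoint` (path).
#' @export
trainPipeline <- function(dataDir, variant = "unet", archConfig = NULL,
                          trainConfig = trainingConfig(), outDir = dataDir,
                          split = NULL) {
  manifest <- utils::read.csv(file.path(dataDir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  parents <- sort(unique(manifest$parent))
  if (is.null(split)) split <- makeSplits(length(parents),
                                          seed = trainConfig@seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  saveSplits(split, file.path(outDir, "split.json"))

  tr <- .readPatchSet(dataDir, manifest, parents[split@train])
  va <- .readPatchSet(dataDir, manifest, parents[split@val])
  if (is.null(archConfig)) {
    d <- dim(tr$images[[1]])
    archConfig <- architectureConfig(variant, depth = 3L,
                                     inputSize = c(d[2], d[1], d[3]),
                                     baseFilters = 8L)
  }
  model <- buildModel(archConfig, seed = trainConfig@seed)
  fit <- trainModel(model, tr$images, tr$masks, va$images, va$masks,
                    config = trainConfig)
  utils::write.csv(fit$history, file.path(outDir, "history.csv"),
                   row.names = FALSE)
  ckpt <- file.path(outDir, sprintf("checkpoint_%s.rds", variant))
  saveCheckpoint(fit$model, ckpt)
  .writeResolvedConfig(outDir, list(
    stage = "train", variant = variant,
    arch = .paramsList(archConfig), training = .paramsList(trainConfig)))
  list(model = fit$model, history = fit$history, split = split,
       checkpoint = ckpt)
}

#' Predict merged binary masks for a preprocessed dataset
#'
#' @param model a [SegmentationModel-class] or a checkpoint path.
#' @param inDir preprocessed dataset directory.
#' @param outDir output directory for `<stem>_pred.png` masks.
#' @param threshold binarization threshold.
#' @param indices optional manifest row indices to predict (default all).
#' @return data.frame pairing predicted and ground-truth mask paths.
#' @export
predictDataset <- function(model, inDir, outDir, threshold = 0.5,
                           indices = NULL) {
  if (is.character(model)) model <- loadCheckpoint(model)
  scenes <- readDataset(inDir)
  if (is.null(indices)) indices <- seq_along(scenes)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(indices, function(i) {
    sc <- scenes[[i]]
    stem <- sub("\\.[^.]+$", "", sc@meta$image_path %||% sprintf("img_%04d", i))
    pm <- predictMask(model, sc@image, threshold = threshold)
    pp <- file.path(outDir, paste0(stem, "_pred.png"))
    png::writePNG(pm, pp)
    data.frame(index = i, pred_path = basename(pp),
               gt_path = sc@meta$mask_path %||% NA_character_)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)
  out
}

#' Evaluate predicted masks against ground truth
#'
#' Writes a per-sample metrics CSV (with an appended macro-average row) and
#' a wound-area CSV, and returns both tables.
#'
#' @param model a [SegmentationModel-class], checkpoint path, or `NULL` to
#'   evaluate pre-binarized masks only (no ROC-AUC).
#' @param inDir preprocessed dataset directory (images + ground truth).
#' @param outDir directory for `metrics.csv` and `areas.csv`.
#' @param indices manifest rows to evaluate (default all).
#' @param threshold binarization threshold.
#' @return list: `metrics` (per-sample + aggregate), `areas`, `meanAbsPE`.
#' @export
evaluateDataset <- function(model, inDir, outDir, indices = NULL,
                            threshold = 0.5) {
  if (is.character(model)) model <- loadCheckpoint(model)
  scenes <- readDataset(inDir)
  if (is.null(indices)) indices <- seq_along(scenes)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  mrows <- list(); preds <- list(); gts <- list()
  for (i in indices) {
    sc <- scenes[[i]]
    qs <- splitQuadrants(sc@image)
    probs <- if (is.function(model)) model(qs@patches)
             else predictProb(model, qs@patches)
    prob <- mergeQuadrants(probs)
    pm <- binarize(prob, threshold)
    rep <- segMetrics(pm, sc@mask, probabilities = prob)
    rep <- cbind(data.frame(sample_id = i), rep)
    mrows[[length(mrows) + 1L]] <- rep
    preds[[length(preds) + 1L]] <- pm
    gts[[length(gts) + 1L]] <- sc@mask
  }
  metrics <- do.call(rbind, mrows)
  agg <- cbind(data.frame(sample_id = "mean"),
               aggregateMetrics(metrics[, -1]))
  metrics$sample_id <- as.character(metrics$sample_id)
  metrics <- rbind(metrics, agg[, names(metrics)])
  areas <- batchAreaReport(preds, gts, ids = indices)
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(areas$reports, file.path(outDir, "areas.csv"),
                   row.names = FALSE)
  list(metrics = metrics, areas = areas$reports,
       meanAbsPE = areas$meanAbsPE)
}

# ---------------------------------------------------------------------------
# Checkpoints
# ---------------------------------------------------------------------------

#' Save a model checkpoint
#'
#' Serializes parameters and batch-norm state (RDS) together with a JSON
#' sidecar recording the architecture configuration.
#'
#' @param model a [SegmentationModel-class].
#' @param path checkpoint file path (`.rds`).
#' @return `path`, invisibly.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(config = .paramsList(model@config), seed = model@seed,
              params = as.list(model@params), state = as.list(model@state))
  saveRDS(obj, path)
  jsonlite::write_json(obj$config, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a model checkpoint written by [saveCheckpoint()]
#'
#' @param path checkpoint `.rds` path.
#' @return a [SegmentationModel-class].
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  cfg <- architectureConfig(obj$config$variant, depth = obj$config$depth,
                            inputSize = obj$config$inputSize,
                            baseFilters = obj$config$baseFilters,
                            useBatchnorm = obj$config$useBatchnorm,
                            upsampling = obj$config$upsampling)
  params <- list2env(obj$params, parent = emptyenv())
  state <- list2env(obj$state, parent = emptyenv())
  new("SegmentationModel", config = cfg, params = params, state = state,
      seed = as.integer(obj$seed))
}
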