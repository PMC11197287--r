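# Shared fixtures, all generated in code.

# A small scene-parameter set that keeps tests fast.
tinyParams <- function(...) {
  args <- utils::modifyList(
    list(width = 64L, height = 48L, nMigratingCells = 2L, seed = 11L),
    list(...))
  do.call(sceneParams, args)
}

# Deterministic random binary mask (1 = cell, 0 = wound).
randMask <- function(h, w, pCell = 0.6, seed = 1) {
  withr::with_seed(seed, matrix((runif(h * w) < pCell) * 1, h, w))
}

# Deterministic random probability map.
randProb <- function(h, w, seed = 1) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# Small model shared across tests (built once per test file load).
tinyArch <- function(variant = "unet", ...) {
  architectureConfig(variant, depth = 2L, inputSize = c(16L, 8L, 1L),
                     baseFilters = 2L, ...)
}

# Independent pixel-enumeration oracle for the confusion counts:
# explicit double loop, no vectorized reuse of the implementation.
oracleConfusion <- function(pred, gt) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; g <- gt[i, j]
      if (p == 0 && g == 0) tp <- tp + 1
      else if (p == 1 && g == 1) tn <- tn + 1
      else if (p == 0 && g == 1) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Brute-force AUC by pair enumeration (ties count 1/2).
oracleAuc <- function(score, labelPos) {
  s <- as.vector(score); y <- as.vector(labelPos)
  pos <- which(y); neg <- which(!y)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  tot / (length(pos) * length(neg))
}
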