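# The three segmentation architectures — plain U-net, nested-skip U-net++
# and attention-gated U-net — written once against the engine's op
# interface, so structural variation is confined to skip-path topology while
# the conv-BN-ReLU blocks, pooling and heads are shared code.

.block <- function(ops, x, name, f, useBN) {
  x <- ops$conv3(x, paste0(name, ".c1"), f)
  if (useBN) x <- ops$bn(x, paste0(name, ".bn1"))
  x <- ops$relu(x)
  x <- ops$conv3(x, paste0(name, ".c2"), f)
  if (useBN) x <- ops$bn(x, paste0(name, ".bn2"))
  ops$relu(x)
}

.up <- function(ops, x, name, f, mode) {
  if (mode == "transposed") ops$convT(x, name, f)
  else ops$conv1(ops$upsample(x), name, f)
}

# Additive attention gate: the coarser decoder signal g (already upsampled
# to the skip's resolution) gates the encoder skip features.
.attGate <- function(ops, xskip, g, name, fint) {
  tx <- ops$conv1(xskip, paste0(name, ".theta"), fint)
  tg <- ops$conv1(g, paste0(name, ".phi"), fint)
  a <- ops$relu(ops$add(tx, tg))
  psi <- ops$sigmoid(ops$conv1(a, paste0(name, ".psi"), 1L))
  ops$gate(xskip, psi)
}

# Runs the configured topology on input handle x0; returns the sigmoid
# probability head. Works identically in init, train and eval op modes.
.runGraph <- function(ops, x0, cfg) {
  d <- cfg@depth
  f <- as.integer(cfg@baseFilters * 2^(0:(d - 1L)))
  bn <- cfg@useBatchnorm
  um <- cfg@upsampling

  if (cfg@variant == "unetpp") {
    # grid of nodes X[i][j]; i = level (1 finest), j = dense-skip column
    X <- vector("list", d)
    for (i in seq_len(d)) X[[i]] <- vector("list", d - i + 1L)
    x <- x0
    for (i in seq_len(d)) {
      if (i > 1L) x <- ops$pool(X[[i - 1L]][[1L]])
      X[[i]][[1L]] <- .block(ops, x, sprintf("x%d_0", i), f[i], bn)
    }
    for (j in seq_len(d - 1L)) {
      for (i in seq_len(d - j)) {
        u <- .up(ops, X[[i + 1L]][[j]], sprintf("up%d_%d", i, j), f[i], um)
        X[[i]][[j + 1L]] <- .block(
          ops, ops$concat(c(X[[i]][seq_len(j)], list(u))),
          sprintf("x%d_%d", i, j), f[i], bn)
      }
    }
    return(ops$sigmoid(ops$conv1(X[[1L]][[d]], "out", 1L)))
  }

  # plain / attention U-net: encoder
  skips <- vector("list", d - 1L)
  x <- x0
  for (l in seq_len(d)) {
    x <- .block(ops, x, sprintf("enc%d", l), f[l], bn)
    if (l < d) {
      skips[[l]] <- x
      x <- ops$pool(x)
    }
  }
  # decoder
  for (l in (d - 1L):1L) {
    u <- .up(ops, x, sprintf("up%d", l), f[l], um)
    s <- skips[[l]]
    if (cfg@variant == "attention_unet")
      s <- .attGate(ops, s, u, sprintf("ag%d", l), max(1L, f[l] %/% 2L))
    x <- .block(ops, ops$concat(list(s, u)), sprintf("dec%d", l), f[l], bn)
  }
  ops$sigmoid(ops$conv1(x, "out", 1L))
}

#' Build a segmentation model
#'
#' Initializes all parameters of the configured topology with seeded He
#' initialization, so that two builds from the same configuration and seed
#' are bitwise identical.
#'
#' @param config an [ArchitectureConfig-class].
#' @param seed integer seed for parameter initialization.
#' @return a [SegmentationModel-class].
#' @examples
#' m <- buildModel(architectureConfig("unet", depth = 3L,
#'                                    inputSize = c(64L, 48L, 3L),
#'                                    baseFilters = 8L))
#' parameterCount(m)
#' @export
buildModel <- function(config, seed = 42L) {
  validObject(config)
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  shape <- c(config@inputSize[3], config@inputSize[2], config@inputSize[1])
  withr::with_seed(as.integer(seed), {
    ops <- initOps(params, state)
    .runGraph(ops, ops$input(shape), config)
  })
  new("SegmentationModel", config = config, params = params, state = state,
      seed = as.integer(seed))
}

#' Number of trainable parameters
#'
#' Counts convolution weights and biases plus batch-norm scale and shift;
#' batch-norm running statistics are state, not parameters.
#'
#' @param model a [SegmentationModel-class].
#' @return integer-valued count.
#' @export
parameterCount <- function(model) {
  sum(vapply(ls(model@params), function(n) length(model@params[[n]]),
             numeric(1)))
}

.checkBatchShape <- function(model, x) {
  d <- dim(x)
  want <- c(model@config@inputSize[3], model@config@inputSize[2],
            model@config@inputSize[1])
  if (!identical(as.integer(d[1:3]), as.integer(want)))
    stop(sprintf(
      "input shape (C,H,W) = (%d,%d,%d) does not match model config (%d,%d,%d)",
      d[1], d[2], d[3], want[1], want[2], want[3]))
}

#' Forward pass: per-pixel wound/cell probabilities
#'
#' Runs the model in inference mode (batch norm uses running statistics).
#' The sigmoid head emits, per pixel, the probability of the cell class
#' (mask value 1, the white ROI convention).
#'
#' @param model a [SegmentationModel-class].
#' @param images a single `(height, width, channels)` array or a list of
#'   them; spatial size must match the model's configured input size.
#' @return a list of `(height, width)` probability matrices, one per image,
#'   values strictly inside (0, 1).
#' @export
predictProb <- function(model, images) {
  x <- imagesToTensor(images)
  .checkBatchShape(model, x)
  ops <- evalOps(model@params, model@state)
  out <- .runGraph(ops, ops$input(x), model@config)
  tensorToMaps(out)
}

# Deep copy of a model (parameters and state live in environments).
.cloneModel <- function(model) {
  p2 <- new.env(parent = emptyenv())
  s2 <- new.env(parent = emptyenv())
  for (n in ls(model@params)) p2[[n]] <- model@params[[n]]
  for (n in ls(model@state)) s2[[n]] <- model@state[[n]]
  new("SegmentationModel", config = model@config, params = p2, state = s2,
      seed = model@seed)
}
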