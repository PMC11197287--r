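# A minimal seeded CNN engine in base R.
#
# Tensors are numeric arrays laid out (channels, height, width, batch); all
# channel mixing is done through BLAS matrix products on (C, H*W*N) views,
# so a 3x3 convolution is nine shifted matrix multiplications. Reverse-mode
# differentiation uses a tape: each op appends a node holding its value and
# a backward closure; backward() walks the tape in reverse, accumulating
# gradients into parents and named parameters. This is deliberately small —
# just the ops the three U-net variants need: 3x3 and 1x1 convolution,
# 2x2 stride-2 transposed convolution, bilinear 2x upsampling, batch norm,
# ReLU, sigmoid, 2x2 max pooling, channel concatenation, elementwise add,
# a single-channel attention gate product, and the soft dice loss.

# ---- tensor helpers -------------------------------------------------------

# Convert a list of (H, W, C) images (or (H, W) masks) to a (C, H, W, N)
# tensor.
imagesToTensor <- function(imgs) {
  if (!is.list(imgs)) imgs <- list(imgs)
  d <- dim(imgs[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, c(d[3], d[1], d[2], length(imgs)))
  for (i in seq_along(imgs)) {
    x <- imgs[[i]]
    if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
    out[, , , i] <- aperm(x, c(3, 1, 2))
  }
  out
}

# Inverse of imagesToTensor for single-channel outputs: (1,H,W,N) -> list of
# (H, W) matrices.
tensorToMaps <- function(x) {
  d <- dim(x)
  lapply(seq_len(d[4]), function(i) matrix(x[1, , , i], d[2], d[3]))
}

.czeros <- function(d) if (length(d) == 1L) numeric(d) else array(0, d)

# ---- core forward/backward kernels (shared by tape and eval modes) --------

.convPad <- function(x) {
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  xp
}

.conv3Fwd <- function(x, W, b) {
  d <- dim(x); Co <- dim(W)[1]
  xp <- .convPad(x)
  y <- matrix(0, Co, d[2] * d[3] * d[4])
  for (a in 0:2) for (bb in 0:2) {
    xs <- xp[, (1L + a):(d[2] + a), (1L + bb):(d[3] + bb), , drop = FALSE]
    y <- y + W[, , a + 1L, bb + 1L] %*% matrix(xs, d[1])
  }
  array(y + b, c(Co, d[2], d[3], d[4]))
}

.conv3Bwd <- function(x, W, dy) {
  d <- dim(x); Co <- dim(W)[1]
  xp <- .convPad(x)
  dyM <- matrix(dy, Co)
  dW <- array(0, dim(W))
  dxp <- array(0, dim(xp))
  for (a in 0:2) for (bb in 0:2) {
    ri <- (1L + a):(d[2] + a); ci <- (1L + bb):(d[3] + bb)
    xs <- xp[, ri, ci, , drop = FALSE]
    dW[, , a + 1L, bb + 1L] <- dyM %*% t(matrix(xs, d[1]))
    dxs <- t(W[, , a + 1L, bb + 1L]) %*% dyM
    dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] +
      array(dxs, c(d[1], d[2], d[3], d[4]))
  }
  list(dx = dxp[, 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE],
       dW = dW, db = rowSums(dyM))
}

.conv1Fwd <- function(x, W, b) {
  d <- dim(x)
  array(W %*% matrix(x, d[1]) + b, c(nrow(W), d[2], d[3], d[4]))
}

.conv1Bwd <- function(x, W, dy) {
  d <- dim(x); dyM <- matrix(dy, nrow(W))
  list(dx = array(t(W) %*% dyM, d),
       dW = dyM %*% t(matrix(x, d[1])), db = rowSums(dyM))
}

# Transposed 2x2 stride-2 convolution: W is (2, 2, Cout, Cin); each input
# pixel expands into a 2x2 output block.
.convT2Fwd <- function(x, W, b) {
  d <- dim(x); Co <- dim(W)[3]
  y <- array(0, c(Co, 2L * d[2], 2L * d[3], d[4]))
  xM <- matrix(x, d[1])
  for (a in 0:1) for (bb in 0:1) {
    y[, seq(1L + a, 2L * d[2], 2L), seq(1L + bb, 2L * d[3], 2L), ] <-
      array(W[a + 1L, bb + 1L, , ] %*% xM, c(Co, d[2], d[3], d[4]))
  }
  y + b
}

.convT2Bwd <- function(x, W, dy) {
  d <- dim(x); Co <- dim(W)[3]
  xM <- matrix(x, d[1])
  dW <- array(0, dim(W))
  dx <- matrix(0, d[1], d[2] * d[3] * d[4])
  for (a in 0:1) for (bb in 0:1) {
    dys <- dy[, seq(1L + a, 2L * d[2], 2L), seq(1L + bb, 2L * d[3], 2L), ,
              drop = FALSE]
    dyM <- matrix(dys, Co)
    dW[a + 1L, bb + 1L, , ] <- dyM %*% t(xM)
    dx <- dx + t(W[a + 1L, bb + 1L, , ]) %*% dyM
  }
  list(dx = array(dx, d), dW = dW, db = rowSums(matrix(dy, Co)))
}

# Fixed bilinear 2x upsampling expressed as two interpolation matrices.
.bilinWeights <- function(n) {
  # output length 2n; output centre (k - 0.5)/2 in input coordinates
  U <- matrix(0, 2L * n, n)
  pos <- (seq_len(2L * n) - 0.5) / 2
  i0 <- pmin(pmax(floor(pos - 0.5) + 1L, 1L), n)
  i1 <- pmin(i0 + 1L, n)
  wgt <- pos - (i0 - 0.5)
  wgt <- pmin(pmax(wgt, 0), 1)
  for (k in seq_len(2L * n)) {
    U[k, i0[k]] <- U[k, i0[k]] + (1 - wgt[k])
    U[k, i1[k]] <- U[k, i1[k]] + wgt[k]
  }
  U
}

.upsample2Fwd <- function(x) {
  d <- dim(x)
  Uh <- .bilinWeights(d[2]); Uw <- .bilinWeights(d[3])
  y <- array(0, c(d[1], 2L * d[2], 2L * d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[1]))
    y[c, , , n] <- Uh %*% x[c, , , n] %*% t(Uw)
  y
}

.upsample2Bwd <- function(x, dy) {
  d <- dim(x)
  Uh <- .bilinWeights(d[2]); Uw <- .bilinWeights(d[3])
  dx <- array(0, d)
  for (n in seq_len(d[4])) for (c in seq_len(d[1]))
    dx[c, , , n] <- t(Uh) %*% dy[c, , , n] %*% Uw
  dx
}

.bnStats <- function(x) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  mu <- rowMeans(xm)
  v <- rowMeans((xm - mu)^2)
  list(mu = mu, v = v)
}

.bnApply <- function(x, gamma, beta, mu, v, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1])
  xn <- (xm - mu) / sqrt(v + eps)
  array(gamma * xn + beta, d)
}

.maxpool2Fwd <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[2], 2L); ci <- seq(1L, d[3], 2L)
  s00 <- x[, ri, ci, , drop = FALSE]
  s01 <- x[, ri, ci + 1L, , drop = FALSE]
  s10 <- x[, ri + 1L, ci, , drop = FALSE]
  s11 <- x[, ri + 1L, ci + 1L, , drop = FALSE]
  y <- pmax(s00, s01, s10, s11)
  # winner index 1..4, first maximum wins (deterministic tie-break)
  win <- 1L * (s00 == y)
  win[win == 0 & s01 == y] <- 2L
  win[!(win %in% c(1L, 2L)) & s10 == y] <- 3L
  win[win == 0] <- 4L
  list(y = y, win = win)
}

.maxpool2Bwd <- function(x, win, dy) {
  d <- dim(x)
  dx <- array(0, d)
  ri <- seq(1L, d[2], 2L); ci <- seq(1L, d[3], 2L)
  dx[, ri, ci, ] <- dy * (win == 1L)
  dx[, ri, ci + 1L, ] <- dx[, ri, ci + 1L, , drop = FALSE] + dy * (win == 2L)
  dx[, ri + 1L, ci, ] <- dx[, ri + 1L, ci, , drop = FALSE] + dy * (win == 3L)
  dx[, ri + 1L, ci + 1L, ] <- dx[, ri + 1L, ci + 1L, , drop = FALSE] +
    dy * (win == 4L)
  dx
}

# ---- tape -----------------------------------------------------------------

newTape <- function(params) {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$params <- params        # environment name -> array
  e$pgrads <- new.env(parent = emptyenv())
  e
}

.pushNode <- function(tape, value, parents, backward) {
  force(value); force(parents)   # force before the tape length is read
  id <- length(tape$nodes) + 1L
  tape$nodes[[id]] <- list(value = value, parents = parents,
                           backward = backward)
  id
}

tapeValue <- function(tape, id) {
  force(id)   # id may be a promise that itself pushes nodes onto the tape
  tape$nodes[[id]]$value
}

.addPGrad <- function(tape, name, g) {
  cur <- tape$pgrads[[name]]
  tape$pgrads[[name]] <- if (is.null(cur)) g else cur + g
}

# Run reverse-mode accumulation from the (scalar) loss node.
tapeBackward <- function(tape, lossId) {
  n <- length(tape$nodes)
  grads <- vector("list", n)
  grads[[lossId]] <- 1
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      if (is.null(grads[[p]])) grads[[p]] <- pg[[k]]
      else grads[[p]] <- grads[[p]] + pg[[k]]
    }
  }
  as.list(tape$pgrads)
}

# ---- op sets --------------------------------------------------------------
#
# The three U-net topologies are written once against this op interface.
# Three implementations exist:
#   initOps — shape inference; creates parameters with seeded He init,
#             counts them, and tracks (C, H, W) shapes symbolically;
#   tapeOps — training mode; builds tape nodes and batch-stat batch norm;
#   evalOps — inference mode; plain arrays and running-stat batch norm.

.heInit <- function(shape, fanIn) {
  v <- stats::rnorm(prod(shape), 0, sqrt(2 / fanIn))
  if (length(shape) == 1L) v else array(v, shape)
}

initOps <- function(params, state) {
  ensure <- function(name, shape, fanIn, zero = FALSE) {
    if (!exists(name, envir = params, inherits = FALSE))
      params[[name]] <- if (zero) .czeros(shape) else .heInit(shape, fanIn)
  }
  list(
    mode = "init",
    input = function(shapeCHW) shapeCHW,
    conv3 = function(x, name, cout) {
      ensure(paste0(name, ".W"), c(cout, x[1], 3L, 3L), x[1] * 9)
      ensure(paste0(name, ".b"), cout, 1, zero = TRUE)
      c(cout, x[2], x[3])
    },
    conv1 = function(x, name, cout) {
      ensure(paste0(name, ".W"), c(cout, x[1]), x[1])
      ensure(paste0(name, ".b"), cout, 1, zero = TRUE)
      c(cout, x[2], x[3])
    },
    convT = function(x, name, cout) {
      ensure(paste0(name, ".W"), c(2L, 2L, cout, x[1]), x[1] * 4)
      ensure(paste0(name, ".b"), cout, 1, zero = TRUE)
      c(cout, 2L * x[2], 2L * x[3])
    },
    bn = function(x, name) {
      if (!exists(paste0(name, ".gamma"), envir = params, inherits = FALSE)) {
        params[[paste0(name, ".gamma")]] <- rep(1, x[1])
        params[[paste0(name, ".beta")]] <- rep(0, x[1])
        state[[paste0(name, ".mean")]] <- rep(0, x[1])
        state[[paste0(name, ".var")]] <- rep(1, x[1])
      }
      x
    },
    relu = function(x) x,
    sigmoid = function(x) x,
    pool = function(x) c(x[1], x[2] %/% 2L, x[3] %/% 2L),
    upsample = function(x) c(x[1], 2L * x[2], 2L * x[3]),
    concat = function(xs) c(sum(vapply(xs, `[`, numeric(1), 1L)),
                            xs[[1]][2], xs[[1]][3]),
    add = function(a, b) a,
    gate = function(x, g) x
  )
}

tapeOps <- function(tape, state, bnMomentum = 0.9) {
  P <- function(name) tape$params[[name]]
  list(
    mode = "train",
    input = function(x) .pushNode(tape, x, integer(0), NULL),
    conv3 = function(x, name, cout) {
      xv <- tapeValue(tape, x)
      W <- P(paste0(name, ".W")); b <- P(paste0(name, ".b"))
      .pushNode(tape, .conv3Fwd(xv, W, b), x, function(dy) {
        bw <- .conv3Bwd(xv, W, dy)
        .addPGrad(tape, paste0(name, ".W"), bw$dW)
        .addPGrad(tape, paste0(name, ".b"), bw$db)
        list(bw$dx)
      })
    },
    conv1 = function(x, name, cout) {
      xv <- tapeValue(tape, x)
      W <- P(paste0(name, ".W")); b <- P(paste0(name, ".b"))
      .pushNode(tape, .conv1Fwd(xv, W, b), x, function(dy) {
        bw <- .conv1Bwd(xv, W, dy)
        .addPGrad(tape, paste0(name, ".W"), bw$dW)
        .addPGrad(tape, paste0(name, ".b"), bw$db)
        list(bw$dx)
      })
    },
    convT = function(x, name, cout) {
      xv <- tapeValue(tape, x)
      W <- P(paste0(name, ".W")); b <- P(paste0(name, ".b"))
      .pushNode(tape, .convT2Fwd(xv, W, b), x, function(dy) {
        bw <- .convT2Bwd(xv, W, dy)
        .addPGrad(tape, paste0(name, ".W"), bw$dW)
        .addPGrad(tape, paste0(name, ".b"), bw$db)
        list(bw$dx)
      })
    },
    bn = function(x, name) {
      xv <- tapeValue(tape, x)
      gamma <- P(paste0(name, ".gamma")); beta <- P(paste0(name, ".beta"))
      st <- .bnStats(xv)
      eps <- 1e-5
      d <- dim(xv); m <- prod(d[-1])
      xn <- (matrix(xv, d[1]) - st$mu) / sqrt(st$v + eps)
      # update running statistics (side effect of a training forward pass)
      mk <- paste0(name, ".mean"); vk <- paste0(name, ".var")
      state[[mk]] <- bnMomentum * state[[mk]] + (1 - bnMomentum) * st$mu
      state[[vk]] <- bnMomentum * state[[vk]] + (1 - bnMomentum) * st$v
      .pushNode(tape, array(gamma * xn + beta, d), x, function(dy) {
        dyM <- matrix(dy, d[1])
        .addPGrad(tape, paste0(name, ".gamma"), rowSums(dyM * xn))
        .addPGrad(tape, paste0(name, ".beta"), rowSums(dyM))
        dxn <- gamma * dyM
        iv <- 1 / sqrt(st$v + eps)
        dx <- iv * (dxn - rowMeans(dxn) - xn * rowMeans(dxn * xn))
        list(array(dx, d))
      })
    },
    relu = function(x) {
      xv <- tapeValue(tape, x)
      pos <- xv > 0
      .pushNode(tape, xv * pos, x, function(dy) list(dy * pos))
    },
    sigmoid = function(x) {
      xv <- tapeValue(tape, x)
      s <- 1 / (1 + exp(-xv))
      .pushNode(tape, s, x, function(dy) list(dy * s * (1 - s)))
    },
    pool = function(x) {
      xv <- tapeValue(tape, x)
      mp <- .maxpool2Fwd(xv)
      .pushNode(tape, mp$y, x, function(dy) list(.maxpool2Bwd(xv, mp$win, dy)))
    },
    upsample = function(x) {
      xv <- tapeValue(tape, x)
      .pushNode(tape, .upsample2Fwd(xv), x,
                function(dy) list(.upsample2Bwd(xv, dy)))
    },
    concat = function(xs) {
      vals <- lapply(xs, tapeValue, tape = tape)
      cs <- vapply(vals, function(v) dim(v)[1], integer(1))
      d1 <- dim(vals[[1]])
      out <- array(0, c(sum(cs), d1[2], d1[3], d1[4]))
      off <- 0L
      for (v in vals) {
        out[off + seq_len(dim(v)[1]), , , ] <- v
        off <- off + dim(v)[1]
      }
      .pushNode(tape, out, unlist(xs), function(dy) {
        off <- 0L
        lapply(cs, function(ck) {
          g <- dy[off + seq_len(ck), , , , drop = FALSE]
          off <<- off + ck
          g
        })
      })
    },
    add = function(a, b) {
      av <- tapeValue(tape, a); bv <- tapeValue(tape, b)
      .pushNode(tape, av + bv, c(a, b), function(dy) list(dy, dy))
    },
    gate = function(x, g) {
      # x: (C,H,W,N); g: (1,H,W,N) attention coefficients broadcast over C
      xv <- tapeValue(tape, x); gv <- tapeValue(tape, g)
      C <- dim(xv)[1]
      gb <- xv * rep(gv, each = C)
      .pushNode(tape, gb, c(x, g), function(dy) {
        dg <- apply(dy * xv, c(2, 3, 4), sum)
        list(dy * rep(gv, each = C), array(dg, dim(gv)))
      })
    }
  )
}

evalOps <- function(params, state) {
  P <- function(name) params[[name]]
  list(
    mode = "eval",
    input = function(x) x,
    conv3 = function(x, name, cout)
      .conv3Fwd(x, P(paste0(name, ".W")), P(paste0(name, ".b"))),
    conv1 = function(x, name, cout)
      .conv1Fwd(x, P(paste0(name, ".W")), P(paste0(name, ".b"))),
    convT = function(x, name, cout)
      .convT2Fwd(x, P(paste0(name, ".W")), P(paste0(name, ".b"))),
    bn = function(x, name)
      .bnApply(x, P(paste0(name, ".gamma")), P(paste0(name, ".beta")),
               state[[paste0(name, ".mean")]], state[[paste0(name, ".var")]]),
    relu = function(x) x * (x > 0),
    sigmoid = function(x) 1 / (1 + exp(-x)),
    pool = function(x) .maxpool2Fwd(x)$y,
    upsample = function(x) .upsample2Fwd(x),
    concat = function(xs) {
      cs <- vapply(xs, function(v) dim(v)[1], integer(1))
      d1 <- dim(xs[[1]])
      out <- array(0, c(sum(cs), d1[2], d1[3], d1[4]))
      off <- 0L
      for (v in xs) {
        out[off + seq_len(dim(v)[1]), , , ] <- v
        off <- off + dim(v)[1]
      }
      out
    },
    add = function(a, b) a + b,
    gate = function(x, g) x * rep(g, each = dim(x)[1])
  )
}
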