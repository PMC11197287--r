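# Architecture construction: shape contracts, parameter counts, seeded
# reproducibility, and gradient correctness of the engine.

test_that("all three variants keep the spatial shape and emit probabilities", {
  for (variant in c("unet", "unetpp", "attention_unet")) {
    cfg <- architectureConfig(variant, depth = 3L,
                              inputSize = c(32L, 16L, 1L), baseFilters = 2L)
    m <- buildModel(cfg, seed = 1L)
    imgs <- lapply(1:2, function(i)
      withr::with_seed(i, array(runif(16 * 32), c(16, 32, 1))))
    out <- predictProb(m, imgs)
    expect_length(out, 2L)
    for (o in out) {
      expect_equal(dim(o), c(16L, 32L))
      expect_true(all(o > 0 & o < 1))    # strict sigmoid range
    }
  }
})

test_that("input sizes not divisible by 2^(depth-1) are rejected", {
  expect_error(architectureConfig("unet", depth = 4L,
                                  inputSize = c(20L, 16L, 1L)),
               "divisible")
  m <- buildModel(tinyArch())
  bad <- array(0.5, c(10, 16, 1))
  expect_error(predictProb(m, bad), "does not match")
})

test_that("parameter counts are deterministic and monotone in width", {
  cfg <- tinyArch()
  expect_equal(parameterCount(buildModel(cfg, seed = 1L)),
               parameterCount(buildModel(cfg, seed = 99L)))
  wide <- architectureConfig("unet", depth = 2L, inputSize = c(16L, 8L, 1L),
                             baseFilters = 4L)
  expect_gt(parameterCount(buildModel(wide)),
            parameterCount(buildModel(cfg)))
})

test_that("a single 3x3 conv layer 1->4 with bias holds 40 parameters", {
  # counted by hand: 3*3*1*4 weights + 4 biases
  params <- new.env(parent = emptyenv())
  state <- new.env(parent = emptyenv())
  ops <- scratchseg:::initOps(params, state)
  ops$conv3(c(1L, 8L, 8L), "solo", 4L)
  expect_equal(sum(vapply(ls(params), function(n) length(params[[n]]),
                          numeric(1))), 40)
})

test_that("attention gates add parameters over the plain U-net", {
  mk <- function(v) architectureConfig(v, depth = 3L,
                                       inputSize = c(32L, 16L, 3L),
                                       baseFilters = 4L)
  expect_gt(parameterCount(buildModel(mk("attention_unet"))),
            parameterCount(buildModel(mk("unet"))))
})

test_that("seeded initialization and forward passes are reproducible", {
  cfg <- tinyArch()
  m1 <- buildModel(cfg, seed = 5L)
  m2 <- buildModel(cfg, seed = 5L)
  for (n in ls(m1@params)) expect_identical(m1@params[[n]], m2@params[[n]])
  x <- withr::with_seed(2, array(runif(8 * 16), c(8, 16, 1)))
  expect_identical(predictProb(m1, x), predictProb(m2, x))
  m3 <- buildModel(cfg, seed = 6L)
  expect_false(identical(predictProb(m1, x), predictProb(m3, x)))
})

test_that("structural variation is confined to the skip paths", {
  # encoder parameters exist under the same names for plain and attention
  mk <- function(v) buildModel(architectureConfig(
    v, depth = 3L, inputSize = c(16L, 16L, 1L), baseFilters = 2L), seed = 1L)
  mu <- mk("unet"); ma <- mk("attention_unet")
  encNames <- grep("^enc", ls(mu@params), value = TRUE)
  expect_true(all(encNames %in% ls(ma@params)))
  for (n in encNames) expect_identical(dim(mu@params[[n]]),
                                       dim(ma@params[[n]]))
  # the attention model's extra parameters are exactly the gate projections
  extra <- setdiff(ls(ma@params), ls(mu@params))
  expect_true(all(grepl("^ag", extra)))
})

test_that("engine gradients match finite differences for every variant", {
  ns <- asNamespace("scratchseg")
  for (variant in c("unet", "unetpp", "attention_unet")) {
    cfg <- architectureConfig(variant, depth = 2L, inputSize = c(8L, 8L, 2L),
                              baseFilters = 2L)
    m <- buildModel(cfg, seed = 1L)
    x <- withr::with_seed(9, array(runif(2 * 8 * 8 * 2), c(2, 8, 8, 2)))
    g <- withr::with_seed(10, array((runif(8 * 8 * 2) > 0.5) * 1,
                                    c(1, 8, 8, 2)))
    lossOf <- function() {
      tape <- ns$newTape(m@params)
      ops <- ns$tapeOps(tape, m@state)
      pred <- ns$.runGraph(ops, ops$input(x), cfg)
      lid <- ns$.tpDiceLoss(tape, pred, g, 1e-6)
      list(tape = tape, lid = lid, val = ns$tapeValue(tape, lid))
    }
    r <- lossOf()
    grads <- ns$tapeBackward(r$tape, r$lid)
    nm <- withr::with_seed(3, sample(names(grads), 5))
    for (n in nm) {
      arr <- m@params[[n]]
      i <- withr::with_seed(4, sample(length(arr), 1))
      eps <- 1e-5
      m@params[[n]][i] <- arr[i] + eps; lp <- lossOf()$val
      m@params[[n]][i] <- arr[i] - eps; lm <- lossOf()$val
      m@params[[n]][i] <- arr[i]
      num <- (lp - lm) / (2 * eps)
      expect_equal(grads[[n]][i], num, tolerance = 1e-4,
                   label = paste(variant, n))
    }
  }
})

test_that("bilinear upsampling variant also preserves shape", {
  cfg <- architectureConfig("unet", depth = 2L, inputSize = c(16L, 8L, 1L),
                            baseFilters = 2L, upsampling = "bilinear")
  m <- buildModel(cfg)
  out <- predictProb(m, array(0.5, c(8, 16, 1)))
  expect_equal(dim(out[[1]]), c(8L, 16L))
})
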