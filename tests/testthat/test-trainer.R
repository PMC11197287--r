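# Dice loss, data splitting protocol, CV fold management, training loop.

test_that("dice loss reproduces the closed-form hand cases", {
  g <- matrix(c(rep(1, 8), rep(0, 8)), 4, 4)
  expect_equal(diceLoss(g, g), 0, tolerance = 1e-6)
  expect_equal(diceLoss(1 - g, g), 1, tolerance = 1e-6)
  # uniform p = 0.5 against a half-ones mask: soft dice = 0.5 either class
  p <- matrix(0.5, 4, 4)
  expect_equal(diceLoss(p, g), 0.5, tolerance = 1e-6)
  expect_equal(diceLoss(p, g, positive = "cell"), 0.5, tolerance = 1e-6)
  expect_error(diceLoss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shapes")
})

test_that("dice loss is bounded in [0, 1] on random inputs", {
  for (seed in 1:20) {
    p <- randProb(6, 6, seed = seed)
    g <- randMask(6, 6, pCell = runif(1), seed = seed + 40)
    l <- diceLoss(p, g)
    expect_gte(l, 0); expect_lte(l, 1)
  }
})

test_that("splits follow the documented rounding rule", {
  sp <- makeSplits(400, seed = 3L)
  expect_length(sp@test, 40L)
  expect_length(sp@train, 324L)
  expect_length(sp@val, 36L)
  sp10 <- makeSplits(10, seed = 1L)
  expect_equal(lengths(list(sp10@test, sp10@train, sp10@val)), c(1L, 8L, 1L))
  expect_error(makeSplits(3), "too few")
  expect_error(makeSplits(100, testFrac = 0), "fractions")
})

test_that("splits are deterministic, disjoint and exhaustive", {
  a <- makeSplits(50, seed = 9L); b <- makeSplits(50, seed = 9L)
  expect_identical(a@test, b@test)
  expect_identical(a@val, b@val)
  all_idx <- c(a@test, a@train, a@val)
  expect_equal(sort(all_idx), 1:50)
  expect_false(identical(makeSplits(50, seed = 10L)@test, a@test))
})

test_that("manual split injection validates the partition", {
  sp <- splitSpec(test = 1:2, train = 3:8, val = 9:10)
  expect_s4_class(sp, "SplitSpec")
  expect_error(splitSpec(test = 1:2, train = 2:8, val = 9:10), "disjoint")
})

test_that("cv folds partition the indices with near-equal sizes", {
  idx <- 1:360
  folds <- makeCvFolds(idx, k = 5L, seed = 2L)
  expect_equal(lengths(folds), rep(72L, 5))
  expect_equal(sort(unlist(folds)), idx)
  # uneven case
  f2 <- makeCvFolds(1:13, k = 5L, seed = 1L)
  expect_equal(sort(lengths(f2), decreasing = TRUE), c(3L, 3L, 3L, 2L, 2L))
  expect_equal(sort(unlist(f2)), 1:13)
  expect_error(makeCvFolds(1:3, k = 5L), "exceeds")
})

test_that("splits and folds survive a JSON roundtrip", {
  dir <- withr::local_tempdir()
  sp <- makeSplits(40, seed = 4L)
  sp@folds <- makeCvFolds(c(sp@train, sp@val), k = 5L, seed = 4L)
  validObject(sp)
  saveSplits(sp, file.path(dir, "split.json"))
  back <- loadSplits(file.path(dir, "split.json"))
  expect_identical(back@test, sp@test)
  expect_identical(back@train, sp@train)
  expect_identical(back@val, sp@val)
  expect_identical(back@folds, sp@folds)
})

test_that("zero epochs returns an empty history and an unchanged model", {
  m <- buildModel(tinyArch(), seed = 1L)
  imgs <- lapply(1:2, function(i)
    withr::with_seed(i, array(runif(8 * 16), c(8, 16, 1))))
  msks <- lapply(1:2, function(i) randMask(8, 16, seed = i))
  fit <- trainModel(m, imgs, msks, config = trainingConfig(epochs = 0L))
  expect_equal(nrow(fit$history), 0L)
  for (n in ls(m@params))
    expect_identical(fit$model@params[[n]], m@params[[n]])
  expect_error(trainModel(m, list(), list()), "empty")
})

test_that("training is reproducible and never mutates the input model", {
  m <- buildModel(tinyArch(), seed = 1L)
  before <- as.list(m@params)
  imgs <- lapply(1:4, function(i)
    withr::with_seed(i, array(runif(8 * 16), c(8, 16, 1))))
  msks <- lapply(1:4, function(i) randMask(8, 16, seed = i))
  cfg <- trainingConfig(epochs = 2L, batchSize = 2L, seed = 7L)
  f1 <- trainModel(m, imgs, msks, config = cfg)
  f2 <- trainModel(m, imgs, msks, config = cfg)
  keep <- setdiff(names(f1$history), "elapsed")   # wall time may differ
  expect_equal(f1$history[keep], f2$history[keep])
  for (n in ls(f1$model@params))
    expect_identical(f1$model@params[[n]], f2$model@params[[n]])
  expect_identical(as.list(m@params), before)   # input untouched
})

test_that("the history records the decayed learning-rate schedule", {
  m <- buildModel(tinyArch(), seed = 1L)
  imgs <- lapply(1:2, function(i)
    withr::with_seed(i, array(runif(8 * 16), c(8, 16, 1))))
  msks <- lapply(1:2, function(i) randMask(8, 16, seed = i))
  fit <- trainModel(m, imgs, msks,
                    config = trainingConfig(epochs = 3L, batchSize = 2L))
  expect_equal(fit$history$lr, 1e-3 * 0.9^(0:2))
  expect_equal(nrow(fit$history), 3L)
  expect_equal(fit$history$train_dice, 1 - fit$history$train_loss)
  expect_true(all(fit$history$train_loss >= 0 &
                  fit$history$train_loss <= 1))
})

test_that("a small model learns an easy synthetic task", {
  # 20 patches from scenes with a strong texture cue; a few epochs must
  # reduce the dice loss measurably
  scenes <- lapply(1:5, function(i)
    generateScene(tinyParams(seed = as.integer(100 + i))))
  imgs <- list(); msks <- list()
  for (sc in scenes) {
    imgs <- c(imgs, patches(splitQuadrants(sceneImage(sc))))
    msks <- c(msks, patches(splitQuadrants(sceneMask(sc))))
  }
  arch <- architectureConfig("unet", depth = 2L, inputSize = c(32L, 24L, 3L),
                             baseFilters = 4L)
  m <- buildModel(arch, seed = 1L)
  fit <- trainModel(m, imgs, msks, imgs[1:4], msks[1:4],
                    config = trainingConfig(epochs = 5L, seed = 1L))
  h <- fit$history
  expect_gt(h$train_dice[5], h$train_dice[1])
  expect_true(all(h$val_dice >= 0 & h$val_dice <= 1))
})
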