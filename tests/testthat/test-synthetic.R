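# Synthetic scratch-assay generator: geometry, determinism, texture
# contrast, time series, dataset I/O.

test_that("a straight fresh band has the exact analytic wound area", {
  p <- sceneParams(width = 100L, height = 60L, edgeRoughnessAmp = 0,
                   nMigratingCells = 0L, woundWidthFrac = 0.25, seed = 5L)
  m <- sceneMask(generateScene(p))
  zeroCols <- sum(colSums(m == 0) == nrow(m))
  expect_equal(zeroCols, 25L)                   # exactly 25 zero-columns
  expect_equal(woundArea(m), 25L * 60L)
  # column-level: the zero region is one contiguous band
  wcols <- which(colSums(m == 0) > 0)
  expect_equal(wcols, seq(min(wcols), max(wcols)))
})

test_that("a fully closed wound yields an all-cell mask", {
  p <- tinyParams(closureFrac = 1)
  m <- sceneMask(generateScene(p))
  expect_true(all(m == 1))
  expect_equal(woundArea(m), 0L)
})

test_that("generation is deterministic given (params, seed)", {
  p <- tinyParams(seed = 7L)
  a <- generateScene(p); b <- generateScene(p)
  expect_identical(sceneImage(a), sceneImage(b))
  expect_identical(sceneMask(a), sceneMask(b))
  # a different seed changes the scene
  p2 <- tinyParams(seed = 8L)
  expect_false(identical(sceneImage(a), sceneImage(generateScene(p2))))
})

test_that("generateScene does not disturb the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generateScene(tinyParams())); after <- runif(3)
  expect_identical(before, after)
})

test_that("wound area strictly decreases with closure fraction", {
  for (amp in c(0, 2)) {
    p <- tinyParams(edgeRoughnessAmp = amp)
    areas <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(cf) {
      p@closureFrac <- cf
      woundArea(sceneMask(generateScene(p)))
    }, numeric(1))
    expect_true(all(diff(areas) < 0))
    expect_equal(areas[5], 0)
  }
})

test_that("edge roughness stays within its amplitude bound", {
  amp <- 4
  p <- sceneParams(width = 120L, height = 80L, edgeRoughnessAmp = amp,
                   nMigratingCells = 0L, woundWidthFrac = 0.3, seed = 3L)
  m <- sceneMask(generateScene(p))
  # straight-band bounds at closure 0: centre +/- w0/2
  w0 <- 0.3 * 120
  lo <- 60 - w0 / 2; hi <- 60 + w0 / 2
  leftEdge <- apply(m == 0, 1, function(r) min(which(r)))
  rightEdge <- apply(m == 0, 1, function(r) max(which(r)))
  expect_true(all(abs((leftEdge - 0.5) - lo) <= amp + 1))
  expect_true(all(abs(rightEdge - hi) <= amp + 1))
  # and the edges genuinely deviate from a straight line
  expect_gt(diff(range(leftEdge)), 0)
})

test_that("migrating spindle cells appear inside the band as cell label", {
  p0 <- tinyParams(nMigratingCells = 0L, edgeRoughnessAmp = 0)
  pn <- tinyParams(nMigratingCells = 8L, edgeRoughnessAmp = 0)
  a0 <- woundArea(sceneMask(generateScene(p0)))
  an <- woundArea(sceneMask(generateScene(pn)))
  expect_lt(an, a0)    # sprites convert wound pixels to cell pixels
})

test_that("cell regions carry more local texture than the wound", {
  sc <- generateScene(sceneParams(width = 128L, height = 96L, seed = 3L))
  img <- sceneImage(sc)[, , 1]
  k <- matrix(1 / 121, 11, 11)
  mu <- EBImage::filter2(img, k)
  s <- sqrt(pmax(EBImage::filter2(img^2, k) - mu^2, 0))
  m <- sceneMask(sc)
  expect_gt(mean(s[m == 1]), mean(s[m == 0]))
})

test_that("horizontal wound axis transposes the geometry", {
  p <- sceneParams(width = 100L, height = 60L, woundAxis = "horizontal",
                   edgeRoughnessAmp = 0, nMigratingCells = 0L,
                   woundWidthFrac = 0.25, seed = 5L)
  m <- sceneMask(generateScene(p))
  expect_equal(dim(m), c(60L, 100L))
  zeroRows <- sum(rowSums(m == 0) == ncol(m))
  expect_equal(zeroRows, 15L)                # 0.25 * 60
})

test_that("invalid scene parameters are rejected", {
  expect_error(sceneParams(woundWidthFrac = 0), "woundWidthFrac")
  expect_error(sceneParams(woundWidthFrac = 1.2), "woundWidthFrac")
  expect_error(sceneParams(closureFrac = 1.5), "closureFrac")
  expect_error(sceneParams(width = 0L), "width")
  expect_error(sceneParams(noiseSd = -1), "noiseSd")
})

test_that("time series closure is monotone and matches per-frame regeneration", {
  p <- tinyParams()
  ts <- generateTimeseries(p, c(0, 0.5, 1))
  areas <- vapply(ts, function(s) woundArea(sceneMask(s)), numeric(1))
  expect_true(areas[1] > areas[2] && areas[2] > areas[3])
  expect_equal(areas[3], 0)

  ts2 <- generateTimeseries(p, c(0.3, 0.3))
  expect_equal(woundArea(sceneMask(ts2[[1]])), woundArea(sceneMask(ts2[[2]])))

  # frame-by-frame regeneration oracle
  fr <- c(0, 0.25, 0.5, 0.75)
  ts3 <- generateTimeseries(p, fr)
  for (i in seq_along(fr)) {
    p@closureFrac <- fr[i]
    expect_identical(sceneMask(ts3[[i]]), sceneMask(generateScene(p)))
  }

  expect_error(generateTimeseries(p, c(0.5, 0.2)), "nondecreasing")
  expect_error(generateTimeseries(p, c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("dataset write/read roundtrips masks exactly", {
  dir <- withr::local_tempdir()
  scenes <- lapply(1:4, function(i) generateScene(tinyParams(seed = i)))
  mf <- writeDataset(scenes, dir)
  expect_equal(nrow(mf), 4L)
  expect_length(list.files(dir, pattern = "\\.png$"), 8L)

  back <- readDataset(dir)
  for (i in 1:4) {
    expect_identical(sceneMask(back[[i]]), sceneMask(scenes[[i]]))
    # images were quantized to 8 bits on write; roundtrip is then exact
    expect_equal(sceneImage(back[[i]]),
                 round(sceneImage(scenes[[i]]) * 255) / 255,
                 tolerance = 1e-12)
  }
  expect_error(writeDataset(scenes, dir, format = "jpeg"), "lossy")
})

test_that("rewriting the same scenes yields identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  scenes <- lapply(1:2, function(i) generateScene(tinyParams(seed = i)))
  writeDataset(scenes, d1)
  writeDataset(scenes, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})
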