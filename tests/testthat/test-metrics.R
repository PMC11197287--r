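# Evaluation metrics under the wound-as-positive convention, checked
# against independent pixel-enumeration oracles.

test_that("confusion counts match the enumeration oracle on hand cases", {
  pred <- matrix(c(0, 1, 1, 1), 2, 2, byrow = TRUE)
  gt <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
  cc <- confusionCounts(pred, gt)
  expect_equal(cc, list(tp = 1L, tn = 2L, fp = 0L, fn = 1L),
               ignore_attr = TRUE)

  m <- randMask(6, 6, seed = 1)
  expect_equal(confusionCounts(m, m)$fp, 0)
  expect_equal(confusionCounts(m, m)$fn, 0)
  inv <- 1 - m
  expect_equal(confusionCounts(inv, m)$tp, 0)
  expect_equal(confusionCounts(inv, m)$tn, 0)

  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(confusionCounts(matrix(0.3, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("metric formulas reproduce the derived half-wound case", {
  # pred all wound, gt half wound: tp = N/2, fp = N/2, fn = 0, tn = 0
  n <- 16
  pred <- matrix(0, 4, 4)
  gt <- matrix(rep(c(0, 1), 8), 4, 4)
  r <- metricsFromCounts(confusionCounts(pred, gt))
  expect_equal(r$dsc, 2 / 3)
  expect_equal(r$iou, 1 / 2)
  expect_equal(r$pre, 1 / 2)
  expect_equal(r$rec, 1)
  expect_equal(r$spe, 0)
  expect_equal(r$acc, 1 / 2)
})

test_that("perfect prediction scores 1 on every metric", {
  m <- randMask(5, 7, seed = 3)
  r <- metricsFromCounts(confusionCounts(m, m))
  expect_true(all(r == 1))
})

test_that("metrics match a brute-force oracle on many random pairs", {
  set.seed(42)
  for (rep in 1:1000) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    pred <- matrix((runif(h * w) < runif(1, 0.2, 0.8)) * 1, h, w)
    gt <- matrix((runif(h * w) < runif(1, 0.2, 0.8)) * 1, h, w)
    oc <- oracleConfusion(pred, gt)
    cc <- confusionCounts(pred, gt)
    expect_equal(unlist(cc), unlist(oc), ignore_attr = TRUE)
    ok <- oc$tp + oc$fp > 0 && oc$tp + oc$fn > 0 && oc$tn + oc$fp > 0
    if (!ok) next
    r <- metricsFromCounts(cc)
    expect_equal(r$dsc, 2 * oc$tp / (oc$fp + 2 * oc$tp + oc$fn))
    expect_equal(r$acc, (oc$tp + oc$tn) / (h * w))
    expect_equal(r$iou, oc$tp / (oc$tp + oc$fp + oc$fn))
    expect_equal(r$pre, oc$tp / (oc$tp + oc$fp))
    expect_equal(r$rec, oc$tp / (oc$tp + oc$fn))
    expect_equal(r$spe, oc$tn / (oc$tn + oc$fp))
    # algebraic identity linking overlap metrics
    expect_equal(r$dsc, 2 * r$iou / (1 + r$iou))
    expect_lte(r$iou, r$dsc + 1e-12)
  }
})

test_that("zero-denominator conventions: forced agreement is 1, else error", {
  allCell <- matrix(1, 3, 3)
  r <- metricsFromCounts(confusionCounts(allCell, allCell))
  expect_true(all(r == 1))      # no wound anywhere: agreement forced
  someWound <- matrix(1, 3, 3); someWound[1] <- 0
  expect_error(metricsFromCounts(confusionCounts(allCell, someWound)),
               "precision")
})

test_that("dice loss and DSC are consistent on binarized maps", {
  for (seed in 1:20) {
    p <- randProb(8, 8, seed = seed)
    g <- randMask(8, 8, pCell = 0.5, seed = seed + 100)
    pb <- binarize(p, 0.5)
    dsc <- metricsFromCounts(confusionCounts(pb, g))$dsc
    expect_equal(1 - diceLoss(pb, g), dsc, tolerance = 1e-5)
  }
})

test_that("class-flip duality: the wound-positive convention is load-bearing", {
  pred <- randMask(8, 8, seed = 9)
  gt <- randMask(8, 8, pCell = 0.5, seed = 10)
  cc <- confusionCounts(pred, gt)
  flip <- confusionCounts(1 - pred, 1 - gt)
  expect_equal(flip$tp, cc$tn)
  expect_equal(flip$tn, cc$tp)
  expect_equal(flip$fp, cc$fn)
  expect_equal(flip$fn, cc$fp)
  r <- metricsFromCounts(cc); rf <- metricsFromCounts(flip)
  expect_equal(rf$spe, r$rec)    # specificity<->recall swap under the flip
  expect_equal(r$acc, rf$acc)    # accuracy is convention-free
})

test_that("ROC-AUC matches pair-counting enumeration", {
  g <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3)
  p <- matrix(c(0.1, 0.3, 0.6, 0.5, 0.8, 0.9), 2, 3)
  auc <- rocAuc(p, g)
  expect_equal(auc, oracleAuc(1 - p, g == 0))

  # probabilities equal to the mask give a perfect ranking
  m <- randMask(6, 6, pCell = 0.5, seed = 2)
  expect_equal(rocAuc(m, m), 1)
  # constant map: AUC 0.5 by the tie convention
  expect_equal(rocAuc(matrix(0.7, 6, 6), m), 0.5)
  # random cases against the oracle
  for (seed in 1:10) {
    p2 <- randProb(4, 5, seed = seed)
    g2 <- randMask(4, 5, pCell = 0.5, seed = seed + 30)
    if (all(g2 == g2[1])) next
    expect_equal(rocAuc(p2, g2), oracleAuc(1 - p2, g2 == 0))
  }
  expect_error(rocAuc(randProb(3, 3), matrix(1, 3, 3)), "single-class")
})

test_that("ROC-AUC agrees with pROC on a random map", {
  skip_if_not_installed("pROC")
  p <- randProb(8, 8, seed = 5)
  g <- randMask(8, 8, pCell = 0.5, seed = 6)
  ours <- rocAuc(p, g)
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = as.vector(g == 0), predictor = as.vector(1 - p),
              direction = "<", quiet = TRUE))))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("binarized-score AUC mode is available and differs in general", {
  p <- randProb(8, 8, seed = 7)
  g <- randMask(8, 8, pCell = 0.5, seed = 8)
  a1 <- rocAuc(p, g)
  a2 <- rocAuc(p, g, onBinarized = TRUE)
  expect_true(a2 >= 0 && a2 <= 1)
  expect_false(isTRUE(all.equal(a1, a2)))
})

test_that("aggregation is a per-image macro average, not a pooled count", {
  r1 <- data.frame(dsc = 0.9, acc = 1, iou = 0.8)
  r2 <- data.frame(dsc = 1.0, acc = 0.9, iou = 1)
  agg <- aggregateMetrics(rbind(r1, r2))
  expect_equal(agg$dsc, 0.95)
  expect_equal(aggregateMetrics(r1)$dsc, 0.9)   # single report: itself
  expect_error(aggregateMetrics(list()), "empty")

  # demonstration that macro != pooled on imbalanced images:
  # image A: 2x2, perfect; image B: 4x4 with a one-column boundary shift
  predA <- matrix(c(0, 0, 1, 1), 2, 2); gtA <- predA
  gtB <- matrix(1, 4, 4); gtB[, 1:2] <- 0
  predB <- matrix(1, 4, 4); predB[, 1:3] <- 0
  dA <- metricsFromCounts(confusionCounts(predA, gtA))$dsc
  dB <- metricsFromCounts(confusionCounts(predB, gtB))$dsc
  macro <- mean(c(dA, dB))
  ccA <- confusionCounts(predA, gtA); ccB <- confusionCounts(predB, gtB)
  pooled <- metricsFromCounts(list(tp = ccA$tp + ccB$tp, tn = ccA$tn + ccB$tn,
                                   fp = ccA$fp + ccB$fp,
                                   fn = ccA$fn + ccB$fn))$dsc
  expect_false(isTRUE(all.equal(macro, pooled)))
})
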