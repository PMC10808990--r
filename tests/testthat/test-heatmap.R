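test_that("gaussianRadius is maximal under the three displacement cases", {
  expect_equal(gaussianRadius(0, 10), 0)
  expect_equal(gaussianRadius(10, 0), 0)
  expect_gte(gaussianRadius(64, 64, 0.7), gaussianRadius(32, 32, 0.7))
  expect_error(gaussianRadius(8, 8, 1.2), "min_overlap")

  # verify against explicit IoU computation: at the returned radius all
  # three corner-displacement patterns keep IoU >= min_overlap, and a
  # slightly larger radius breaks at least one of them
  caseIous <- function(w, h, r) {
    base <- boundingBox(0, 0, w, h)
    c(iou(base, boundingBox(r, r, w + r, h + r)),       # translation
      iou(base, boundingBox(-r, -r, w + r, h + r)),     # both corners out
      iou(base, boundingBox(r, r, max(r, w - r), max(r, h - r))))
  }
  for (sz in list(c(32, 32), c(10, 24), c(64, 16))) {
    ov <- 0.7
    r <- gaussianRadius(sz[1], sz[2], ov)
    expect_true(all(caseIous(sz[1], sz[2], r) >= ov - 1e-9))
    expect_true(any(caseIous(sz[1], sz[2], r * 1.05 + 0.01) < ov))
  }
})

test_that("encodeHeatmap writes peak-1 Gaussians with exact zero tails", {
  cfg <- gaussianEncodingConfig()
  # no boxes -> all-zero map
  h0 <- encodeHeatmap(imageAnnotation("e", 64, 64), 4, cfg)
  expect_true(all(h0 == 0))
  expect_equal(dim(h0), c(16, 16))

  # box centered at (64, 64) at r = 4 encodes a 1 at cell (16, 16)
  ann <- imageAnnotation("c", 128, 128,
                         boundingBox(44, 44, 84, 84), clip = FALSE)
  h <- encodeHeatmap(ann, 4, cfg)
  expect_equal(h[17, 17], 1)  # cell (x=16, y=16) is [row 17, col 17]
  expect_true(all(h >= 0 & h <= 1))
  expect_true(all(h[h < cfg$zero_threshold] == 0))

  # duplicated box at the same center: elementwise max is idempotent
  ann2 <- imageAnnotation("c2", 128, 128,
                          rbind(boundingBox(44, 44, 84, 84),
                                boundingBox(44, 44, 84, 84)),
                          clip = FALSE)
  expect_equal(as.numeric(encodeHeatmap(ann2, 4, cfg)), as.numeric(h))
})

test_that("nonzero footprint equals brute-force Gaussian enumeration", {
  cfg <- gaussianEncodingConfig()
  for (side in c(40, 80, 120)) {
    ann <- imageAnnotation("b", 256, 256,
                           boundingBox(100 - side / 2, 100 - side / 2,
                                       100 + side / 2, 100 + side / 2),
                           clip = FALSE)
    h <- encodeHeatmap(ann, 4, cfg)
    rad <- gaussianRadius(side / 4, side / 4, cfg$min_overlap)
    sigma <- (2 * rad + 1) / 6
    expected <- oracleGaussianCount(nrow(h), ncol(h), 25, 25, sigma,
                                    cfg$zero_threshold)
    expect_equal(sum(h != 0), expected)
  }
})

test_that("sample allocation partitions the grid under both strategies", {
  h0 <- matrix(0, 8, 8)
  a0 <- allocateSamples(h0, "expanded")
  expect_equal(sum(a0$positive_mask), 0)
  expect_true(all(a0$negative_mask))

  ann <- imageAnnotation("b", 256, 256,
                         boundingBox(60, 60, 140, 140), clip = FALSE)
  h <- encodeHeatmap(ann, 4)
  ae <- allocateSamples(h, "expanded")
  ao <- allocateSamples(h, "original")
  # masks partition the grid
  expect_true(all(xor(ae$positive_mask, ae$negative_mask)))
  expect_true(all(xor(ao$positive_mask, ao$negative_mask)))
  # expanded counts = brute-force nonzero count; original = one per fruit
  expect_equal(sum(ae$positive_mask), sum(h != 0))
  expect_equal(sum(ao$positive_mask), 1)
  expect_gt(sum(ae$positive_mask), sum(ao$positive_mask))
  # expanded positives are a superset of original positives
  expect_true(all(ao$positive_mask[ae$positive_mask == FALSE] == FALSE))
  # targets follow the strategy
  expect_identical(ae$target_values, as.matrix(h))
  expect_true(all(ao$target_values %in% c(0, 1)))
  expect_error(allocateSamples(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("number of encoded 1-entries equals number of distinct centers", {
  set.seed(21)
  for (k in 1:10) {
    ann <- randomSeparatedAnnotation(96, 96, n = 4, minSep = 16)
    h <- encodeHeatmap(ann, 4)
    expect_equal(sum(h == 1), nrow(attr(h, "centers")))
  }
})

test_that("loss values match direct substitution at frozen points", {
  cfg <- lossConfig()
  # single positive pixel, prediction 0.5
  expect_equal(modifiedFocalLoss(matrix(0.5), matrix(1), cfg),
               -(1 - 0.5)^2 * log(0.5), tolerance = 1e-12)
  expect_equal(modifiedFocalLoss(matrix(0.5), matrix(1), cfg),
               0.25 * log(2), tolerance = 1e-10)
  # single negative pixel
  expect_equal(modifiedFocalLoss(matrix(0.5), matrix(0), cfg),
               -0.5^2 * log(0.5), tolerance = 1e-12)
  # continuous loss agrees with focal at the binary point
  expect_equal(continuousLabelLoss(matrix(0.5), matrix(1), cfg),
               modifiedFocalLoss(matrix(0.5), matrix(1), cfg),
               tolerance = 1e-12)
  # fractional label 0.8 vs prediction 0.5
  expect_equal(continuousLabelLoss(matrix(0.5), matrix(0.8), cfg),
               -(0.3)^2 * (0.2 * log(0.5) + 0.8 * log(0.5)),
               tolerance = 1e-12)
  expect_equal(continuousLabelLoss(matrix(0.5), matrix(0.8), cfg),
               0.0624, tolerance = 1e-3)
  # near-perfect positive prediction: loss vanishes with the clamp
  expect_lt(modifiedFocalLoss(matrix(1 - 1e-6), matrix(1), cfg), 1e-11)
})

test_that("losses equal per-pixel substitution oracles on random grids", {
  set.seed(22)
  cfg <- lossConfig()
  for (k in 1:8) {
    gt <- matrix(runif(64), 8, 8)
    gt[sample(64, 5)] <- 1
    gt[sample(64, 20)] <- 0
    pred <- matrix(runif(64, 0.01, 0.99), 8, 8)
    expect_equal(modifiedFocalLoss(pred, gt, cfg),
                 oracleFocal(pred, gt), tolerance = 1e-6)
    expect_equal(continuousLabelLoss(pred, gt, cfg),
                 oracleContinuous(pred, gt), tolerance = 1e-6)
    expect_gte(modifiedFocalLoss(pred, gt, cfg), 0)
    expect_gte(continuousLabelLoss(pred, gt, cfg), 0)
  }
})

test_that("continuous loss is zero iff prediction equals ground truth", {
  set.seed(23)
  gt <- matrix(runif(36), 6, 6)
  expect_equal(continuousLabelLoss(gt, gt), 0)
  pred <- gt; pred[3, 3] <- pred[3, 3] / 2 + 0.25 + 1e-3
  expect_gt(continuousLabelLoss(pred, gt), 0)
})

test_that("continuous loss equals focal loss elementwise on binary maps", {
  set.seed(24)
  cfg <- lossConfig()
  for (k in 1:10) {
    gt <- matrix(rbinom(25, 1, 0.3), 5, 5)
    pred <- matrix(runif(25, 0.05, 0.95), 5, 5)
    # elementwise: compare per-pixel via 1x1 maps
    for (i in sample(25, 6)) {
      expect_equal(
        continuousLabelLoss(matrix(pred[i]), matrix(gt[i]), cfg),
        modifiedFocalLoss(matrix(pred[i]), matrix(gt[i]), cfg),
        tolerance = 1e-12)
    }
    expect_equal(continuousLabelLoss(pred, gt, cfg),
                 modifiedFocalLoss(pred, gt, cfg), tolerance = 1e-12)
  }
})

test_that("supervision strength decreases away from the center", {
  ann <- imageAnnotation("m", 256, 256,
                         boundingBox(68, 68, 188, 188), clip = FALSE)
  h <- encodeHeatmap(ann, 4)
  ctr <- attr(h, "centers")
  cx <- ctr[1, "x"]; cy <- ctr[1, "y"]
  cfg <- lossConfig()
  # per-pixel continuous-loss penalty at constant prediction c = 0.1,
  # along a ray to the right of the center, while the target exceeds c
  penalty <- function(target)
    continuousLabelLoss(matrix(0.1), matrix(target), cfg)
  ray <- h[cy + 1, (cx + 1):ncol(h)]
  ray <- ray[ray > 0.1]
  pens <- vapply(ray, penalty, numeric(1))
  expect_true(all(diff(pens) <= 1e-12))
})

test_that("branch loss dispatch honours the strategy pairings", {
  ann <- imageAnnotation("d", 64, 64, boundingBox(8, 8, 56, 56),
                         clip = FALSE)
  h <- encodeHeatmap(ann, 4)
  pred <- matrix(0.5, nrow(h), ncol(h))
  # baseline pairing on the binarized map equals the focal loss on it
  expect_equal(
    heatmapBranchLoss(pred, h, "original", "focal"),
    modifiedFocalLoss(pred, allocateSamples(h, "original")$target_values))
  # improved pairing with perfect prediction is zero
  expect_equal(heatmapBranchLoss(h, h, "expanded", "continuous"), 0)
  # improved pairing equals the brute-force per-pixel oracle
  expect_equal(heatmapBranchLoss(pred, h, "expanded", "continuous"),
               oracleContinuous(pred, as.matrix(h)), tolerance = 1e-6)
  expect_error(heatmapBranchLoss(pred, h, "expanded", "focal"),
               "incoherent")
  expect_error(modifiedFocalLoss(matrix(0.5, 2, 2), matrix(1)), "shape")
})

test_that("analytic loss gradients match numeric differentiation", {
  set.seed(25)
  cfg <- lossConfig()
  gt <- matrix(runif(16), 4, 4); gt[1, 1] <- 1; gt[2, 2] <- 0
  pred <- matrix(runif(16, 0.1, 0.9), 4, 4)
  for (fn in list(
    c(loss = continuousLabelLoss, grad = fruitpoint:::contLossGrad),
    c(loss = modifiedFocalLoss, grad = fruitpoint:::focalLossGrad))) {
    g <- fn$grad(pred, gt, cfg)
    for (i in sample(16, 4)) {
      eps <- 1e-6
      pp <- pred; pp[i] <- pp[i] + eps
      pm <- pred; pm[i] <- pm[i] - eps
      num <- (fn$loss(pp, gt, cfg) - fn$loss(pm, gt, cfg)) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})
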