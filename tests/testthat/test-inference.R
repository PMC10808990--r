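test_that("decoding an empty or sub-threshold heatmap yields no
           detections", {
  out <- list(r = 4L, hm = matrix(0.1, 16, 16),
              size = array(0, c(16, 16, 2)),
              off = array(0, c(16, 16, 2)))
  dets <- decodeLayer(out, 4, decodeConfig(score_threshold = 0.3))
  expect_equal(nrow(dets), 0)
})

test_that("ideal maps decode back to the ground-truth boxes", {
  ann <- imageAnnotation("rt", 64, 64,
                         rbind(boundingBox(6, 6, 26, 22),     # small
                               boundingBox(28, 28, 62, 60)),  # large
                         clip = FALSE)
  ideal <- idealOutputs(ann)
  d1 <- decodeLayer(ideal$layer1, 2, imageSize = c(64, 64))
  d2 <- decodeLayer(ideal$layer2, 4, imageSize = c(64, 64))
  expect_equal(nrow(d1), 1); expect_equal(nrow(d2), 1)
  expect_equal(d1$score, 1); expect_equal(d2$score, 1)
  expect_equal(d1$source_layer, 1L); expect_equal(d2$source_layer, 2L)
  expect_equal(unlist(d1[1, 1:4]),
               c(x_min = 6, y_min = 6, x_max = 26, y_max = 22),
               tolerance = 1e-4)
  expect_equal(unlist(d2[1, 1:4]),
               c(x_min = 28, y_min = 28, x_max = 62, y_max = 60),
               tolerance = 1e-4)
})

test_that("decoding is equivariant to integer translations of ideal
           maps", {
  base <- boundingBox(8, 10, 24, 26)
  for (shift in c(4, 8)) {
    a1 <- imageAnnotation("t1", 64, 64, base, clip = FALSE)
    a2 <- imageAnnotation("t2", 64, 64,
                          boundingBox(base$x_min + shift,
                                      base$y_min + shift,
                                      base$x_max + shift,
                                      base$y_max + shift),
                          clip = FALSE)
    d1 <- decodeLayer(idealOutputs(a1)$layer1, 2,
                      imageSize = c(64, 64))
    d2 <- decodeLayer(idealOutputs(a2)$layer1, 2,
                      imageSize = c(64, 64))
    expect_equal(d2$x_min, d1$x_min + shift, tolerance = 1e-9)
    expect_equal(d2$y_max, d1$y_max + shift, tolerance = 1e-9)
  }
})

test_that("layer merging keeps the higher-scoring duplicate", {
  d1 <- cbind(boundingBox(0, 0, 10, 10),
              data.frame(score = 0.9, source_layer = 1L))
  d2 <- cbind(boundingBox(0, 0, 10, 10),
              data.frame(score = 0.7, source_layer = 2L))
  m <- mergeLayers(d1, d2)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 0.9)
  expect_equal(m$source_layer, 1L)

  # disjoint sets concatenate, sorted by score
  d3 <- cbind(boundingBox(40, 40, 50, 50),
              data.frame(score = 0.95, source_layer = 2L))
  m2 <- mergeLayers(d1, d3)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$score, c(0.95, 0.9))
})

test_that("layer merging equals the quadratic greedy suppression
           oracle", {
  set.seed(51)
  for (k in 1:20) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    mk <- function(n, layer) {
      if (n == 0) return(fruitpoint:::emptyDetections())
      cbind(randomBoxes(n, 60, 60, minSide = 5, maxSide = 25),
            data.frame(score = runif(n),
                       source_layer = rep(layer, n)))
    }
    d1 <- mk(n1, 1L); d2 <- mk(n2, 2L)
    got <- mergeLayers(d1, d2, decodeConfig(cross_layer_nms_iou = 0.5))
    want <- oracleNms(rbind(d1, d2), 0.5)
    expect_equal(got$score, want$score)
    expect_equal(got$x_min, want$x_min)
    expect_lte(nrow(got), n1 + n2)
    # a detection with no overlapping partner is never dropped
    all <- rbind(d1, d2)
    if (nrow(all) > 1) {
      M <- iouMatrix(all, all); diag(M) <- 0
      lone <- which(apply(M, 1, max) == 0)
      for (i in lone)
        expect_true(any(abs(got$score - all$score[i]) < 1e-12))
    }
  }
})

test_that("round trip recovers centers within r and sizes exactly on
           random scenes", {
  set.seed(52)
  for (k in 1:25) {
    ann <- randomSeparatedAnnotation(64, 64, n = sample(1:4, 1))
    ideal <- idealOutputs(ann)
    dets <- mergeLayers(
      decodeLayer(ideal$layer1, 2, imageSize = c(64, 64)),
      decodeLayer(ideal$layer2, 4, imageSize = c(64, 64)))
    gt <- annotationBoxes(ann)
    expect_equal(nrow(dets), nrow(gt))
    gC <- boxCenter(gt); dC <- boxCenter(dets)
    for (j in seq_len(nrow(gt))) {
      dist <- sqrt((dC[, 1] - gC[j, 1])^2 + (dC[, 2] - gC[j, 2])^2)
      i <- which.min(dist)
      r <- if (isSmallObject(gt[j, ], 64, 64)) 2 else 4
      expect_lt(dist[i], r)
      expect_equal(boxWidth(dets[i, ]), boxWidth(gt[j, ]),
                   tolerance = 1e-9)
      expect_equal(boxHeight(dets[i, ]), boxHeight(gt[j, ]),
                   tolerance = 1e-9)
    }
  }
})

test_that("pseudo-label export writes per-image annotations and a
           summary", {
  cfgS <- sceneConfig(width = 64, height = 64, fruits = c(2, 2),
                      occlusion_prob = 0)
  scenes <- suppressMessages(lapply(1:3, function(i)
    generateScene(cfgS, seed = 600 + i)))
  imgs <- lapply(scenes, `[[`, "image")
  names(imgs) <- sprintf("img%02d", 1:3)
  det <- buildDetector(tinyModelConfig(), seed = 5)

  # route raw detections through the refinement hook to well-formed
  # fixed boxes, isolating the export plumbing from model quality
  set.seed(54)
  fixedBoxes <- lapply(1:3, function(i)
    cbind(randomBoxes(2, 64, 64, minSide = 6, maxSide = 20),
          data.frame(score = runif(2, 0.3, 1), source_layer = 2L)))
  names(fixedBoxes) <- names(imgs)
  out <- tempfile(fileext = ".json")
  smry <- exportPseudoLabels(imgs, det, out, "coco",
                             decodeConfig(score_threshold = 0.2),
                             hook = function(id, d) fixedBoxes[[id]])
  expect_equal(smry$images, 3L)
  expect_equal(smry$boxes, 6L)
  back <- readAnnotations(out, "coco")
  expect_equal(length(back), 3L)
  expect_equal(sum(vapply(back, nBoxes, integer(1))), smry$boxes)
  expect_equal(annotationBoxes(back[["img02"]])$x_min,
               fixedBoxes[["img02"]]$x_min, tolerance = 1e-9)

  # a threshold of 1 exports empty files
  out2 <- tempfile(fileext = ".json")
  smry2 <- exportPseudoLabels(imgs, det, out2, "coco",
                              decodeConfig(score_threshold = 1))
  expect_equal(smry2$boxes, 0L)
  expect_true(all(vapply(readAnnotations(out2, "coco"), nBoxes,
                         integer(1)) == 0))

  # the refinement hook can filter labels before export
  out3 <- tempfile(fileext = ".json")
  exportPseudoLabels(imgs, det, out3, "coco",
                     decodeConfig(score_threshold = 0.2),
                     hook = function(id, d) {
                       fb <- fixedBoxes[[id]]
                       fb[fb$score >= 0.6, , drop = FALSE]
                     })
  expect_true(all(vapply(readAnnotations(out3, "coco"), function(a) {
    b <- annotationBoxes(a)
    nrow(b) == 0 || all(b$score >= 0.6)
  }, logical(1))))
})

test_that("exported labels re-evaluate to the same AP as in-memory
           detections", {
  set.seed(53)
  cfgS <- sceneConfig(width = 64, height = 64, fruits = c(2, 3),
                      occlusion_prob = 0)
  scenes <- suppressMessages(lapply(1:4, function(i)
    generateScene(cfgS, seed = 700 + i)))
  gts <- lapply(scenes, `[[`, "annotation")
  ids <- sprintf("img%02d", seq_along(scenes))
  names(gts) <- ids
  # detections: the GT boxes jittered, plus noise boxes, with scores
  dets <- lapply(gts, function(a) {
    g <- annotationBoxes(a)
    jit <- g + matrix(runif(4 * nrow(g), -3, 3), nrow(g))
    jit <- clipBoxes(jit, 64, 64)
    d <- rbind(jit, randomBoxes(2, 64, 64, minSide = 5, maxSide = 20))
    cbind(d, data.frame(score = runif(nrow(d), 0.1, 1),
                        source_layer = 2L))
  })
  names(dets) <- ids
  apMem <- averagePrecision(dets, gts)
  f <- tempfile(fileext = ".json")
  anns <- lapply(ids, function(id)
    imageAnnotation(id, 64, 64, dets[[id]]))
  names(anns) <- ids
  writeAnnotations(anns, f, "coco")
  evFile <- evaluateDetections(f, gts)
  expect_equal(evFile@ap, apMem, tolerance = 1e-9)
})
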