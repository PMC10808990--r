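test_that("the cropped neck graph has 6 fusion nodes and no
           shallow-to-deep edge", {
  g <- neckGraph("cropped_double")
  nodes <- unique(g[, c("to_m", "to_n")])
  expect_equal(nrow(nodes), 6L)
  # every fusion node has exactly two parents: (m, n-1) and (2m, n-1)
  for (k in seq_len(nrow(nodes))) {
    par <- g[g$to_m == nodes$to_m[k] & g$to_n == nodes$to_n[k], ]
    expect_equal(nrow(par), 2L)
    expect_setequal(par$from_m, c(nodes$to_m[k], 2 * nodes$to_m[k]))
    expect_true(all(par$from_n == nodes$to_n[k] - 1))
  }
  # no edge fuses information from a shallower (smaller m) source into
  # a deeper (larger m) node
  expect_false(any(g$from_m < g$to_m))
  # valid index set per the deep-to-shallow recursion
  expect_setequal(paste(nodes$to_m, nodes$to_n),
                  c("8 1", "4 1", "4 2", "2 1", "2 2", "2 3"))
})

test_that("the original neck executes exactly 3 fusion steps on
           progressively deeper maps", {
  g <- neckGraph("original_single")
  expect_equal(sort(unique(g$to_n)), 1:3)
  du <- g[g$op == "DU", ]
  expect_equal(du$from_m[order(du$to_n)], c(8, 16, 32))
  expect_true(all(g$to_m == 4))
})

test_that("backbone emits the contracted pyramid shapes deterministically", {
  det <- buildDetector(tinyModelConfig(), seed = 7)
  img <- flatImage(64, 64, 0.3)
  pyr <- backboneForward(det, img)
  expect_setequal(names(pyr), c("2", "4", "8", "16"))
  for (m in c(2, 4, 8, 16))
    expect_equal(dim(pyr[[as.character(m)]])[1:2], c(64 / m, 64 / m))
  # determinism: identical weights and input give identical maps
  pyr2 <- backboneForward(det, img)
  expect_identical(pyr, pyr2)
  # non-multiple-of-16 input is zero-padded, original size recorded
  pyr3 <- backboneForward(det, array(0.2, c(50, 60, 3)))
  expect_equal(attr(pyr3, "orig"), c(50, 60))
  expect_equal(dim(pyr3[["2"]])[1:2], c(32, 32))
})

test_that("neck outputs are at exactly 2x and 4x downsampling", {
  det <- buildDetector(tinyModelConfig(), seed = 8)
  for (side in c(64, 96)) {
    outs <- detectorOutputs(det, flatImage(side, side))
    expect_setequal(names(outs), c("layer1", "layer2"))
    expect_equal(dim(outs$layer1$hm), c(side / 2, side / 2))
    expect_equal(dim(outs$layer2$hm), c(side / 4, side / 4))
    expect_equal(outs$layer1$r, 2L)
    expect_equal(outs$layer2$r, 4L)
  }
  detO <- buildDetector(tinyModelConfig("original_single"), seed = 8)
  outsO <- detectorOutputs(detO, flatImage(64, 64))
  expect_equal(names(outsO), "layer2")
  expect_equal(dim(outsO$layer2$hm), c(16, 16))
})

test_that("constant inputs flow along aggregation paths with binomial
           multiplicity", {
  # with identity fusion operators the deep-to-shallow recursion
  # O(m, n) = O(m, n-1) + O(2m, n-1) makes each projected input reach
  # the outputs with path-counting coefficients:
  #   O(2, 3) = v2 + 3 v4 + 3 v8 + v16 ; O(4, 2) = v4 + 2 v8 + v16
  cfg <- modelConfig(backbone_channels = c(4, 4, 4, 4),
                     neck_channels = 4, head_channels = 4)
  det <- buildDetector(cfg, seed = 9)
  idw <- array(0, dim = c(3, 3, 4, 4))
  for (c in 1:4) idw[2, 2, c, c] <- 1
  idp <- array(0, dim = c(1, 1, 4, 4))
  for (c in 1:4) idp[1, 1, c, c] <- 1
  p <- det@params
  for (nm in names(p)) {
    if (grepl("^(dc|du)_.*\\.w$", nm)) p[[nm]] <- idw
    if (grepl("^proj.*\\.w$", nm)) p[[nm]] <- idp
    if (grepl("^(dc|du|proj).*\\.b$", nm)) p[[nm]] <- rep(0, 4)
  }
  det@params <- p
  v <- c("2" = 0.1, "4" = 0.2, "8" = 0.4, "16" = 0.8)
  pyramid <- lapply(names(v), function(m) {
    side <- 64 / as.numeric(m)
    array(v[[m]], dim = c(side, side, 4))
  })
  names(pyramid) <- names(v)
  neck <- neckForwardCropped(det, pyramid)
  expect_equal(max(abs(neck$layer1 -
                         (0.1 + 3 * 0.2 + 3 * 0.4 + 0.8))), 0,
               tolerance = 1e-12)
  expect_equal(max(abs(neck$layer2 - (0.2 + 2 * 0.4 + 0.8))), 0,
               tolerance = 1e-12)

  # original single-layer neck: F3 = v4 + v8 + v16 + v32
  cfgO <- modelConfig(backbone_channels = c(4, 4, 4, 4),
                      neck_channels = 4, head_channels = 4,
                      neck = "original_single")
  detO <- buildDetector(cfgO, seed = 9)
  pO <- detO@params
  for (nm in names(pO)) {
    if (grepl("^(fdc|fdu)_.*\\.w$", nm)) pO[[nm]] <- idw
    if (grepl("^proj.*\\.w$", nm)) pO[[nm]] <- idp
    if (grepl("^(fdc|fdu|proj).*\\.b$", nm)) pO[[nm]] <- rep(0, 4)
  }
  detO@params <- pO
  vO <- c("4" = 0.2, "8" = 0.4, "16" = 0.8, "32" = 1.0)
  pyrO <- lapply(names(vO), function(m) {
    side <- 128 / as.numeric(m)
    array(vO[[m]], dim = c(side, side, 4))
  })
  names(pyrO) <- names(vO)
  neckO <- neckForwardOriginal(detO, pyrO)
  expect_equal(max(abs(neckO$layer2 - (0.2 + 0.4 + 0.8 + 1.0))), 0,
               tolerance = 1e-12)
})

test_that("heads produce three branches with the contracted shapes", {
  det <- buildDetector(tinyModelConfig(), seed = 10)
  neckOut <- list(layer1 = array(0.1, c(32, 32, 16)),
                  layer2 = array(0.1, c(16, 16, 16)))
  heads <- headsForward(det, neckOut)
  expect_equal(dim(heads$layer1$hm), c(32, 32))
  expect_equal(dim(heads$layer1$size), c(32, 32, 2))
  expect_equal(dim(heads$layer1$off), c(32, 32, 2))
  expect_true(all(heads$layer1$hm >= 0 & heads$layer1$hm <= 1))
  # zero-ish input with the -2.19 heatmap bias gives a foreground
  # prior near 0.1
  headsZ <- headsForward(det, list(layer1 = array(0, c(32, 32, 16)),
                                   layer2 = array(0, c(16, 16, 16))))
  expect_equal(mean(headsZ$layer1$hm), 1 / (1 + exp(2.19)),
               tolerance = 1e-9)
})

test_that("backpropagation reaches backbone weights with correct
           gradients", {
  set.seed(31)
  det <- buildDetector(tinyModelConfig(), seed = 31)
  # one small and one large fruit so both prediction layers carry
  # heatmap, size and offset supervision
  ann <- imageAnnotation("g", 64, 64,
                         rbind(boundingBox(4, 4, 20, 18),
                               boundingBox(24, 24, 60, 62)),
                         clip = FALSE)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  cfg <- tinyTrainConfig(epochs = 1)
  lcfg <- lossConfig()
  tg <- buildLayerTargets(ann)
  lg <- fruitpoint:::lossAndGrads(det, img, tg, cfg, lcfg)
  expect_true(is.finite(lg$total))
  for (nm in c("bb1.w", "proj8.w", "du_m2n3.w", "h2_off_o.w")) {
    expect_true(nm %in% names(lg$grads))
    p <- det@params[[nm]]
    i <- sample(length(p), 1)
    eps <- 1e-5
    perturb <- function(v) {
      d2 <- det; d2@params[[nm]][i] <- v
      fruitpoint:::lossAndGrads(d2, img, tg, cfg, lcfg)$total
    }
    num <- (perturb(p[i] + eps) - perturb(p[i] - eps)) / (2 * eps)
    expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-3)
  }
})

test_that("the tiny model stays small and fast", {
  det <- buildDetector(tinyModelConfig(), seed = 1)
  expect_lt(nParameters(det), 200000)
  t0 <- Sys.time()
  detectorOutputs(det, flatImage(64, 64))
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1)
})

test_that("checkpoints round-trip weights and configuration", {
  det <- buildDetector(tinyModelConfig(), seed = 3)
  f <- tempfile(fileext = ".ckpt")
  saveDetector(det, f)
  back <- loadDetector(f)
  expect_identical(back@config, det@config)
  expect_identical(back@params, det@params)
  saveRDS(list(format = "other"), f)
  expect_error(loadDetector(f), "checkpoint")
})
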