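# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately written as direct, unoptimized translations
# of the definitions so they stay independent of the package's
# implementation paths.

# Direct per-pixel substitution of the modified focal loss, total-pixel
# normalizer.
oracleFocal <- function(pred, gt, alpha = 2, beta = 4, eps = 1e-6) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  s <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    s <- s + if (gt[i, j] == 1) {
      (1 - p[i, j])^alpha * log(p[i, j])
    } else {
      (1 - gt[i, j])^beta * p[i, j]^alpha * log(1 - p[i, j])
    }
  }
  -s / length(gt)
}

# Direct per-pixel substitution of the continuous label value loss.
oracleContinuous <- function(pred, gt, beta = 2, eps = 1e-6) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  s <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    s <- s + abs(gt[i, j] - p[i, j])^beta *
      ((1 - gt[i, j]) * log(1 - p[i, j]) +
         gt[i, j] * log(p[i, j]))
  }
  -s / length(gt)
}

# Count grid cells whose unnormalized Gaussian code (center cx, cy,
# given sigma) reaches the zero threshold: brute-force enumeration
# over the full grid.
oracleGaussianCount <- function(nrowH, ncolH, cx, cy, sigma,
                                threshold = 2^-7) {
  cnt <- 0
  for (y in 0:(nrowH - 1)) for (x in 0:(ncolH - 1)) {
    v <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2))
    if (v >= threshold) cnt <- cnt + 1
  }
  cnt
}

# Greedy score-ordered IoU suppression, quadratic reference.
oracleNms <- function(dets, iouThr) {
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  rownames(dets) <- NULL
  keep <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(dets))) {
      if (j <= i || !keep[j]) next
      if (iou(dets[i, ], dets[j, ]) > iouThr) keep[j] <- FALSE
    }
  }
  dets[keep, , drop = FALSE]
}

# Greedy score-ordered one-to-one matching, written longhand.
oracleMatch <- function(dets, gts, iouThr) {
  dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
  rownames(dets) <- NULL
  tp <- logical(nrow(dets))
  used <- logical(nrow(gts))
  for (i in seq_len(nrow(dets))) {
    best <- 0; bestJ <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- iou(dets[i, ], gts[j, ])
      if (v > best) { best <- v; bestJ <- j }
    }
    if (bestJ > 0 && best >= iouThr) {
      tp[i] <- TRUE; used[bestJ] <- TRUE
    }
  }
  tp
}

# Random non-degenerate boxes inside a W x H image.
randomBoxes <- function(n, W = 100, H = 100, minSide = 2,
                        maxSide = 30) {
  w <- runif(n, minSide, maxSide); h <- runif(n, minSide, maxSide)
  x <- runif(n, 0, W - w); y <- runif(n, 0, H - h)
  boundingBox(x, y, x + w, y + h)
}

# Random annotation whose box centers fall in distinct, well-separated
# heatmap cells at both prediction strides, so ideal-map decoding is
# unambiguous.
randomSeparatedAnnotation <- function(W = 64, H = 64, n = 3,
                                      minSep = 12) {
  centers <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(centers) < n && guard < 200) {
    guard <- guard + 1
    cand <- c(runif(1, 10, W - 10), runif(1, 10, H - 10))
    if (nrow(centers) == 0 ||
        min(sqrt(colSums((t(centers) - cand)^2))) >= minSep)
      centers <- rbind(centers, cand)
  }
  w <- runif(nrow(centers), 6, 18)
  h <- runif(nrow(centers), 6, 18)
  b <- boundingBox(centers[, 1] - w / 2, centers[, 2] - h / 2,
                   centers[, 1] + w / 2, centers[, 2] + h / 2)
  b <- clipBoxes(b, W, H)
  imageAnnotation(sprintf("rand%03d", sample.int(1000, 1)), W, H, b,
                  clip = FALSE)
}

# Ideal per-layer prediction maps from ground truth: the encoded
# heatmap itself plus exact size/offset values at the encoded center
# cells (the encode -> decode round-trip oracle input).
idealOutputs <- function(annotation,
                         encoding = gaussianEncodingConfig()) {
  tg <- buildLayerTargets(annotation, encoding)
  outs <- list()
  for (nm in c("layer1", "layer2")) {
    t1 <- tg[[nm]]
    hm <- t1$heatmap
    size <- array(0, dim = c(nrow(hm), ncol(hm), 2))
    off <- array(0, dim = c(nrow(hm), ncol(hm), 2))
    ctr <- t1$centers
    for (k in seq_len(nrow(ctr))) {
      size[ctr$cy[k] + 1, ctr$cx[k] + 1, 1] <- ctr$w[k]
      size[ctr$cy[k] + 1, ctr$cx[k] + 1, 2] <- ctr$h[k]
      off[ctr$cy[k] + 1, ctr$cx[k] + 1, 1] <- ctr$dx[k]
      off[ctr$cy[k] + 1, ctr$cx[k] + 1, 2] <- ctr$dy[k]
    }
    outs[[nm]] <- list(r = t1$r, hm = hm, size = size, off = off)
  }
  outs$targets <- tg
  outs
}

# A tiny flat-color test image.
flatImage <- function(H = 64, W = 64, value = 0.5) {
  array(value, dim = c(H, W, 3))
}
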