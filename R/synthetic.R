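#' @include annotations-io.R targets.R
NULL

#' Synthetic orchard scene configuration
#'
#' The generator emulates the two domain gaps of the auto-labeling
#' setting with geometric scenes: a foreground (scale) gap via the
#' \code{scale_regime}, and a background gap via the
#' \code{background_style}. Fruits are shaded ellipses; fruit sizes
#' are drawn in absolute pixels because the small-object criterion
#' mixes an absolute area cutoff with a relative one.
#'
#' \describe{
#'   \item{source_like}{narrow size distribution (box scale about
#'     40 px, sd 3), near-round fruits; no fruit satisfies the
#'     small-object criterion.}
#'   \item{target_like}{a mixture: with probability
#'     \code{small_fraction} a small fruit (scale 8-20 px, always
#'     small by the criterion), otherwise a large fruit (scale from
#'     34 px up to 35\% of the image side, never small); elliptical
#'     aspect ratios up to \code{aspect_max}.}
#' }
#'
#' @param width,height image size in pixels (default 256 x 256).
#' @param fruits integer range \code{c(min, max)} of fruits per image.
#' @param scale_regime \code{"source_like"} or \code{"target_like"}.
#' @param small_fraction fraction of small fruits under
#'   \code{target_like} (default 0.5).
#' @param aspect_max maximum fruit aspect ratio (default 1.15
#'   source-like round fruit, 1.8 target-like ellipses).
#' @param background_style \code{"style_A"} (green gradient +
#'   leaf-like distractors) or \code{"style_B"} (brown gradient +
#'   branch-like strokes).
#' @param palette base fruit RGB in \code{[0, 1]}.
#' @param color_jitter per-fruit RGB jitter sd.
#' @param occlusion_prob probability a fruit receives an occluding
#'   leaf.
#' @param max_occluded_fraction cap on the fruit fraction an occluder
#'   may cover.
#' @param min_visible_fraction fruits whose visible fraction falls
#'   below this are not annotated (boxes are amodal: they cover the
#'   unoccluded extent).
#' @return a validated configuration list.
#' @export
sceneConfig <- function(width = 256, height = 256, fruits = c(3, 8),
                        scale_regime = c("source_like", "target_like"),
                        small_fraction = 0.5, aspect_max = NULL,
                        background_style = c("style_A", "style_B"),
                        palette = c(0.93, 0.55, 0.12),
                        color_jitter = 0.06,
                        occlusion_prob = 0.2,
                        max_occluded_fraction = 0.5,
                        min_visible_fraction = 0.25) {
  scale_regime <- match.arg(scale_regime)
  background_style <- match.arg(background_style)
  if (is.null(aspect_max))
    aspect_max <- if (scale_regime == "source_like") 1.15 else 1.8
  stopifnot(width >= 32, height >= 32, length(fruits) == 2,
            fruits[1] >= 0, fruits[2] >= fruits[1],
            small_fraction >= 0, small_fraction <= 1, aspect_max >= 1,
            length(palette) == 3, all(palette >= 0 & palette <= 1),
            occlusion_prob >= 0, occlusion_prob <= 1,
            min_visible_fraction >= 0, min_visible_fraction <= 1)
  list(width = as.integer(width), height = as.integer(height),
       fruits = as.integer(fruits), scale_regime = scale_regime,
       small_fraction = small_fraction, aspect_max = aspect_max,
       background_style = background_style, palette = palette,
       color_jitter = color_jitter, occlusion_prob = occlusion_prob,
       max_occluded_fraction = max_occluded_fraction,
       min_visible_fraction = min_visible_fraction)
}

# Sample one fruit's box width/height (pixels). Area is preserved
# under the aspect ratio, so the small-object criterion depends only
# on the sampled scale s (box area = s^2).
sampleFruitSize <- function(config) {
  s <- if (config$scale_regime == "source_like") {
    min(48, max(34, rnorm(1, 40, 3)))
  } else if (runif(1) < config$small_fraction) {
    runif(1, 8, 20)
  } else {
    runif(1, 34, max(48, 0.35 * min(config$width, config$height)))
  }
  a <- runif(1, 1, config$aspect_max)
  if (runif(1) < 0.5) a <- 1 / a
  c(w = s * sqrt(a), h = s / sqrt(a))
}

# Paint a shaded ellipse; `owner` tracks which object owns each pixel
# (for visibility bookkeeping). Returns updated img/owner.
paintEllipse <- function(img, owner, id, cx, cy, ax, ay, baseCol,
                         shade = TRUE) {
  H <- dim(img)[1]; W <- dim(img)[2]
  xlo <- max(1, floor(cx - ax + 1)); xhi <- min(W, ceiling(cx + ax + 1))
  ylo <- max(1, floor(cy - ay + 1)); yhi <- min(H, ceiling(cy + ay + 1))
  if (xhi < xlo || yhi < ylo)
    return(list(img = img, owner = owner))
  xs <- xlo:xhi; ys <- ylo:yhi
  # pixel (row y, col x) has center (x - 0.5, y - 0.5) in image coords
  rr <- outer(((ys - 0.5 - cy) / ay)^2, ((xs - 0.5 - cx) / ax)^2, `+`)
  mask <- rr <= 1
  if (!any(mask)) return(list(img = img, owner = owner))
  shadeFac <- if (shade) 0.6 + 0.5 * (1 - rr[mask]) else
    rep(1, sum(mask))
  for (ch in 1:3) {
    plane <- img[ys, xs, ch, drop = FALSE]
    dim(plane) <- dim(rr)
    plane[mask] <- pmin(1, pmax(0, baseCol[ch] * shadeFac))
    img[ys, xs, ch] <- plane
  }
  own <- owner[ys, xs, drop = FALSE]
  own[mask] <- id
  owner[ys, xs] <- own
  list(img = img, owner = owner)
}

paintBackground <- function(config) {
  H <- config$height; W <- config$width
  img <- array(0, dim = c(H, W, 3))
  t <- matrix(seq(0, 1, length.out = H), H, W)
  cols <- if (config$background_style == "style_A")
    list(top = c(0.36, 0.52, 0.26), bottom = c(0.18, 0.33, 0.14))
  else
    list(top = c(0.48, 0.40, 0.32), bottom = c(0.24, 0.21, 0.18))
  for (ch in 1:3)
    img[, , ch] <- cols$top[ch] * (1 - t) + cols$bottom[ch] * t +
      rnorm(H * W, sd = 0.015)
  owner <- matrix(0L, H, W)
  if (config$background_style == "style_A") {
    # leaf-like ellipses
    for (k in seq_len(max(3, round(W * H / 4000)))) {
      cx <- runif(1, 0, W); cy <- runif(1, 0, H)
      ax <- runif(1, 4, 10); ay <- ax / runif(1, 2.2, 3.5)
      if (runif(1) < 0.5) { tmp <- ax; ax <- ay; ay <- tmp }
      col <- c(0.15, 0.42, 0.12) + rnorm(3, sd = 0.04)
      p <- paintEllipse(img, owner, 0L, cx, cy, ax, ay,
                        pmin(1, pmax(0, col)), shade = FALSE)
      img <- p$img; owner <- p$owner
    }
  } else {
    # branch-like strokes
    for (k in seq_len(max(2, round(W / 40)))) {
      x0 <- runif(1, 0, W); y0 <- runif(1, 0, H)
      ang <- runif(1, 0, pi); len <- runif(1, 0.3, 0.9) * W
      wdt <- runif(1, 1, 2.5)
      col <- c(0.30, 0.22, 0.14) + rnorm(3, sd = 0.03)
      ts <- seq(0, 1, length.out = ceiling(len))
      xs <- x0 + ts * len * cos(ang); ys <- y0 + ts * len * sin(ang)
      for (q in seq_along(ts)) {
        p <- paintEllipse(img, owner, 0L, xs[q], ys[q], wdt, wdt,
                          pmin(1, pmax(0, col)), shade = FALSE)
        img <- p$img; owner <- p$owner
      }
    }
  }
  img[] <- pmin(1, pmax(0, img))
  list(img = img, owner = owner)
}

#' Generate one synthetic orchard scene
#'
#' Renders a style-dependent background, a seeded number of shaded
#' elliptical fruits with per-fruit color jitter, and optional
#' occluding leaves. The annotation lists one amodal box per fruit
#' whose visible fraction is at least
#' \code{min_visible_fraction}; boxes are tight to the unoccluded
#' fruit extent and clipped to the image. The same (config, seed) pair
#' reproduces the scene exactly.
#'
#' @param config a [sceneConfig()].
#' @param seed integer RNG seed.
#' @return \code{list(image = (H, W, 3) array, annotation =
#'   ImageAnnotation)}.
#' @export
generateScene <- function(config = sceneConfig(), seed = 1L) {
  set.seed(seed)
  H <- config$height; W <- config$width
  bg <- paintBackground(config)
  img <- bg$img; owner <- bg$owner
  n <- if (config$fruits[1] == config$fruits[2]) config$fruits[1]
  else sample(config$fruits[1]:config$fruits[2], 1)
  fruits <- list()
  placed <- emptyBoxes()
  for (i in seq_len(n)) {
    ok <- FALSE
    # the size is drawn once per fruit; retries only move it, so
    # crowding does not skew the scale distribution of placed fruits
    sz <- sampleFruitSize(config)
    w <- min(sz["w"], W - 2); h <- min(sz["h"], H - 2)
    for (try in seq_len(25)) {
      cx <- runif(1, w / 2, W - w / 2)
      cy <- runif(1, h / 2, H - h / 2)
      cand <- boundingBox(cx - w / 2, cy - h / 2, cx + w / 2,
                          cy + h / 2)
      if (nrow(placed) == 0) { ok <- TRUE; break }
      # bound both IoU and the covered fraction of the smaller fruit,
      # so a large fruit cannot bury a small one entirely
      iw <- pmax(0, pmin(cand$x_max, placed$x_max) -
                   pmax(cand$x_min, placed$x_min))
      ih <- pmax(0, pmin(cand$y_max, placed$y_max) -
                   pmax(cand$y_min, placed$y_min))
      inter <- iw * ih
      coverFrac <- inter / pmin(boxArea(cand), boxArea(placed))
      if (max(iouMatrix(cand, placed)) < 0.35 &&
          max(coverFrac) < 0.5) { ok <- TRUE; break }
    }
    if (!ok) {
      message(sprintf(
        "scene seed %d: no feasible placement for fruit %d; %d placed",
        seed, i, length(fruits)))
      next
    }
    placed <- rbind(placed, cand)
    col <- pmin(1, pmax(0.05,
                        config$palette + rnorm(3, sd = config$color_jitter)))
    fruits[[length(fruits) + 1]] <-
      list(cx = cx, cy = cy, ax = w / 2, ay = h / 2, col = col,
           box = cand)
  }
  for (i in seq_along(fruits)) {
    f <- fruits[[i]]
    p <- paintEllipse(img, owner, i, f$cx, f$cy, f$ax, f$ay, f$col)
    img <- p$img; owner <- p$owner
  }
  # occluding leaves, drawn over fruits near their rim
  occCol <- if (config$background_style == "style_A")
    c(0.14, 0.40, 0.10) else c(0.28, 0.24, 0.12)
  for (i in seq_along(fruits)) {
    if (runif(1) >= config$occlusion_prob) next
    f <- fruits[[i]]
    frac <- runif(1, 0.1, config$max_occluded_fraction)
    oa <- f$ax * sqrt(frac) * 1.3; ob <- f$ay * sqrt(frac) * 1.3
    ang <- runif(1, 0, 2 * pi)
    p <- paintEllipse(img, owner, -1L,
                      f$cx + cos(ang) * f$ax * 0.7,
                      f$cy + sin(ang) * f$ay * 0.7,
                      oa, ob, pmin(1, pmax(0, occCol + rnorm(3, 0.02))),
                      shade = FALSE)
    img <- p$img; owner <- p$owner
  }
  boxes <- emptyBoxes()
  for (i in seq_along(fruits)) {
    f <- fruits[[i]]
    total <- pi * f$ax * f$ay
    visible <- sum(owner == i) / max(1, total)
    if (visible >= config$min_visible_fraction)
      boxes <- rbind(boxes, f$box)
  }
  ann <- imageAnnotation(sprintf("scene%09d", seed), W, H, boxes)
  list(image = img, annotation = ann)
}

#' Generate a list of scenes in memory
#'
#' @param config a [sceneConfig()].
#' @param n number of scenes.
#' @param seed base seed; scene \code{i} uses \code{seed + i}.
#' @return list of \code{list(image, annotation)} samples.
#' @export
generateSamples <- function(config, n, seed = 1L) {
  lapply(seq_len(n), function(i) generateScene(config, seed + i))
}

#' Generate a two-split benchmark with a domain gap
#'
#' Writes PNG images and COCO annotations for a training split and a
#' test split, plus a JSON manifest recording both configurations and
#' all seeds, sufficient to regenerate the dataset byte-identically.
#' The default pairing emulates the auto-labeling setting: training on
#' source-like scale statistics over background style A, testing on
#' target-like scales (including small fruits) over style B.
#'
#' @param out output directory (refused if non-empty, unless
#'   \code{overwrite}).
#' @param n_train,n_test number of images per split.
#' @param trainConfig,testConfig [sceneConfig()]s for the two splits.
#' @param seed base seed; train image i uses \code{seed + i}, test
#'   image j uses \code{seed + 100000 + j}.
#' @param overwrite allow writing into an existing non-empty
#'   directory.
#' @return invisibly, the manifest list.
#' @export
generateBenchmark <- function(out, n_train = 50, n_test = 20,
                              trainConfig = sceneConfig(
                                scale_regime = "source_like",
                                background_style = "style_A"),
                              testConfig = sceneConfig(
                                scale_regime = "target_like",
                                background_style = "style_B"),
                              seed = 1L, overwrite = FALSE) {
  if (dir.exists(out) && length(list.files(out)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", out,
         " (use overwrite = TRUE)")
  splits <- list(
    train = list(config = trainConfig, n = n_train, offset = 0L),
    test = list(config = testConfig, n = n_test, offset = 100000L))
  manifest <- list(format = "fruitpoint-benchmark", version = 1L,
                   seed = seed, splits = list())
  for (nm in names(splits)) {
    sp <- splits[[nm]]
    imgDir <- file.path(out, nm, "images")
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
    anns <- list()
    for (i in seq_len(sp$n)) {
      sc <- generateScene(sp$config, seed + sp$offset + i)
      id <- sprintf("%s%04d", nm, i)
      sc$annotation@imageId <- id
      png::writePNG(sc$image, file.path(imgDir, paste0(id, ".png")))
      anns[[id]] <- sc$annotation
    }
    writeAnnotations(anns, file.path(out, nm, "annotations.json"),
                     "coco")
    manifest$splits[[nm]] <- list(n = sp$n, seed_offset = sp$offset,
                                  config = sp$config)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load one split of a generated benchmark
#'
#' @param dir benchmark directory written by [generateBenchmark()].
#' @param split \code{"train"} or \code{"test"}.
#' @return list of \code{list(image, annotation)} samples.
#' @export
loadBenchmarkSplit <- function(dir, split = c("train", "test")) {
  split <- match.arg(split)
  anns <- readAnnotations(file.path(dir, split, "annotations.json"),
                          "coco")
  lapply(names(anns), function(id) {
    img <- png::readPNG(file.path(dir, split, "images",
                                  paste0(id, ".png")))
    if (length(dim(img)) == 2) img <- array(rep(img, 3),
                                            dim = c(dim(img), 3))
    list(image = img[, , 1:3, drop = FALSE], annotation = anns[[id]])
  })
}
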