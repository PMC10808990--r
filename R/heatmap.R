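#' @include boxes.R
NULL

#' Gaussian encoding configuration
#'
#' Controls how ground-truth centers are written into the heatmap. The
#' radius is chosen so that a box displaced by it still overlaps the
#' original at IoU \code{min_overlap} (the corner-keypoint convention);
#' the Gaussian is truncated to exact zero below \code{zero_threshold}
#' so "nonzero entry" is a well-defined notion for sample allocation.
#'
#' @param min_overlap IoU used to size the Gaussian radius (default 0.7).
#' @param zero_threshold code value below which entries are set to
#'   exactly 0 (default \code{2^-7}). Values equal to the threshold are
#'   kept, so every retained entry is a positive sample under the
#'   expanded allocation.
#' @param sigma_rule how the Gaussian width follows the radius:
#'   \code{"diameter_over_6"} (the center/corner-keypoint convention,
#'   \code{sigma = (2 r + 1)/6}; default) or \code{"radius_over_3"}
#'   (\code{sigma = r/3}, its large-radius limit, which collapses to
#'   single-pixel footprints for small fruits).
#' @return a configuration list.
#' @export
gaussianEncodingConfig <- function(min_overlap = 0.7,
                                   zero_threshold = 2^-7,
                                   sigma_rule = c("diameter_over_6",
                                                  "radius_over_3")) {
  sigma_rule <- match.arg(sigma_rule)
  if (!(min_overlap > 0 && min_overlap < 1))
    stop("min_overlap must lie in (0, 1)")
  if (!(zero_threshold > 0 && zero_threshold < 1))
    stop("zero_threshold must lie in (0, 1)")
  list(min_overlap = min_overlap, zero_threshold = zero_threshold,
       sigma_rule = sigma_rule)
}

#' Gaussian radius for a box at heatmap scale
#'
#' Largest radius such that a box whose corners are perturbed by it
#' still attains IoU \code{>= min_overlap} with the original: the
#' minimum of the three standard quadratic-root cases (both corners
#' shifted inward, both outward, one in one out). Degenerate boxes give
#' radius 0.
#'
#' @param width,height box size in heatmap pixels (\code{>= 0}).
#' @param min_overlap required IoU in (0, 1).
#' @return a non-negative radius in heatmap pixels.
#' @export
gaussianRadius <- function(width, height, min_overlap = 0.7) {
  if (!(min_overlap > 0 && min_overlap < 1))
    stop("min_overlap must lie in (0, 1)")
  stopifnot(width >= 0, height >= 0)
  if (width == 0 || height == 0) return(0)

  a1 <- 1
  b1 <- height + width
  c1 <- width * height * (1 - min_overlap) / (1 + min_overlap)
  r1 <- (b1 - sqrt(b1^2 - 4 * a1 * c1)) / (2 * a1)

  a2 <- 4
  b2 <- 2 * (height + width)
  c2 <- (1 - min_overlap) * width * height
  r2 <- (b2 - sqrt(b2^2 - 4 * a2 * c2)) / (2 * a2)

  a3 <- 4 * min_overlap
  b3 <- -2 * min_overlap * (height + width)
  c3 <- (min_overlap - 1) * width * height
  r3 <- (-b3 + sqrt(b3^2 - 4 * a3 * c3)) / (2 * a3)

  max(0, min(r1, r2, r3))
}

#' Encode ground-truth boxes into a center-point heatmap
#'
#' Each object contributes an unnormalized 2-D Gaussian with peak 1 at
#' the integer heatmap cell containing the box center, with
#' \code{sigma} tied to the overlap radius by the configured rule
#' (see [gaussianEncodingConfig()]); overlapping objects combine by
#' elementwise maximum, and entries below the zero threshold are set to
#' exactly 0. The heatmap is an \code{ceiling(H/r) x ceiling(W/r)}
#' matrix indexed \code{[row = y + 1, col = x + 1]} for heatmap pixel
#' \code{(x, y)}.
#'
#' @param annotation an [ImageAnnotation-class].
#' @param r integer downsampling factor.
#' @param config a [gaussianEncodingConfig()].
#' @return a numeric matrix with entries in \code{[0, 1]}; attribute
#'   \code{"r"} records the downsampling factor and attribute
#'   \code{"centers"} the integer (x, y) heatmap cell of each encoded
#'   object.
#' @export
encodeHeatmap <- function(annotation, r,
                          config = gaussianEncodingConfig()) {
  stopifnot(is(annotation, "ImageAnnotation"), r >= 1)
  hh <- as.integer(ceiling(annotation@height / r))
  ww <- as.integer(ceiling(annotation@width / r))
  H <- matrix(0, nrow = hh, ncol = ww)
  b <- annotation@boxes
  centers <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  for (j in seq_len(nrow(b))) {
    ctr <- boxCenter(b[j, , drop = FALSE])
    cx <- floor(ctr[1, "x"] / r)
    cy <- floor(ctr[1, "y"] / r)
    if (cx < 0 || cx >= ww || cy < 0 || cy >= hh) {
      warning(sprintf(
        "object %d center maps outside the %dx%d heatmap; skipped",
        j, ww, hh))
      next
    }
    rad <- gaussianRadius(boxWidth(b[j, , drop = FALSE]) / r,
                          boxHeight(b[j, , drop = FALSE]) / r,
                          config$min_overlap)
    centers <- rbind(centers, c(x = cx, y = cy))
    win <- as.integer(ceiling(rad * 1.5)) + 2L
    xs <- max(0, cx - win):min(ww - 1, cx + win)
    ys <- max(0, cy - win):min(hh - 1, cy + win)
    if (rad > 0) {
      sigma <- if (identical(config$sigma_rule, "radius_over_3"))
        rad / 3 else (2 * rad + 1) / 6
      g <- exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * sigma^2))
    } else {
      g <- matrix(0, length(ys), length(xs))
      g[ys == cy, xs == cx] <- 1
    }
    block <- H[ys + 1, xs + 1, drop = FALSE]
    H[ys + 1, xs + 1] <- pmax(block, g)
  }
  H[H < config$zero_threshold] <- 0
  structure(H, r = r, centers = unique(centers))
}

#' Allocate positive and negative heatmap samples
#'
#' Implements the two supervision regimes of the heatmap branch.
#' Under the \code{"original"} one-point allocation each fruit
#' contributes exactly one positive sample (its encoded center,
#' \code{H == 1}) and targets are binary. Under the \code{"expanded"}
#' allocation every nonzero-encoded pixel is a positive sample and the
#' Gaussian code itself is the supervision target, which dramatically
#' increases the number of positives per fruit.
#'
#' @param H a ground-truth heatmap (matrix in \code{[0, 1]}).
#' @param strategy \code{"expanded"} or \code{"original"}.
#' @return a list with logical matrices \code{positive_mask} and
#'   \code{negative_mask} (a partition of the grid), numeric
#'   \code{target_values}, and \code{strategy}.
#' @export
allocateSamples <- function(H, strategy = c("expanded", "original")) {
  strategy <- match.arg(strategy)
  H <- as.matrix(H)
  if (any(H < 0 | H > 1))
    stop("ground-truth heatmap values must lie in [0, 1]")
  pos <- if (strategy == "expanded") H != 0 else H == 1
  targets <- if (strategy == "expanded") H else (H == 1) * 1
  list(positive_mask = pos, negative_mask = !pos,
       target_values = targets, strategy = strategy)
}

#' Heatmap loss configuration
#'
#' @param alpha focusing exponent of the modified focal loss (default 2).
#' @param beta_focal negative-down-weighting exponent of the modified
#'   focal loss (default 4).
#' @param beta_cont modulating exponent of the continuous-label loss
#'   (default 2).
#' @param eps clamp applied to predictions before logarithms
#'   (default 1e-6).
#' @param normalization \code{"pixels"} divides by the total number of
#'   heatmap pixels (the default, literal reading of the loss
#'   normalizer N); \code{"objects"} divides by the number of encoded
#'   centers (at least 1), the convention of the original center-point
#'   detector, kept for cross-checking.
#' @return a configuration list.
#' @export
lossConfig <- function(alpha = 2, beta_focal = 4, beta_cont = 2,
                       eps = 1e-6,
                       normalization = c("pixels", "objects")) {
  stopifnot(alpha > 0, beta_focal > 0, beta_cont > 0,
            eps > 0, eps <= 1e-3)
  list(alpha = alpha, beta_focal = beta_focal, beta_cont = beta_cont,
       eps = eps, normalization = match.arg(normalization))
}

lossNormalizer <- function(gt, config) {
  if (config$normalization == "pixels") length(gt)
  else max(1, sum(gt == 1))
}

checkShapes <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt)))
    stop("prediction and ground-truth heatmaps must have the same shape")
}

#' Modified focal loss for the heatmap branch
#'
#' \deqn{L = -\frac{1}{N}\sum_{xy}
#'   \begin{cases}(1-\hat H_{xy})^\alpha \log \hat H_{xy} & H_{xy}=1\\
#'   (1-H_{xy})^\beta \hat H_{xy}^\alpha \log(1-\hat H_{xy}) &
#'   \text{otherwise}\end{cases}}
#'
#' Predictions are clamped to \code{[eps, 1-eps]} before logarithms.
#'
#' @param pred predicted heatmap (matrix in \code{[0, 1]}).
#' @param gt ground-truth heatmap of the same shape.
#' @param config a [lossConfig()].
#' @return a finite non-negative scalar.
#' @export
modifiedFocalLoss <- function(pred, gt, config = lossConfig()) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  checkShapes(pred, gt)
  p <- pmin(pmax(pred, config$eps), 1 - config$eps)
  posTerm <- (1 - p)^config$alpha * log(p)
  negTerm <- (1 - gt)^config$beta_focal * p^config$alpha * log(1 - p)
  contrib <- ifelse(gt == 1, posTerm, negTerm)
  -sum(contrib) / lossNormalizer(gt, config)
}

#' Continuous label value loss for the heatmap branch
#'
#' \deqn{L = -\frac{1}{N}\sum_{xy} |H_{xy}-\hat H_{xy}|^\beta
#'   \left[(1-H_{xy})\log(1-\hat H_{xy}) +
#'   H_{xy}\log \hat H_{xy}\right]}
#'
#' The supervision label \eqn{H_{xy}} may be any value in
#' \code{[0, 1]}, so Gaussian-coded pixels can be supervised directly
#' with their code value; supervision strength decreases with distance
#' from the object center. For binary labels the loss coincides with
#' the modified focal loss at matched exponents.
#'
#' @inheritParams modifiedFocalLoss
#' @return a finite non-negative scalar; exactly 0 iff
#'   \code{pred == gt} up to the clamp.
#' @export
continuousLabelLoss <- function(pred, gt, config = lossConfig()) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  checkShapes(pred, gt)
  p <- pmin(pmax(pred, config$eps), 1 - config$eps)
  a <- (1 - gt) * log(1 - p) + gt * log(p)
  contrib <- abs(gt - p)^config$beta_cont * a
  -sum(contrib) / lossNormalizer(gt, config)
}

#' Heatmap branch loss under a named allocation/loss pairing
#'
#' Dispatches to the configured loss after building the sample
#' allocation. The improved configuration is
#' \code{(expanded, continuous)}; the center-point baseline is
#' \code{(original, focal)}. The pairing \code{(expanded, focal)} is
#' rejected: with binary focal labels the expanded positives would be
#' indistinguishable from true center positives, defeating accurate
#' center localization.
#'
#' @inheritParams modifiedFocalLoss
#' @param strategy sample allocation, \code{"expanded"} or
#'   \code{"original"}.
#' @param loss \code{"continuous"} or \code{"focal"}.
#' @return a non-negative scalar.
#' @export
heatmapBranchLoss <- function(pred, gt,
                              strategy = c("expanded", "original"),
                              loss = c("continuous", "focal"),
                              config = lossConfig()) {
  strategy <- match.arg(strategy); loss <- match.arg(loss)
  if (strategy == "expanded" && loss == "focal")
    stop("incoherent pairing: under the expanded allocation a binary ",
         "focal label makes off-center positives indistinguishable ",
         "from center positives; use the continuous label loss")
  alloc <- allocateSamples(gt, strategy)
  if (loss == "continuous")
    continuousLabelLoss(pred, alloc$target_values, config)
  else
    modifiedFocalLoss(pred, alloc$target_values, config)
}

# dL/dpred for the two losses (already divided by N); used by the
# training loop. Gradient is zero where the clamp is active.
focalLossGrad <- function(pred, gt, config = lossConfig()) {
  p <- pmin(pmax(pred, config$eps), 1 - config$eps)
  al <- config$alpha; be <- config$beta_focal
  dpos <- al * (1 - p)^(al - 1) * log(p) - (1 - p)^al / p
  dneg <- -(1 - gt)^be * (al * p^(al - 1) * log(1 - p) - p^al / (1 - p))
  g <- ifelse(gt == 1, dpos, dneg) / lossNormalizer(gt, config)
  g[pred < config$eps | pred > 1 - config$eps] <- 0
  g
}

contLossGrad <- function(pred, gt, config = lossConfig()) {
  p <- pmin(pmax(pred, config$eps), 1 - config$eps)
  be <- config$beta_cont
  d <- gt - p
  a <- (1 - gt) * log(1 - p) + gt * log(p)
  g <- be * abs(d)^(be - 1) * sign(d) * a -
    abs(d)^be * (gt / p - (1 - gt) / (1 - p))
  g <- g / lossNormalizer(gt, config)
  g[pred < config$eps | pred > 1 - config$eps] <- 0
  g
}

#' Write a heatmap as a grayscale PNG for visual inspection
#'
#' Diagnostic helper; values are mapped linearly from \code{[0, 1]} to
#' gray levels.
#'
#' @param H heatmap matrix in \code{[0, 1]}.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeHeatmapImage <- function(H, path) {
  png::writePNG(pmin(pmax(as.matrix(H), 0), 1), path)
  invisible(path)
}
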