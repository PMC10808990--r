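#' @include heatmap.R
NULL

#' Small-object criterion
#'
#' A fruit box is "small" when its pixel area is below \code{32 x 32}
#' or the square root of its relative area ratio is below 3\%. Small
#' objects are routed to prediction layer 1 (2x downsampling), all
#' others to layer 2 (4x).
#'
#' @param boxes a box data.frame (vectorized over rows).
#' @param width,height image size in pixels (both \code{> 0}).
#' @return logical vector, one entry per box.
#' @examples
#' isSmallObject(boundingBox(0, 0, 20, 20), 640, 640)    # TRUE
#' isSmallObject(boundingBox(0, 0, 100, 100), 640, 640)  # FALSE
#' @export
isSmallObject <- function(boxes, width, height) {
  if (width <= 0 || height <= 0)
    stop("image area must be positive")
  a <- boxArea(boxes)
  a < 32 * 32 | sqrt(a / (width * height)) < 0.03
}

#' Build per-layer training targets
#'
#' Routes every ground-truth object to exactly one prediction layer by
#' the small-object criterion, encodes each layer's ground-truth
#' heatmap at its downsampling factor, and tabulates size targets
#' (box width/height in input-image pixels) and sub-pixel center
#' offsets (heatmap-cell units) at the encoded center cells. Size and
#' offset are supervised at center cells only, also under the expanded
#' heatmap allocation.
#'
#' @param annotation an [ImageAnnotation-class] (sizes must refer to
#'   the padded image fed to the model; see [padToMultiple()]).
#' @param encoding a [gaussianEncodingConfig()].
#' @param paddedSize optional \code{c(height, width)} of the padded
#'   image; defaults to the annotation's own size.
#' @return a list with one element per layer
#'   (\code{layer1}: r = 2, \code{layer2}: r = 4), each holding
#'   \code{r}, \code{heatmap}, and a \code{centers} data.frame with
#'   columns \code{cx, cy} (0-based heatmap cell), \code{w, h}
#'   (pixels) and \code{dx, dy} (offsets in \code{[0, 1)}); plus a
#'   \code{routing} integer vector (1 or 2 per object).
#' @export
buildLayerTargets <- function(annotation,
                              encoding = gaussianEncodingConfig(),
                              paddedSize = NULL) {
  stopifnot(is(annotation, "ImageAnnotation"))
  b <- annotation@boxes
  W <- annotation@width; H <- annotation@height
  if (is.null(paddedSize)) paddedSize <- c(H, W)
  small <- if (nrow(b)) isSmallObject(b, W, H) else logical(0)
  routing <- ifelse(small, 1L, 2L)
  out <- list()
  for (l in 1:2) {
    r <- if (l == 1) 2L else 4L
    sub <- b[routing == l, , drop = FALSE]
    subAnn <- imageAnnotation(annotation@imageId, paddedSize[2],
                              paddedSize[1], sub, clip = FALSE)
    hm <- encodeHeatmap(subAnn, r, encoding)
    ctr <- boxCenter(sub)
    centers <- data.frame(
      cx = floor(ctr[, "x"] / r), cy = floor(ctr[, "y"] / r),
      w = boxWidth(sub), h = boxHeight(sub),
      dx = ctr[, "x"] / r - floor(ctr[, "x"] / r),
      dy = ctr[, "y"] / r - floor(ctr[, "y"] / r))
    keep <- centers$cx >= 0 & centers$cx < ncol(hm) &
      centers$cy >= 0 & centers$cy < nrow(hm)
    out[[paste0("layer", l)]] <- list(r = r, heatmap = hm,
                                      centers = centers[keep, , drop = FALSE])
  }
  out$routing <- routing
  out
}
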