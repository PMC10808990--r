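#' @include AllClasses.R
NULL

#' Bounding-box helpers
#'
#' Boxes are rows of a data.frame with columns
#' \code{x_min, y_min, x_max, y_max} in continuous, 0-based, half-open
#' pixel coordinates: a box covers \code{[x_min, x_max) x [y_min, y_max)},
#' so its width is \code{x_max - x_min} and its center
#' \code{((x_min + x_max)/2, (y_min + y_max)/2)}.
#'
#' @param x_min,y_min,x_max,y_max numeric vectors (recycled).
#' @return \code{boundingBox()} returns a box data.frame.
#' @examples
#' b <- boundingBox(0, 0, 10, 20)
#' boxArea(b)    # 200
#' boxCenter(b)  # (5, 10)
#' @export
boundingBox <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  if (any(b$x_max < b$x_min) || any(b$y_max < b$y_min))
    stop("invalid box: x_max < x_min or y_max < y_min")
  b
}

#' @rdname boundingBox
#' @export
emptyBoxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0))
}

#' @rdname boundingBox
#' @param boxes a box data.frame.
#' @export
boxWidth <- function(boxes) boxes$x_max - boxes$x_min

#' @rdname boundingBox
#' @export
boxHeight <- function(boxes) boxes$y_max - boxes$y_min

#' @rdname boundingBox
#' @export
boxArea <- function(boxes) boxWidth(boxes) * boxHeight(boxes)

#' @rdname boundingBox
#' @export
boxCenter <- function(boxes) {
  cbind(x = (boxes$x_min + boxes$x_max) / 2,
        y = (boxes$y_min + boxes$y_max) / 2)
}

#' Clip boxes to an image extent
#'
#' Idempotent: clipping twice equals clipping once. Coordinates end up
#' in \code{[0, width] x [0, height]}.
#'
#' @param boxes box data.frame.
#' @param width,height image size in pixels.
#' @return the clipped box data.frame.
#' @export
clipBoxes <- function(boxes, width, height) {
  boxes$x_min <- pmin(pmax(boxes$x_min, 0), width)
  boxes$x_max <- pmin(pmax(boxes$x_max, 0), width)
  boxes$y_min <- pmin(pmax(boxes$y_min, 0), height)
  boxes$y_max <- pmin(pmax(boxes$y_max, 0), height)
  boxes
}

#' Intersection over union of two boxes
#'
#' @param a,b single-row box data.frames (or anything with the four
#'   coordinate columns; only the first row is used).
#' @return IoU in \code{[0, 1]}; degenerate zero-area pairs give 0.
#' @examples
#' iou(boundingBox(0, 0, 2, 2), boundingBox(1, 0, 3, 2))  # 1/3
#' @export
iou <- function(a, b) {
  iw <- max(0, min(a$x_max[1], b$x_max[1]) - max(a$x_min[1], b$x_min[1]))
  ih <- max(0, min(a$y_max[1], b$y_max[1]) - max(a$y_min[1], b$y_min[1]))
  inter <- iw * ih
  un <- boxArea(a[1, ]) + boxArea(b[1, ]) - inter
  if (un <= 0) return(0)
  inter / un
}

#' Pairwise IoU matrix
#'
#' @param a,b box data.frames with \code{nrow(a)} and \code{nrow(b)} rows.
#' @return an \code{nrow(a) x nrow(b)} matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0)
    return(matrix(0, na, nb))
  iw <- pmax(0, outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax))
  ih <- pmax(0, outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax))
  inter <- iw * ih
  un <- outer(boxArea(a), boxArea(b), `+`) - inter
  out <- ifelse(un > 0, inter / un, 0)
  matrix(out, na, nb)
}
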