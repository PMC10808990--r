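#' @include fruitpoint-package.R
NULL

#' Image annotation for single-class fruit detection
#'
#' Holds the axis-aligned fruit bounding boxes of one image. Coordinates
#' are continuous, 0-based and half-open: a box covers
#' \code{[x_min, x_max) x [y_min, y_max)} in pixel units, so
#' \code{width = x_max - x_min}. COCO \code{[x, y, w, h]} converts
#' exactly; Pascal VOC's 1-based inclusive corners are converted at the
#' file boundary (see [readAnnotations()]).
#'
#' @slot imageId character identifier (usually the image file stem).
#' @slot width,height image size in pixels.
#' @slot boxes a \code{data.frame} with numeric columns
#'   \code{x_min, y_min, x_max, y_max}, one row per fruit.
#'
#' @seealso [imageAnnotation()], [readAnnotations()], [writeAnnotations()]
#' @export
setClass("ImageAnnotation",
  representation(imageId = "character", width = "numeric",
                 height = "numeric", boxes = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (length(object@width) != 1 || object@width <= 0 ||
        length(object@height) != 1 || object@height <= 0)
      msg <- c(msg, "image width and height must be single positive numbers")
    b <- object@boxes
    need <- c("x_min", "y_min", "x_max", "y_max")
    if (!all(need %in% names(b))) {
      msg <- c(msg, "boxes must have columns x_min, y_min, x_max, y_max")
    } else if (nrow(b) > 0) {
      if (any(!is.finite(as.matrix(b[, need]))))
        msg <- c(msg, "box coordinates must be finite")
      else if (any(b$x_max < b$x_min) || any(b$y_max < b$y_min))
        msg <- c(msg, "boxes must satisfy x_max >= x_min and y_max >= y_min")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageAnnotation
#'
#' @param imageId image identifier.
#' @param width,height image size in pixels.
#' @param boxes data.frame with columns \code{x_min, y_min, x_max, y_max}
#'   (0-based half-open pixel coordinates); a zero-row data.frame is a
#'   valid empty annotation.
#' @param clip clip boxes to the image extent (default \code{TRUE}).
#' @return an [ImageAnnotation-class] object.
#' @examples
#' ann <- imageAnnotation("img1", 64, 64,
#'                        data.frame(x_min = 10, y_min = 10,
#'                                   x_max = 30, y_max = 28))
#' nBoxes(ann)
#' @export
imageAnnotation <- function(imageId, width, height,
                            boxes = emptyBoxes(), clip = TRUE) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) == 0) boxes <- emptyBoxes()
  if (clip && nrow(boxes) > 0)
    boxes <- clipBoxes(boxes, width, height)
  keep <- intersect(c("x_min", "y_min", "x_max", "y_max", "score"),
                    names(boxes))
  boxes <- boxes[, keep, drop = FALSE]
  rownames(boxes) <- NULL
  new("ImageAnnotation", imageId = as.character(imageId),
      width = as.numeric(width), height = as.numeric(height),
      boxes = boxes)
}

#' @describeIn ImageAnnotation-class image identifier accessor
#' @param object,x an \code{ImageAnnotation}
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("imageId", "ImageAnnotation", function(x) x@imageId)

#' @describeIn ImageAnnotation-class \code{c(width, height)} in pixels
#' @export
setGeneric("imageSize", function(x) standardGeneric("imageSize"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("imageSize", "ImageAnnotation",
          function(x) c(width = x@width, height = x@height))

#' @describeIn ImageAnnotation-class bounding-box data.frame accessor
#' @export
setGeneric("annotationBoxes", function(x) standardGeneric("annotationBoxes"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("annotationBoxes", "ImageAnnotation", function(x) x@boxes)

#' @describeIn ImageAnnotation-class number of annotated fruits
#' @export
setGeneric("nBoxes", function(x) standardGeneric("nBoxes"))

#' @rdname ImageAnnotation-class
#' @export
setMethod("nBoxes", "ImageAnnotation", function(x) nrow(x@boxes))

#' @exportMethod show
setMethod("show", "ImageAnnotation", function(object) {
  cat(sprintf("ImageAnnotation '%s' (%g x %g px): %d fruit box(es)\n",
              object@imageId, object@width, object@height,
              nrow(object@boxes)))
  if (nrow(object@boxes) > 0) {
    print(head(object@boxes, 5))
    if (nrow(object@boxes) > 5)
      cat(sprintf("... and %d more\n", nrow(object@boxes) - 5))
  }
})

#' Detection evaluation summary
#'
#' Precision, recall and F1 are reported at the balance point, the
#' confidence threshold where precision is approximately equal to
#' recall. AP is the area under the all-point interpolated
#' precision-recall curve and does not depend on the balance threshold.
#'
#' @slot precision,recall,f1,ap ratios in \code{[0, 1]}.
#' @slot balanceThreshold confidence threshold realizing the balance point.
#' @slot iouThreshold IoU used for detection-to-truth matching.
#' @slot prCurve data.frame with columns
#'   \code{threshold, precision, recall, f1}.
#' @export
setClass("EvalResult",
  representation(precision = "numeric", recall = "numeric",
                 f1 = "numeric", ap = "numeric",
                 balanceThreshold = "numeric", iouThreshold = "numeric",
                 prCurve = "data.frame"),
  validity = function(object) {
    vals <- c(object@precision, object@recall, object@f1, object@ap)
    if (any(vals < -1e-9 | vals > 1 + 1e-9))
      "precision, recall, f1 and ap must lie in [0, 1]" else TRUE
  })

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult (balance point)\n")
  cat(sprintf("  precision: %.4f  recall: %.4f  F1: %.4f  AP: %.4f\n",
              object@precision, object@recall, object@f1, object@ap))
  cat(sprintf("  balance threshold: %.4f  (IoU %.2f, %d curve points)\n",
              object@balanceThreshold, object@iouThreshold,
              nrow(object@prCurve)))
})

#' Trained center-point fruit detector
#'
#' Bundles the network weights with the model configuration (backbone
#' channel widths, neck width, neck variant, head width). Weights live
#' in a flat named list of numeric arrays; [saveDetector()] and
#' [loadDetector()] serialize the pair as a versioned checkpoint.
#'
#' @slot config model configuration list (see [modelConfig()]).
#' @slot params named list of weight arrays.
#' @export
setClass("FruitDetector",
  representation(config = "list", params = "list"))

setMethod("show", "FruitDetector", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "FruitDetector: neck '%s', neck width %d, %d parameters\n",
    object@config$neck, object@config$neck_channels, np))
  cat(sprintf("  backbone channels: %s\n",
              paste(object@config$backbone_channels, collapse = ", ")))
})

#' @describeIn FruitDetector-class total number of trainable parameters
#' @param x a \code{FruitDetector}
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))

#' @rdname FruitDetector-class
#' @export
setMethod("nParameters", "FruitDetector",
          function(x) sum(vapply(x@params, length, integer(1))))

#' @describeIn FruitDetector-class model configuration accessor
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname FruitDetector-class
#' @export
setMethod("modelConfigOf", "FruitDetector", function(x) x@config)
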