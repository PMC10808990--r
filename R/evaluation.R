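#' @include boxes.R inference.R
NULL

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending score order: each detection
#' claims the unmatched ground-truth box of highest IoU and is a true
#' positive iff that IoU reaches the threshold.
#'
#' @param dets detection data.frame sorted by descending score (it is
#'   re-sorted defensively).
#' @param gts ground-truth box data.frame.
#' @param iou_threshold matching IoU (default 0.5).
#' @return a list: logical \code{tp} per detection (in the sorted
#'   order), the sorted detections, and \code{unmatched_gt}.
#' @export
matchDetections <- function(dets, gts, iou_threshold = 0.5) {
  if (nrow(dets) > 0) {
    dets <- dets[order(dets$score, decreasing = TRUE), , drop = FALSE]
    rownames(dets) <- NULL
  }
  tp <- logical(nrow(dets))
  taken <- logical(nrow(gts))
  if (nrow(dets) > 0 && nrow(gts) > 0) {
    M <- iouMatrix(dets, gts)
    for (i in seq_len(nrow(dets))) {
      free <- which(!taken)
      if (length(free) == 0) break
      j <- free[which.max(M[i, free])]
      if (M[i, j] >= iou_threshold) {
        tp[i] <- TRUE
        taken[j] <- TRUE
      }
    }
  }
  list(tp = tp, detections = dets, unmatched_gt = sum(!taken))
}

# Pool matching across images: returns scores + tp flags + total GT.
poolMatches <- function(detsByImage, gtsByImage, iou_threshold) {
  ids <- names(gtsByImage)
  scores <- numeric(0); tp <- logical(0); nGt <- 0L
  for (id in ids) {
    g <- gtsByImage[[id]]
    if (is(g, "ImageAnnotation")) g <- annotationBoxes(g)
    d <- detsByImage[[id]]
    if (is.null(d)) d <- emptyDetections()
    m <- matchDetections(d, g, iou_threshold)
    scores <- c(scores, m$detections$score)
    tp <- c(tp, m$tp)
    nGt <- nGt + nrow(g)
  }
  list(scores = scores, tp = tp, n_gt = nGt)
}

#' Average precision over a test set
#'
#' Detections are matched per image, pooled, and ranked globally by
#' score; AP is the area under the all-point interpolated
#' precision-recall curve (the precision envelope). Optionally the
#' 11-point interpolation is available for cross-checking.
#'
#' @param detsByImage named list of detection data.frames.
#' @param gtsByImage named list of [ImageAnnotation-class] objects or
#'   box data.frames; its names define the image set.
#' @param iou_threshold matching IoU (default 0.5).
#' @param interpolation \code{"all_point"} (default) or
#'   \code{"eleven_point"}.
#' @return AP in \code{[0, 1]}.
#' @export
averagePrecision <- function(detsByImage, gtsByImage,
                             iou_threshold = 0.5,
                             interpolation = c("all_point",
                                               "eleven_point")) {
  interpolation <- match.arg(interpolation)
  pm <- poolMatches(detsByImage, gtsByImage, iou_threshold)
  if (pm$n_gt == 0)
    stop("average precision is undefined with zero ground-truth boxes")
  if (length(pm$scores) == 0) return(0)
  ord <- order(pm$scores, decreasing = TRUE)
  tp <- pm$tp[ord]
  cumTp <- cumsum(tp); cumFp <- cumsum(!tp)
  prec <- cumTp / (cumTp + cumFp)
  rec <- cumTp / pm$n_gt
  if (interpolation == "all_point") {
    env <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * env)
  } else {
    mean(vapply(seq(0, 1, by = 0.1), function(rt) {
      ok <- rec >= rt
      if (any(ok)) max(prec[ok]) else 0
    }, numeric(1)))
  }
}

#' Precision-recall curve over score thresholds
#'
#' One row per candidate threshold (the unique detection scores);
#' precision, recall and F1 are computed from the pooled
#' cross-image matching.
#'
#' @inheritParams averagePrecision
#' @return data.frame with columns \code{threshold, precision, recall,
#'   f1}.
#' @export
prCurve <- function(detsByImage, gtsByImage, iou_threshold = 0.5) {
  pm <- poolMatches(detsByImage, gtsByImage, iou_threshold)
  if (length(pm$scores) == 0)
    return(data.frame(threshold = numeric(0), precision = numeric(0),
                      recall = numeric(0), f1 = numeric(0)))
  ord <- order(pm$scores, decreasing = TRUE)
  scores <- pm$scores[ord]; tp <- pm$tp[ord]
  thresholds <- sort(unique(scores), decreasing = TRUE)
  rows <- lapply(thresholds, function(th) {
    sel <- scores >= th
    nTp <- sum(tp[sel]); nDet <- sum(sel)
    p <- if (nDet > 0) nTp / nDet else 0
    r <- if (pm$n_gt > 0) nTp / pm$n_gt else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(threshold = th, precision = p, recall = r, f1 = f1)
  })
  do.call(rbind, rows)
}

#' Balance point of a precision-recall curve
#'
#' The confidence threshold where precision is approximately equal to
#' recall: the row minimizing \code{|P - R|}, ties broken by higher F1
#' and then by lower threshold.
#'
#' @param curve a data.frame from [prCurve()].
#' @return a one-row data.frame \code{(threshold, precision, recall,
#'   f1)}.
#' @export
balancePoint <- function(curve) {
  if (nrow(curve) == 0)
    return(data.frame(threshold = NA_real_, precision = 0,
                      recall = 0, f1 = 0))
  gap <- abs(curve$precision - curve$recall)
  ord <- order(gap, -curve$f1, curve$threshold)
  curve[ord[1], c("threshold", "precision", "recall", "f1"),
        drop = FALSE]
}

#' End-to-end evaluation
#'
#' Computes the balance-point precision, recall and F1 together with
#' AP at the configured matching IoU. Accepts either in-memory
#' detections, a detector (inference is run on the supplied images),
#' or exported annotation files (auditing pseudo-labels; their
#' \code{score} column supplies the ranking).
#'
#' @param detections one of: a named list of detection data.frames; a
#'   [FruitDetector-class] (then \code{images} must be given); or a
#'   path to an exported annotation file/directory (then
#'   \code{dialect} applies).
#' @param groundTruth named list of [ImageAnnotation-class] objects,
#'   or a path readable by [readAnnotations()].
#' @param images named list of image arrays (only when
#'   \code{detections} is a detector).
#' @param iou_threshold matching IoU (default 0.5).
#' @param dialect annotation dialect for file input.
#' @param config a [decodeConfig()] (detector input only); the default
#'   lowers the score floor to 0.05 so AP is computed over the full
#'   ranked detection list rather than the export threshold.
#' @return an [EvalResult-class].
#' @export
evaluateDetections <- function(detections, groundTruth, images = NULL,
                               iou_threshold = 0.5,
                               dialect = c("coco", "voc"),
                               config = decodeConfig(score_threshold = 0.05)) {
  dialect <- match.arg(dialect)
  if (is.character(groundTruth))
    groundTruth <- readAnnotations(groundTruth, dialect)
  if (length(groundTruth) == 0) stop("empty test set")
  if (is(detections, "FruitDetector")) {
    stopifnot(!is.null(images))
    detections <- lapply(images, function(img)
      detectImage(detections, img, config))
    names(detections) <- names(images)
  } else if (is.character(detections)) {
    anns <- readAnnotations(detections, dialect)
    detections <- lapply(anns, function(a) {
      b <- annotationBoxes(a)
      if (is.null(b$score)) b$score <- rep(1, nrow(b))
      b
    })
  }
  curve <- prCurve(detections, groundTruth, iou_threshold)
  bp <- balancePoint(curve)
  ap <- averagePrecision(detections, groundTruth, iou_threshold)
  new("EvalResult",
      precision = bp$precision, recall = bp$recall, f1 = bp$f1,
      ap = ap,
      balanceThreshold = if (is.na(bp$threshold)) 0 else bp$threshold,
      iouThreshold = iou_threshold, prCurve = curve)
}
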