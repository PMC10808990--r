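#' @include model.R targets.R annotations-io.R
NULL

#' Decoding configuration
#'
#' @param top_k maximum number of peaks kept per prediction layer.
#' @param score_threshold minimum heatmap confidence for a detection.
#' @param peak_window local-maximum neighborhood side (odd; default 3).
#' @param cross_layer_nms_iou IoU above which duplicate detections from
#'   the two layers are collapsed, keeping the higher score; set to 1
#'   to disable suppression.
#' @return a configuration list.
#' @export
decodeConfig <- function(top_k = 100, score_threshold = 0.3,
                         peak_window = 3, cross_layer_nms_iou = 0.5) {
  stopifnot(top_k >= 1, score_threshold >= 0, score_threshold <= 1,
            peak_window >= 1, peak_window %% 2 == 1,
            cross_layer_nms_iou >= 0, cross_layer_nms_iou <= 1)
  list(top_k = as.integer(top_k), score_threshold = score_threshold,
       peak_window = as.integer(peak_window),
       cross_layer_nms_iou = cross_layer_nms_iou)
}

emptyDetections <- function() {
  cbind(emptyBoxes(),
        data.frame(score = numeric(0), source_layer = integer(0)))
}

# Sliding-window maximum with -Inf padding.
maxFilter <- function(m, window) {
  half <- (window - 1L) %/% 2L
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dj in -half:half) for (di in -half:half) {
    if (di == 0 && dj == 0) next
    sh <- matrix(-Inf, nr, nc)
    ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- cj >= 1 & cj <= nc
    sh[ok_r, ok_c] <- m[ri[ok_r], cj[ok_c]]
    out <- pmax(out, sh)
  }
  out
}

#' Decode one prediction layer into scored boxes
#'
#' Peaks are heatmap pixels equal to their local-window maximum with
#' score at or above the threshold; the top-k peaks become detections
#' with center \code{((x + dx) * r, (y + dy) * r)} from the offset map
#' and box size from the size map, clipped to the image. The score is
#' the raw heatmap value.
#'
#' @param outputs one layer of [detectorOutputs()] (fields \code{hm},
#'   \code{size}, \code{off}).
#' @param r downsampling factor of the layer.
#' @param config a [decodeConfig()].
#' @param imageSize \code{c(width, height)} to clip boxes to; defaults
#'   to the heatmap extent times \code{r}.
#' @return a detection data.frame with columns \code{x_min, y_min,
#'   x_max, y_max, score, source_layer}.
#' @export
decodeLayer <- function(outputs, r = outputs$r,
                        config = decodeConfig(), imageSize = NULL) {
  hm <- as.matrix(outputs$hm)
  if (is.null(imageSize))
    imageSize <- c(ncol(hm) * r, nrow(hm) * r)
  peaks <- hm == maxFilter(hm, config$peak_window) &
    hm >= config$score_threshold
  idx <- which(peaks, arr.ind = TRUE)
  if (nrow(idx) == 0) return(emptyDetections())
  scores <- hm[idx]
  ord <- order(scores, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), config$top_k))]
  idx <- idx[ord, , drop = FALSE]; scores <- scores[ord]
  cy <- idx[, 1] - 1; cx <- idx[, 2] - 1
  dx <- outputs$off[cbind(idx[, 1], idx[, 2], 1)]
  dy <- outputs$off[cbind(idx[, 1], idx[, 2], 2)]
  w <- outputs$size[cbind(idx[, 1], idx[, 2], 1)]
  h <- outputs$size[cbind(idx[, 1], idx[, 2], 2)]
  xc <- (cx + dx) * r; yc <- (cy + dy) * r
  box <- data.frame(x_min = xc - w / 2, y_min = yc - h / 2,
                    x_max = xc + w / 2, y_max = yc + h / 2)
  box$x_max <- pmax(box$x_max, box$x_min)
  box$y_max <- pmax(box$y_max, box$y_min)
  box <- clipBoxes(box, imageSize[1], imageSize[2])
  layer <- if (r == 2) 1L else 2L
  cbind(box, data.frame(score = scores,
                        source_layer = rep(layer, nrow(box))))
}

#' Merge detections from the two prediction layers
#'
#' Union of both lists with greedy IoU suppression: walking the pooled
#' list in descending score order, a detection is dropped when it
#' overlaps an already-kept detection with IoU strictly above
#' \code{cross_layer_nms_iou}. Never increases the number of
#' detections; detections without an overlapping partner are always
#' kept.
#'
#' @param dets1,dets2 detection data.frames (from [decodeLayer()]).
#' @param config a [decodeConfig()].
#' @return merged detection data.frame, sorted by descending score.
#' @export
mergeLayers <- function(dets1, dets2, config = decodeConfig()) {
  all <- rbind(dets1, dets2)
  if (nrow(all) == 0) return(emptyDetections())
  all <- all[order(all$score, decreasing = TRUE), , drop = FALSE]
  rownames(all) <- NULL
  keep <- logical(nrow(all))
  for (i in seq_len(nrow(all))) {
    kept <- which(keep)
    if (length(kept) == 0) { keep[i] <- TRUE; next }
    ious <- iouMatrix(all[i, , drop = FALSE],
                      all[kept, , drop = FALSE])
    keep[i] <- all(ious <= config$cross_layer_nms_iou)
  }
  out <- all[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect fruits in one image
#'
#' Runs the model, decodes each prediction layer at its own
#' downsampling factor, clips to the un-padded image extent, and
#' merges layers.
#'
#' @param detector a [FruitDetector-class].
#' @param image \code{(H, W, 3)} array in \code{[0, 1]}.
#' @param config a [decodeConfig()].
#' @return a detection data.frame.
#' @export
detectImage <- function(detector, image, config = decodeConfig()) {
  outs <- detectorOutputs(detector, image)
  orig <- attr(outs, "orig")
  dets <- lapply(outs, function(o)
    decodeLayer(o, o$r, config, imageSize = c(orig[2], orig[1])))
  if (length(dets) == 1) return(dets[[1]])
  mergeLayers(dets$layer1, dets$layer2, config)
}

#' Export pseudo-labels for unlabeled images
#'
#' Runs detection on every image and writes the resulting boxes as
#' annotation files, the auto-labeling step of the pipeline. A plug-in
#' \code{hook} may filter or rewrite the detections of each image
#' before export (e.g. an external pseudo-label refinement strategy);
#' it receives \code{(imageId, detections)} and must return a
#' detection data.frame. Zero-area detections are dropped before
#' writing.
#'
#' @param images character vector of PNG file paths, or a named list of
#'   \code{(H, W, 3)} arrays.
#' @param detector a [FruitDetector-class] or a checkpoint path.
#' @param path output file (COCO) or directory (VOC).
#' @param dialect \code{"coco"} or \code{"voc"}.
#' @param config a [decodeConfig()].
#' @param hook optional \code{function(imageId, detections)}.
#' @return invisibly, a summary list: images processed and skipped,
#'   boxes written, and a five-number summary of scores.
#' @export
exportPseudoLabels <- function(images, detector, path,
                               dialect = c("coco", "voc"),
                               config = decodeConfig(), hook = NULL) {
  dialect <- match.arg(dialect)
  if (is.character(detector) && length(detector) == 1)
    detector <- loadDetector(detector)
  anns <- list(); skipped <- 0L; allScores <- numeric(0)
  ids <- if (is.character(images))
    sub("\\.[A-Za-z]+$", "", basename(images)) else names(images)
  if (is.null(ids)) ids <- sprintf("image%03d", seq_along(images))
  for (i in seq_along(images)) {
    img <- if (is.character(images)) {
      tryCatch(png::readPNG(images[[i]]), error = function(e) NULL)
    } else images[[i]]
    if (is.null(img)) {
      message("skipping unreadable image: ", images[[i]])
      skipped <- skipped + 1L
      next
    }
    if (length(dim(img)) == 3 && dim(img)[3] > 3)
      img <- img[, , 1:3, drop = FALSE]
    dets <- detectImage(detector, img, config)
    if (!is.null(hook)) dets <- hook(ids[[i]], dets)
    # degenerate zero-area boxes are useless as labels
    dets <- dets[boxArea(dets) > 0, , drop = FALSE]
    allScores <- c(allScores, dets$score)
    anns[[ids[[i]]]] <- imageAnnotation(ids[[i]], dim(img)[2],
                                        dim(img)[1], dets)
  }
  writeAnnotations(anns, path, dialect)
  invisible(list(images = length(anns), skipped = skipped,
                 boxes = length(allScores),
                 score_summary = if (length(allScores))
                   summary(allScores) else NULL))
}
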