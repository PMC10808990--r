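#' @include boxes.R
NULL

# Internal 0-based half-open convention:
#   COCO [x, y, w, h]            -> [x, y, x + w, y + h]        (exact)
#   VOC 1-based inclusive corners -> [xmin - 1, ymin - 1, xmax, ymax]

#' Read object-detection annotations
#'
#' Reads COCO JSON (one file, many images) or Pascal VOC XML (one file
#' per image; \code{path} may be a single \code{.xml} file or a
#' directory of them). Boxes are converted to the package's 0-based
#' half-open pixel convention. Degenerate zero-area ground-truth boxes
#' are dropped with a warning rather than silently kept.
#'
#' @param path file (COCO, or one VOC file) or directory (VOC).
#' @param dialect \code{"coco"} or \code{"voc"}.
#' @return a named list of [ImageAnnotation-class] objects.
#' @seealso [writeAnnotations()]
#' @export
readAnnotations <- function(path, dialect = c("coco", "voc")) {
  dialect <- match.arg(dialect)
  if (dialect == "coco") readCoco(path) else readVoc(path)
}

#' Write object-detection annotations
#'
#' Inverse of [readAnnotations()]: COCO writes a single JSON file, VOC
#' writes one XML file per image into the directory \code{path} (or to
#' \code{path} itself if it ends in \code{.xml} and a single annotation
#' is given). Round-tripping through either dialect reproduces the box
#' list (COCO exactly up to float round-off; VOC after the 1-based
#' conversion).
#'
#' @param annotations a list of [ImageAnnotation-class] objects (a bare
#'   \code{ImageAnnotation} is accepted).
#' @param path output file (COCO) or directory (VOC).
#' @param dialect \code{"coco"} or \code{"voc"}.
#' @return \code{path}, invisibly.
#' @export
writeAnnotations <- function(annotations, path,
                             dialect = c("coco", "voc")) {
  dialect <- match.arg(dialect)
  if (is(annotations, "ImageAnnotation")) annotations <- list(annotations)
  stopifnot(all(vapply(annotations, is, logical(1), "ImageAnnotation")))
  if (dialect == "coco") writeCoco(annotations, path)
  else writeVoc(annotations, path)
  invisible(path)
}

dropDegenerate <- function(boxes, where) {
  if (nrow(boxes) == 0) return(boxes)
  bad <- boxArea(boxes) <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d degenerate zero-area box(es) in %s",
                    sum(bad), where))
    boxes <- boxes[!bad, , drop = FALSE]
    rownames(boxes) <- NULL
  }
  boxes
}

readCoco <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed COCO JSON in '", path, "': ",
                         conditionMessage(e)))
  for (field in c("images", "annotations"))
    if (is.null(doc[[field]]))
      stop("malformed COCO file '", path, "': missing '", field, "' array")
  anns <- list()
  byImage <- split(doc$annotations,
                   vapply(doc$annotations, function(a) {
                     if (is.null(a$image_id) || is.null(a$bbox))
                       stop("malformed COCO annotation record (id ",
                            if (!is.null(a$id)) a$id else "?",
                            "): needs image_id and bbox")
                     as.character(a$image_id)
                   }, character(1)))
  for (img in doc$images) {
    if (is.null(img$id) || is.null(img$width) || is.null(img$height))
      stop("malformed COCO image record: needs id, width, height")
    recs <- byImage[[as.character(img$id)]]
    boxes <- if (length(recs)) {
      do.call(rbind, lapply(recs, function(a) {
        bb <- as.numeric(a$bbox)
        if (length(bb) != 4 || any(!is.finite(bb)))
          stop("malformed bbox in COCO annotation id ",
               if (!is.null(a$id)) a$id else "?")
        data.frame(x_min = bb[1], y_min = bb[2],
                   x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
                   score = if (!is.null(a$score))
                     as.numeric(a$score) else NA_real_)
      }))
    } else emptyBoxes()
    if (!is.null(boxes$score) && all(is.na(boxes$score)))
      boxes$score <- NULL
    id <- if (!is.null(img$file_name))
      sub("\\.[A-Za-z]+$", "", basename(img$file_name))
    else as.character(img$id)
    boxes <- dropDegenerate(boxes, sprintf("image '%s'", id))
    anns[[id]] <- imageAnnotation(id, img$width, img$height, boxes)
  }
  anns
}

writeCoco <- function(annotations, path) {
  images <- list(); records <- list(); aid <- 0L
  for (i in seq_along(annotations)) {
    ann <- annotations[[i]]
    images[[i]] <- list(id = i, file_name = paste0(imageId(ann), ".png"),
                        width = ann@width, height = ann@height)
    b <- ann@boxes
    for (j in seq_len(nrow(b))) {
      aid <- aid + 1L
      rec <- list(id = aid, image_id = i, category_id = 1L,
                  bbox = c(b$x_min[j], b$y_min[j],
                           b$x_max[j] - b$x_min[j],
                           b$y_max[j] - b$y_min[j]),
                  area = (b$x_max[j] - b$x_min[j]) *
                         (b$y_max[j] - b$y_min[j]),
                  iscrowd = 0L)
      if (!is.null(b$score)) rec$score <- b$score[j]
      records[[aid]] <- rec
    }
  }
  doc <- list(images = images, annotations = records,
              categories = list(list(id = 1L, name = "fruit",
                                     supercategory = "none")))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
}

readVocFile <- function(file) {
  doc <- tryCatch(xml2::read_xml(file),
                  error = function(e)
                    stop("malformed VOC XML '", file, "': ",
                         conditionMessage(e)))
  sz <- xml2::xml_find_first(doc, ".//size")
  if (inherits(sz, "xml_missing"))
    stop("malformed VOC XML '", file, "': missing <size>")
  W <- as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./width")))
  H <- as.numeric(xml2::xml_text(xml2::xml_find_first(sz, "./height")))
  objs <- xml2::xml_find_all(doc, ".//object")
  boxes <- if (length(objs)) {
    do.call(rbind, lapply(objs, function(o) {
      bb <- xml2::xml_find_first(o, "./bndbox")
      val <- function(tag) {
        node <- xml2::xml_find_first(bb, paste0("./", tag))
        v <- suppressWarnings(as.numeric(xml2::xml_text(node)))
        if (is.na(v))
          stop("malformed <bndbox> in '", file, "': bad or missing <",
               tag, ">")
        v
      }
      sc <- xml2::xml_find_first(bb, "./score")
      # VOC is 1-based inclusive; our convention is 0-based half-open
      data.frame(x_min = val("xmin") - 1, y_min = val("ymin") - 1,
                 x_max = val("xmax"), y_max = val("ymax"),
                 score = if (inherits(sc, "xml_missing")) NA_real_
                 else as.numeric(xml2::xml_text(sc)))
    }))
  } else emptyBoxes()
  if (!is.null(boxes$score) && all(is.na(boxes$score)))
    boxes$score <- NULL
  fname <- xml2::xml_text(xml2::xml_find_first(doc, ".//filename"))
  id <- if (!is.na(fname) && nzchar(fname))
    sub("\\.[A-Za-z]+$", "", basename(fname))
  else sub("\\.xml$", "", basename(file))
  boxes <- dropDegenerate(boxes, sprintf("'%s'", file))
  imageAnnotation(id, W, H, boxes)
}

readVoc <- function(path) {
  files <- if (dir.exists(path))
    list.files(path, pattern = "\\.xml$", full.names = TRUE)
  else path
  if (length(files) == 0) stop("no VOC XML files found under ", path)
  anns <- lapply(sort(files), readVocFile)
  setNames(anns, vapply(anns, imageId, character(1)))
}

writeVoc <- function(annotations, path) {
  single <- length(annotations) == 1 && grepl("\\.xml$", path)
  if (!single && !dir.exists(path))
    dir.create(path, recursive = TRUE)
  for (ann in annotations) {
    doc <- xml2::xml_new_root("annotation")
    xml2::xml_add_child(doc, "filename", paste0(imageId(ann), ".png"))
    sz <- xml2::xml_add_child(doc, "size")
    xml2::xml_add_child(sz, "width", format(ann@width, digits = 12))
    xml2::xml_add_child(sz, "height", format(ann@height, digits = 12))
    xml2::xml_add_child(sz, "depth", "3")
    b <- ann@boxes
    for (j in seq_len(nrow(b))) {
      obj <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(obj, "name", "fruit")
      xml2::xml_add_child(obj, "difficult", "0")
      bb <- xml2::xml_add_child(obj, "bndbox")
      fmt <- function(v) format(v, digits = 12)
      xml2::xml_add_child(bb, "xmin", fmt(b$x_min[j] + 1))
      xml2::xml_add_child(bb, "ymin", fmt(b$y_min[j] + 1))
      xml2::xml_add_child(bb, "xmax", fmt(b$x_max[j]))
      xml2::xml_add_child(bb, "ymax", fmt(b$y_max[j]))
      if (!is.null(b$score))
        xml2::xml_add_child(bb, "score", fmt(b$score[j]))
    }
    out <- if (single) path
    else file.path(path, paste0(imageId(ann), ".xml"))
    xml2::write_xml(doc, out)
  }
}
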