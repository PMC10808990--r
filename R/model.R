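#' @include nn.R AllClasses.R
NULL

#' Model configuration
#'
#' Describes the detector architecture. The backbone is a plain
#' strided-convolution pyramid (the reference architecture of the
#' center-point lineage is not mandated here; channel widths and depth
#' are configuration, not constants). The neck's \code{DC} fusion
#' operator is realized as a 3x3 convolution + ReLU and \code{DU} as
#' the same followed by 2x bilinear upsampling; \code{fusion_op}
#' records this realization in checkpoints.
#'
#' @param backbone_channels channel widths at downsampling factors
#'   2, 4, 8, 16 (a fifth entry is derived for the factor-32 level used
#'   by the original single-layer neck).
#' @param backbone_depth number of stride-1 refinement convolutions per
#'   level (default 1).
#' @param neck_channels shared channel width of all fusion nodes; the
#'   backbone map at each factor is brought to this width by a 1x1
#'   projection before fusion.
#' @param head_channels hidden width of the three prediction branches.
#' @param neck \code{"cropped_double"} (deep-to-shallow iterative
#'   fusion, prediction layers at 2x and 4x) or
#'   \code{"original_single"} (shallow-to-deep baseline, single 4x
#'   prediction layer).
#' @param fusion_op fusion-operator realization; only
#'   \code{"conv3x3"} (plain convolution) is available.
#' @return a validated configuration list.
#' @export
modelConfig <- function(backbone_channels = c(8, 16, 24, 32),
                        backbone_depth = 1,
                        neck_channels = 16,
                        head_channels = 16,
                        neck = c("cropped_double", "original_single"),
                        fusion_op = "conv3x3") {
  neck <- match.arg(neck)
  stopifnot(length(backbone_channels) == 4, all(backbone_channels >= 1),
            backbone_depth >= 0, neck_channels >= 1, head_channels >= 1)
  if (!identical(fusion_op, "conv3x3"))
    stop("unsupported fusion_op: ", fusion_op)
  list(backbone_channels = as.integer(backbone_channels),
       backbone_depth = as.integer(backbone_depth),
       neck_channels = as.integer(neck_channels),
       head_channels = as.integer(head_channels),
       neck = neck, fusion_op = fusion_op)
}

#' A deliberately small configuration for desk-scale experiments
#'
#' @param neck neck variant, as in [modelConfig()].
#' @return a [modelConfig()] list.
#' @export
tinyModelConfig <- function(neck = "cropped_double") {
  modelConfig(backbone_channels = c(8, 16, 24, 32), backbone_depth = 1,
              neck_channels = 16, head_channels = 16, neck = neck)
}

# Fusion nodes of the cropped (deep-to-shallow) neck, in dependency
# order. Node (m, n) fuses parents (m, n-1) and (2m, n-1); the valid
# index set is m=16:n=0 (projection only), m=8:n<=1, m=4:n<=2, m=2:n<=3.
croppedNeckNodes <- function() {
  list(list(m = 8, n = 1), list(m = 4, n = 1), list(m = 2, n = 1),
       list(m = 4, n = 2), list(m = 2, n = 2), list(m = 2, n = 3))
}

#' Fusion graph of a neck variant
#'
#' Returns the directed fusion edges for structural inspection: each
#' row is one edge from a source node \code{(from_m, from_n)} into a
#' fusion node \code{(to_m, to_n)} via operator \code{DC} (same
#' resolution) or \code{DU} (from the deeper, lower-resolution parent).
#'
#' @param neck \code{"cropped_double"} or \code{"original_single"}.
#' @return a data.frame of edges.
#' @examples
#' g <- neckGraph("cropped_double")
#' nrow(unique(g[, c("to_m", "to_n")]))  # 6 fusion nodes
#' @export
neckGraph <- function(neck = c("cropped_double", "original_single")) {
  neck <- match.arg(neck)
  if (neck == "cropped_double") {
    do.call(rbind, lapply(croppedNeckNodes(), function(nd) {
      data.frame(from_m = c(nd$m, 2 * nd$m), from_n = nd$n - 1,
                 to_m = nd$m, to_n = nd$n, op = c("DC", "DU"))
    }))
  } else {
    # F_n^4 = DC(F_{n-1}^4) + DU(O^{2^(n+2)}), n = 1..3
    do.call(rbind, lapply(1:3, function(n) {
      data.frame(from_m = c(4, 2^(n + 2)), from_n = c(n - 1, 0),
                 to_m = 4, to_n = n, op = c("DC", "DU"))
    }))
  }
}

backboneFactors <- function(config)
  if (config$neck == "cropped_double") c(2, 4, 8, 16) else c(4, 8, 16, 32)

# Channel width of the backbone map at a given downsampling factor.
levelChannels <- function(config, m) {
  ch <- c(config$backbone_channels,
          config$backbone_channels[4])  # factor 32 reuses the deepest width
  ch[as.integer(log2(m))]
}

#' Initialize a detector with random weights
#'
#' Weights use He-normal initialization; the final heatmap-branch bias
#' is set to \code{-2.19} so the initial foreground probability is
#' about 0.1, which stabilizes the first epochs of the focal-family
#' losses.
#'
#' @param config a [modelConfig()].
#' @param seed optional RNG seed for reproducible initialization.
#' @return a [FruitDetector-class].
#' @export
buildDetector <- function(config = tinyModelConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- list()
  nLevels <- if (config$neck == "cropped_double") 4L else 5L
  cin <- 3L
  for (lvl in seq_len(nLevels)) {
    cout <- levelChannels(config, 2^lvl)
    p <- initConv(p, paste0("bb", lvl), 3, cin, cout)
    for (d in seq_len(config$backbone_depth))
      p <- initConv(p, paste0("bb", lvl, "r", d), 3, cout, cout)
    cin <- cout
  }
  nc <- config$neck_channels
  for (m in backboneFactors(config))
    p <- initConv(p, paste0("proj", m), 1, levelChannels(config, m), nc)
  if (config$neck == "cropped_double") {
    for (nd in croppedNeckNodes()) {
      p <- initConv(p, sprintf("dc_m%dn%d", nd$m, nd$n), 3, nc, nc)
      p <- initConv(p, sprintf("du_m%dn%d", nd$m, nd$n), 3, nc, nc)
    }
    layers <- c(1L, 2L)
  } else {
    for (n in 1:3) {
      p <- initConv(p, paste0("fdc_n", n), 3, nc, nc)
      p <- initConv(p, paste0("fdu_n", n), 3, nc, nc)
    }
    layers <- 2L
  }
  hc <- config$head_channels
  for (l in layers) {
    for (br in c("hm", "size", "off")) {
      p <- initConv(p, sprintf("h%d_%s_c", l, br), 3, nc, hc)
      cout <- if (br == "hm") 1L else 2L
      bias <- if (br == "hm") -2.19 else 0
      p <- initConv(p, sprintf("h%d_%s_o", l, br), 1, hc, cout,
                    bias = bias)
    }
  }
  new("FruitDetector", config = config, params = p)
}

# Pad an (H, W, C) image array with zeros to a multiple of `mult`;
# records the original size so detections can be un-padded.
padToMultiple <- function(image, mult) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  Hp <- as.integer(ceiling(H / mult) * mult)
  Wp <- as.integer(ceiling(W / mult) * mult)
  if (Hp == H && Wp == W) return(structure(image, orig = c(H, W)))
  out <- array(0, dim = c(Hp, Wp, d[3]))
  out[seq_len(H), seq_len(W), ] <- image
  structure(out, orig = c(H, W))
}

padMultiple <- function(config)
  if (config$neck == "cropped_double") 16L else 32L

# Backbone ops on an existing tape; returns list of value ids by factor.
runBackboneOps <- function(tp, config, xid) {
  ids <- list()
  nLevels <- if (config$neck == "cropped_double") 4L else 5L
  cur <- xid
  for (lvl in seq_len(nLevels)) {
    cur <- tpRelu(tp, tpConv(tp, cur, paste0("bb", lvl), stride = 2))
    for (d in seq_len(config$backbone_depth))
      cur <- tpRelu(tp, tpConv(tp, cur, paste0("bb", lvl, "r", d)))
    ids[[as.character(2^lvl)]] <- cur
  }
  ids[as.character(backboneFactors(config))]
}

# DC = conv3x3 + ReLU; DU = conv3x3 + ReLU + 2x bilinear upsampling.
fuseDC <- function(tp, id, pname) tpRelu(tp, tpConv(tp, id, pname))
fuseDU <- function(tp, id, pname, factor = 2)
  tpUpsample(tp, tpRelu(tp, tpConv(tp, id, pname)), factor)

runNeckOps <- function(tp, config, pyramidIds) {
  proj <- lapply(names(pyramidIds), function(m)
    tpConv(tp, pyramidIds[[m]], paste0("proj", m)))
  names(proj) <- names(pyramidIds)
  if (config$neck == "cropped_double") {
    O <- list()
    for (m in backboneFactors(config)) O[[key(m, 0)]] <- proj[[as.character(m)]]
    for (nd in croppedNeckNodes()) {
      a <- fuseDC(tp, O[[key(nd$m, nd$n - 1)]],
                  sprintf("dc_m%dn%d", nd$m, nd$n))
      b <- fuseDU(tp, O[[key(2 * nd$m, nd$n - 1)]],
                  sprintf("du_m%dn%d", nd$m, nd$n))
      O[[key(nd$m, nd$n)]] <- tpAdd(tp, a, b)
    }
    list(layer1 = O[[key(2, 3)]], layer2 = O[[key(4, 2)]])
  } else {
    f <- proj[["4"]]
    for (n in 1:3) {
      a <- fuseDC(tp, f, paste0("fdc_n", n))
      b <- fuseDU(tp, proj[[as.character(2^(n + 2))]],
                  paste0("fdu_n", n), factor = 2^n)
      f <- tpAdd(tp, a, b)
    }
    list(layer2 = f)
  }
}

key <- function(m, n) sprintf("m%d.n%d", m, n)

runHeadOps <- function(tp, config, neckIds) {
  lapply(names(neckIds), function(nm) {
    l <- if (nm == "layer1") 1L else 2L
    branch <- function(br) {
      h <- tpRelu(tp, tpConv(tp, neckIds[[nm]],
                             sprintf("h%d_%s_c", l, br)))
      tpConv(tp, h, sprintf("h%d_%s_o", l, br))
    }
    hmLogit <- branch("hm")
    list(r = if (l == 1L) 2L else 4L,
         hm = tpSigmoid(tp, hmLogit), hm_logit = hmLogit,
         size = branch("size"), off = branch("off"))
  }) |> setNames(names(neckIds))
}

# Full forward pass on a tape. Returns the tape plus per-layer value
# ids; used by training (backward) and by the eager wrappers below.
forwardFull <- function(detector, image) {
  config <- detector@config
  img <- padToMultiple(image, padMultiple(config))
  tp <- tapeNew(detector@params)
  xid <- tpInput(tp, img)
  pyr <- runBackboneOps(tp, config, xid)
  neck <- runNeckOps(tp, config, pyr)
  heads <- runHeadOps(tp, config, neck)
  list(tape = tp, heads = heads, pyramid = pyr,
       padded = dim(img)[1:2], orig = attr(img, "orig"))
}

#' Run the backbone on an image
#'
#' @param detector a [FruitDetector-class].
#' @param image an \code{(H, W, 3)} array in \code{[0, 1]}; sizes that
#'   are not a multiple of the required factor are zero-padded and the
#'   original size recorded in attribute \code{"orig"}.
#' @return a named list of \code{(H/m, W/m, C_m)} arrays keyed by
#'   downsampling factor (\code{"2","4","8","16"} for the cropped
#'   double-layer neck; \code{"4","8","16","32"} for the original
#'   baseline).
#' @export
backboneForward <- function(detector, image) {
  fw <- forwardFull(detector, image)
  out <- lapply(fw$pyramid, function(id) tpVal(fw$tape, id))
  structure(out, orig = fw$orig, padded = fw$padded)
}

#' Cropped deep-to-shallow neck forward pass
#'
#' Computes the six fusion nodes in dependency order, each as
#' \code{DC(parent at m) + DU(parent at 2m)}, and returns the two
#' prediction feature maps.
#'
#' @param detector a [FruitDetector-class] with \code{neck =
#'   "cropped_double"}.
#' @param pyramid backbone output from [backboneForward()].
#' @return list with elements \code{layer1} (2x downsampling) and
#'   \code{layer2} (4x downsampling).
#' @export
neckForwardCropped <- function(detector, pyramid) {
  stopifnot(detector@config$neck == "cropped_double")
  missing <- setdiff(c("2", "4", "8", "16"), names(pyramid))
  if (length(missing))
    stop("pyramid is missing factor(s): ", paste(missing, collapse = ", "))
  tp <- tapeNew(detector@params)
  ids <- lapply(pyramid, function(x) tpInput(tp, x))
  neck <- runNeckOps(tp, detector@config, ids)
  lapply(neck, function(id) tpVal(tp, id))
}

#' Original shallow-to-deep neck forward pass (ablation baseline)
#'
#' Executes the three fusion steps
#' \code{F_n = DC(F_{n-1}) + DU(O at factor 2^(n+2))} and returns the
#' single 4x-downsampling prediction feature map.
#'
#' @param detector a [FruitDetector-class] with \code{neck =
#'   "original_single"}.
#' @param pyramid backbone output with factors 4, 8, 16, 32.
#' @return list with the single element \code{layer2}.
#' @export
neckForwardOriginal <- function(detector, pyramid) {
  stopifnot(detector@config$neck == "original_single")
  missing <- setdiff(c("4", "8", "16", "32"), names(pyramid))
  if (length(missing))
    stop("pyramid is missing factor(s): ", paste(missing, collapse = ", "))
  tp <- tapeNew(detector@params)
  ids <- lapply(pyramid, function(x) tpInput(tp, x))
  neck <- runNeckOps(tp, detector@config, ids)
  lapply(neck, function(id) tpVal(tp, id))
}

#' Prediction heads forward pass
#'
#' Applies the three convolutional branches per prediction layer:
#' heatmap (1 channel, sigmoid-squashed to \code{[0, 1]}), box size
#' (2 channels, input-image pixels) and center offset (2 channels,
#' heatmap-cell units).
#'
#' @param detector a [FruitDetector-class].
#' @param neckOutputs list of neck feature maps (\code{layer1} and/or
#'   \code{layer2}).
#' @return per layer, a list with \code{r}, \code{hm} (matrix),
#'   \code{size} and \code{off} (\code{(h, w, 2)} arrays).
#' @export
headsForward <- function(detector, neckOutputs) {
  tp <- tapeNew(detector@params)
  ids <- lapply(neckOutputs, function(x) tpInput(tp, x))
  heads <- runHeadOps(tp, detector@config, ids)
  lapply(heads, function(h)
    list(r = h$r, hm = drop(tpVal(tp, h$hm)),
         size = tpVal(tp, h$size), off = tpVal(tp, h$off)))
}

#' End-to-end raw model outputs for one image
#'
#' @inheritParams backboneForward
#' @return as [headsForward()], plus attributes \code{"orig"} and
#'   \code{"padded"} recording the image sizes.
#' @export
detectorOutputs <- function(detector, image) {
  fw <- forwardFull(detector, image)
  out <- lapply(fw$heads, function(h)
    list(r = h$r, hm = drop(tpVal(fw$tape, h$hm)),
         size = tpVal(fw$tape, h$size), off = tpVal(fw$tape, h$off)))
  structure(out, orig = fw$orig, padded = fw$padded)
}

#' Save / load a detector checkpoint
#'
#' Checkpoints store a format version, the model configuration and the
#' weights.
#'
#' @param detector a [FruitDetector-class].
#' @param path checkpoint file path.
#' @return \code{saveDetector} returns \code{path} invisibly;
#'   \code{loadDetector} returns the [FruitDetector-class].
#' @export
saveDetector <- function(detector, path) {
  saveRDS(list(format = "fruitpoint-checkpoint",
               version = 1L,
               config = detector@config,
               params = detector@params), path)
  invisible(path)
}

#' @rdname saveDetector
#' @export
loadDetector <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fruitpoint-checkpoint"))
    stop("not a fruitpoint checkpoint: ", path)
  if (ck$version != 1L)
    stop("unsupported checkpoint version: ", ck$version)
  new("FruitDetector", config = ck$config, params = ck$params)
}
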