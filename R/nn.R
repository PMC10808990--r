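#' @include fruitpoint-package.R
NULL

# A minimal eager tape for dense CNNs. Values are (H, W, C) arrays;
# parameters live in a flat named list ("<name>.w" / "<name>.b").
# Each op records what backward needs; tapeBackward() replays in
# reverse and accumulates parameter gradients.

tapeNew <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$vals <- list()
  tp$ops <- list()
  tp$n <- 0L
  tp
}

tpPush <- function(tp, val, op) {
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- val
  op$out <- tp$n
  tp$ops[[length(tp$ops) + 1L]] <- op
  tp$n
}

tpVal <- function(tp, id) {
  id <- as.integer(id)  # force before touching tp: nested calls mutate it
  tp$vals[[id]]
}

tpInput <- function(tp, x) {
  if (length(dim(x)) == 2) dim(x) <- c(dim(x), 1L)
  tpPush(tp, x, list(type = "input"))
}

tpConv <- function(tp, id, pname, stride = 1L, pad = NULL) {
  w <- tp$params[[paste0(pname, ".w")]]
  b <- tp$params[[paste0(pname, ".b")]]
  if (is.null(w)) stop("unknown conv parameter: ", pname)
  if (is.null(pad)) pad <- (dim(w)[1] - 1L) %/% 2L
  y <- .convForward(tpVal(tp, id), w, b, as.integer(stride),
                    as.integer(pad))
  tpPush(tp, y, list(type = "conv", a = id, pname = pname,
                     stride = as.integer(stride), pad = as.integer(pad)))
}

tpRelu <- function(tp, id) {
  x <- tpVal(tp, id)
  tpPush(tp, pmax(x, 0), list(type = "relu", a = id))
}

tpAdd <- function(tp, id1, id2) {
  tpPush(tp, tpVal(tp, id1) + tpVal(tp, id2),
         list(type = "add", a = id1, b = id2))
}

tpUpsample <- function(tp, id, factor) {
  x <- tpVal(tp, id)
  tpPush(tp, .upsampleForward(x, as.integer(factor)),
         list(type = "upsample", a = id, factor = as.integer(factor),
              inH = dim(x)[1], inW = dim(x)[2]))
}

tpSigmoid <- function(tp, id) {
  x <- tpVal(tp, id)
  tpPush(tp, 1 / (1 + exp(-x)), list(type = "sigmoid", a = id))
}

# seeds: named list mapping value id (as character) to dL/dvalue.
# Returns list(param_grads = named list aligned with tp$params).
tapeBackward <- function(tp, seeds) {
  grads <- vector("list", tp$n)
  for (id in names(seeds)) {
    i <- as.integer(id)
    g <- seeds[[id]]
    if (length(dim(g)) == 2) dim(g) <- c(dim(g), 1L)
    grads[[i]] <- if (is.null(grads[[i]])) g else grads[[i]] + g
  }
  pgrads <- list()
  addGrad <- function(cur, g) if (is.null(cur)) g else cur + g
  for (k in rev(seq_along(tp$ops))) {
    op <- tp$ops[[k]]
    g <- grads[[op$out]]
    if (is.null(g)) next
    switch(op$type,
      input = NULL,
      conv = {
        res <- .convBackward(tpVal(tp, op$a),
                             tp$params[[paste0(op$pname, ".w")]],
                             g, op$stride, op$pad)
        grads[[op$a]] <- addGrad(grads[[op$a]], res$dx)
        wn <- paste0(op$pname, ".w"); bn <- paste0(op$pname, ".b")
        pgrads[[wn]] <- addGrad(pgrads[[wn]], res$dw)
        pgrads[[bn]] <- addGrad(pgrads[[bn]], res$db)
      },
      relu = {
        mask <- tpVal(tp, op$a) > 0
        grads[[op$a]] <- addGrad(grads[[op$a]], g * mask)
      },
      add = {
        grads[[op$a]] <- addGrad(grads[[op$a]], g)
        grads[[op$b]] <- addGrad(grads[[op$b]], g)
      },
      upsample = {
        dx <- .upsampleBackward(g, op$inH, op$inW, op$factor)
        grads[[op$a]] <- addGrad(grads[[op$a]], dx)
      },
      sigmoid = {
        y <- tpVal(tp, op$out)
        grads[[op$a]] <- addGrad(grads[[op$a]], g * y * (1 - y))
      },
      stop("unknown op type: ", op$type))
    grads[[op$out]] <- NULL
  }
  pgrads
}

# He-normal initialization for a conv layer; bias defaults to 0.
initConv <- function(params, name, k, cin, cout, bias = 0) {
  fan <- k * k * cin
  params[[paste0(name, ".w")]] <-
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / fan)),
          dim = c(k, k, cin, cout))
  params[[paste0(name, ".b")]] <- rep(bias, cout)
  params
}

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
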