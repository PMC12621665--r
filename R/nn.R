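# Small self-contained neural-network layer library (no external deep
# learning framework exists for R in this stack). Spatial tensors use dim
# (H, W, C, N); feature tensors are N x F matrices. Convolution is im2col +
# BLAS matmul, vectorized over the batch, with exact analytic backprop for
# every layer (checked against finite differences in the test suite).

# ---- layer constructors ----------------------------------------------------

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L) {
  fan_in <- k * k * cin
  W <- matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), cin = as.integer(cin), cout = as.integer(cout),
       params = list(W = W, b = numeric(cout)))
}

nn_relu <- function() list(type = "relu", params = list())

nn_maxpool2 <- function() list(type = "maxpool2", params = list())

nn_gap <- function() list(type = "gap", params = list())

nn_linear <- function(din, dout) {
  W <- matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
  list(type = "linear", din = as.integer(din), dout = as.integer(dout),
       params = list(W = W, b = numeric(dout)))
}

nn_dropout <- function(p) list(type = "dropout", p = p, params = list())

nn_bn <- function(f, spatial = FALSE, momentum = 0.1, eps = 1e-5) {
  list(type = if (spatial) "bn2d" else "bn1d", f = as.integer(f),
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, f), beta = numeric(f)),
       buffers = list(run_mean = numeric(f), run_var = rep(1, f)))
}

nn_resblock <- function(cin, cout, stride = 1L) {
  main <- list(nn_conv(cin, cout, 3L, stride), nn_bn(cout, spatial = TRUE),
               nn_relu(), nn_conv(cout, cout, 3L, 1L), nn_bn(cout, spatial = TRUE))
  shortcut <- if (stride != 1L || cin != cout) {
    list(nn_conv(cin, cout, 1L, stride, pad = 0L), nn_bn(cout, spatial = TRUE))
  } else NULL
  list(type = "resblock", main = main, shortcut = shortcut, params = list())
}

# ---- conv ------------------------------------------------------------------
# The conv and pooling kernels live in src/nn_ops.cpp; backward passes
# recompute im2col / argmax from the cached layer input, so caches hold only
# references to existing arrays and the R heap stays small during training.

conv_forward <- function(layer, x, mode) {
  out <- cs_conv_forward(x, layer$params$W, layer$params$b,
                         layer$k, layer$stride, layer$pad)
  list(out = out, cache = list(x = x))
}

conv_backward <- function(layer, cache, dout) {
  r <- cs_conv_backward(cache$x, layer$params$W, dout,
                        layer$k, layer$stride, layer$pad)
  list(dx = r$dx, grads = list(W = r$W, b = r$b))
}

# ---- pooling / activations -------------------------------------------------

maxpool2_forward <- function(layer, x, mode) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  list(out = cs_maxpool2_forward(x), cache = list(x = x))
}

maxpool2_backward <- function(layer, cache, dout) {
  list(dx = cs_maxpool2_backward(cache$x, dout), grads = list())
}

relu_forward <- function(layer, x, mode) {
  list(out = pmax(x, 0), cache = list(x = x))
}

relu_backward <- function(layer, cache, dout) {
  list(dx = dout * (cache$x > 0), grads = list())
}

gap_forward <- function(layer, x, mode) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(H * W, C * N)
  out <- t(matrix(colMeans(xm), C, N))
  list(out = out, cache = list(H = H, W = W, C = C, N = N))
}

gap_backward <- function(layer, cache, dout) {
  H <- cache$H; W <- cache$W
  dx <- array(rep(as.vector(t(dout)) / (H * W), each = H * W),
              dim = c(H, W, cache$C, cache$N))
  list(dx = dx, grads = list())
}

dropout_forward <- function(layer, x, mode) {
  if (mode != "train" || layer$p <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  mask <- (array(stats::runif(length(x)), dim = dim(x)) >= layer$p) / (1 - layer$p)
  list(out = x * mask, cache = list(mask = mask))
}

dropout_backward <- function(layer, cache, dout) {
  dx <- if (is.null(cache$mask)) dout else dout * cache$mask
  list(dx = dx, grads = list())
}

linear_forward <- function(layer, x, mode) {
  out <- x %*% layer$params$W
  out <- out + rep(layer$params$b, each = nrow(out))
  list(out = out, cache = list(x = x))
}

linear_backward <- function(layer, cache, dout) {
  list(dx = dout %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

# ---- batch norm ------------------------------------------------------------

# core on an (M x F) matrix; returns updated buffers when training
bn_core_forward <- function(layer, xm, mode) {
  g <- layer$params$gamma; b <- layer$params$beta; eps <- layer$eps
  if (mode == "train") {
    M <- nrow(xm)
    bm <- colMeans(xm)
    xc <- xm - rep(bm, each = M)
    bv <- colMeans(xc * xc)                      # population variance
    inv <- 1 / sqrt(bv + eps)
    xhat <- xc * rep(inv, each = M)
    out <- xhat * rep(g, each = M) + rep(b, each = M)
    mom <- layer$momentum
    buffers <- list(run_mean = (1 - mom) * layer$buffers$run_mean + mom * bm,
                    run_var = (1 - mom) * layer$buffers$run_var + mom * bv)
    list(out = out, cache = list(xhat = xhat, inv = inv, M = M, train = TRUE),
         buffers = buffers)
  } else {
    inv <- 1 / sqrt(layer$buffers$run_var + eps)
    M <- nrow(xm)
    xhat <- (xm - rep(layer$buffers$run_mean, each = M)) * rep(inv, each = M)
    out <- xhat * rep(g, each = M) + rep(b, each = M)
    list(out = out, cache = list(xhat = xhat, inv = inv, M = M, train = FALSE),
         buffers = layer$buffers)
  }
}

bn_core_backward <- function(layer, cache, dmat) {
  g <- layer$params$gamma
  M <- cache$M
  dgamma <- colSums(dmat * cache$xhat)
  dbeta <- colSums(dmat)
  dxhat <- dmat * rep(g, each = M)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dx <- (dxhat - rep(s1 / M, each = M) -
             cache$xhat * rep(s2 / M, each = M)) * rep(cache$inv, each = M)
  } else {
    dx <- dxhat * rep(cache$inv, each = M)
  }
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

bn1d_forward <- function(layer, x, mode) {
  r <- bn_core_forward(layer, x, mode)
  layer$buffers <- r$buffers
  list(out = r$out, cache = r$cache, layer = layer)
}

bn2d_forward <- function(layer, x, mode) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_core_forward(layer, xm, mode)
  out <- r$out; dim(out) <- c(d[1], d[2], d[4], d[3])
  layer$buffers <- r$buffers
  list(out = aperm(out, c(1, 2, 4, 3)),
       cache = c(r$cache, list(d = d)), layer = layer)
}

bn2d_backward <- function(layer, cache, dout) {
  d <- cache$d
  dm <- aperm(dout, c(1, 2, 4, 3)); dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  r <- bn_core_backward(layer, cache, dm)
  dx <- r$dx; dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), grads = r$grads)
}

# ---- resblock --------------------------------------------------------------

resblock_forward <- function(layer, x, mode) {
  fm <- seq_forward(layer$main, x, mode)
  layer$main <- fm$layers
  if (is.null(layer$shortcut)) {
    sc_out <- x; fs <- NULL
  } else {
    fs <- seq_forward(layer$shortcut, x, mode)
    layer$shortcut <- fs$layers
    sc_out <- fs$out
  }
  pre <- fm$out + sc_out
  out <- pmax(pre, 0)
  list(out = out,
       cache = list(main = fm$caches, shortcut = if (is.null(fs)) NULL else fs$caches,
                    mask = pre > 0),
       layer = layer)
}

resblock_backward <- function(layer, cache, dout) {
  dpre <- dout * cache$mask
  bm <- seq_backward(layer$main, cache$main, dpre)
  if (is.null(layer$shortcut)) {
    dx <- bm$dx + dpre
    grads <- list(main = bm$grads, shortcut = NULL)
  } else {
    bs <- seq_backward(layer$shortcut, cache$shortcut, dpre)
    dx <- bm$dx + bs$dx
    grads <- list(main = bm$grads, shortcut = bs$grads)
  }
  list(dx = dx, grads = grads)
}

# ---- dispatch --------------------------------------------------------------

layer_forward <- function(layer, x, mode) {
  r <- switch(layer$type,
    conv = conv_forward(layer, x, mode),
    relu = relu_forward(layer, x, mode),
    maxpool2 = maxpool2_forward(layer, x, mode),
    gap = gap_forward(layer, x, mode),
    linear = linear_forward(layer, x, mode),
    dropout = dropout_forward(layer, x, mode),
    bn1d = bn1d_forward(layer, x, mode),
    bn2d = bn2d_forward(layer, x, mode),
    resblock = resblock_forward(layer, x, mode),
    stop("unknown layer type ", layer$type))
  if (is.null(r$layer)) r$layer <- layer
  r
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv = conv_backward(layer, cache, dout),
    relu = relu_backward(layer, cache, dout),
    maxpool2 = maxpool2_backward(layer, cache, dout),
    gap = gap_backward(layer, cache, dout),
    linear = linear_backward(layer, cache, dout),
    dropout = dropout_backward(layer, cache, dout),
    bn1d = bn_core_backward(layer, cache, dout),
    bn2d = bn2d_backward(layer, cache, dout),
    resblock = resblock_backward(layer, cache, dout),
    stop("unknown layer type ", layer$type))
}

seq_forward <- function(layers, x, mode) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, mode)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

seq_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dout, grads = grads)
}

# ---- Adam ------------------------------------------------------------------

adam_init_layers <- function(layers) {
  lapply(layers, function(l) {
    st <- lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    if (l$type == "resblock") {
      st <- list(.params = st, main = adam_init_layers(l$main),
                 shortcut = if (is.null(l$shortcut)) NULL
                            else adam_init_layers(l$shortcut))
    }
    st
  })
}

adam_update_layers <- function(layers, grads, state, lr, t,
                               beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (l$type == "resblock") {
      rm_ <- adam_update_layers(l$main, g$main, s$main, lr, t, beta1, beta2, eps)
      l$main <- rm_$layers; s$main <- rm_$state
      if (!is.null(l$shortcut)) {
        rs <- adam_update_layers(l$shortcut, g$shortcut, s$shortcut, lr, t,
                                 beta1, beta2, eps)
        l$shortcut <- rs$layers; s$shortcut <- rs$state
      }
    } else if (length(l$params)) {
      for (nm in names(l$params)) {
        gi <- g[[nm]]
        si <- s[[nm]]
        si$m <- beta1 * si$m + (1 - beta1) * gi
        si$v <- beta2 * si$v + (1 - beta2) * gi * gi
        mhat <- si$m / (1 - beta1^t)
        vhat <- si$v / (1 - beta2^t)
        l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        s[[nm]] <- si
      }
    }
    layers[[i]] <- l; state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# max absolute gradient entry per layer list (used by the gradient-flow check)
grads_max_abs <- function(grads) {
  vals <- unlist(lapply(grads, function(g) {
    if (is.null(g)) return(0)
    unlist(lapply(g, function(x) if (is.list(x)) grads_max_abs(list(x)) else max(abs(x))))
  }))
  if (length(vals)) max(vals) else 0
}
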