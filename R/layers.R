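# Primitive differentiable layers.
#
# Every layer is a list with class "scn_layer": $type, $par (named list of
# numeric arrays, possibly empty) and type-specific hyperparameters.
# layer_forward() returns list(y, cache); layer_backward() consumes the
# cache and upstream gradient and returns list(dx, grads) with `grads`
# congruent to $par. Activations are (H, W, C, N) arrays except after
# global average pooling, where they become (C, N) matrices.

new_layer <- function(type, par = list(), ...) {
  structure(c(list(type = type, par = par), list(...)), class = "scn_layer")
}

# Kaiming-uniform initialization: U(-b, b), b = sqrt(6 / fan_in). Draws
# from the caller's RNG stream so whole-model builds are seed-reproducible.
kaiming_uniform <- function(dims, fan_in) {
  b <- sqrt(6 / fan_in)
  array(runif(prod(dims), -b, b), dim = dims)
}

layer_conv2d <- function(in_channels, out_channels, kh, kw = kh, stride = 1L) {
  W <- kaiming_uniform(c(kh, kw, in_channels, out_channels), kh * kw * in_channels)
  new_layer("conv", par = list(W = W, b = numeric(out_channels)),
            stride = as.integer(stride),
            pad = c(kh %/% 2L, kw %/% 2L))
}

# Batch normalization (per channel over batch and spatial positions).
# Running statistics live in an environment so they persist through the
# functional parameter updates; build_network() creates fresh state and
# train_model() resets it, keeping runs seed-reproducible.
layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  stats <- new.env(parent = emptyenv())
  stats$mean <- numeric(channels)
  stats$var <- rep(1, channels)
  new_layer("bn", par = list(gamma = rep(1, channels),
                             beta = numeric(channels)),
            momentum = momentum, eps = eps, stats = stats)
}

bn_reset <- function(layer) {
  layer$stats$mean[] <- 0
  layer$stats$var[] <- 1
  invisible(layer)
}

layer_relu    <- function() new_layer("relu")
layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}
layer_avgpool <- function(k = 3L, stride = 1L, pad = 1L) {
  new_layer("avgpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
}
layer_gap     <- function() new_layer("gap")
layer_dropout <- function(rate = 0.5) new_layer("dropout", rate = rate)

layer_linear <- function(in_features, out_features) {
  W <- matrix(runif(out_features * in_features,
                    -sqrt(6 / in_features), sqrt(6 / in_features)),
              out_features, in_features)
  new_layer("linear", par = list(W = W, b = numeric(out_features)))
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      if (dim(x)[3L] != dim(layer$par$W)[3L]) {
        stop("conv layer expects ", dim(layer$par$W)[3L], " channels, got ",
             dim(x)[3L], call. = FALSE)
      }
      y <- cpp_conv2d_forward(x, layer$par$W, layer$par$b,
                              layer$stride, layer$stride,
                              layer$pad[1L], layer$pad[2L])
      list(y = y, cache = x)
    },
    relu = {
      mask <- x > 0
      list(y = x * mask, cache = mask)
    },
    bn = {
      d <- dim(x)
      xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(xm^2) - mu^2
        layer$stats$mean <- layer$momentum * layer$stats$mean +
          (1 - layer$momentum) * mu
        layer$stats$var <- layer$momentum * layer$stats$var +
          (1 - layer$momentum) * v
      } else {
        mu <- layer$stats$mean
        v <- layer$stats$var
      }
      ivar <- 1 / sqrt(v + layer$eps)
      xh <- sweep(sweep(xm, 2L, mu, "-"), 2L, ivar, "*")
      ym <- sweep(sweep(xh, 2L, layer$par$gamma, "*"), 2L, layer$par$beta, "+")
      y <- aperm(array(ym, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
      list(y = y, cache = list(xh = xh, ivar = ivar, d = d, train = train))
    },
    maxpool = {
      r <- cpp_maxpool_forward(x, layer$k, layer$stride, layer$pad)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    avgpool = {
      y <- cpp_avgpool_forward(x, layer$k, layer$stride, layer$pad)
      list(y = y, cache = dim(x))
    },
    gap = {
      d <- dim(x)
      y <- matrix(colMeans(matrix(x, d[1L] * d[2L], d[3L] * d[4L])), d[3L], d[4L])
      list(y = y, cache = d)
    },
    dropout = {
      if (train && layer$rate > 0) {
        keep <- array(runif(length(x)) >= layer$rate, dim = dim(x)) / (1 - layer$rate)
        list(y = x * keep, cache = keep)
      } else {
        list(y = x, cache = NULL)
      }
    },
    linear = {
      list(y = layer$par$W %*% x + layer$par$b, cache = x)
    },
    scat = scat_layer_forward(layer, x),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      g <- cpp_conv2d_backward(cache, layer$par$W, dy,
                               layer$stride, layer$stride,
                               layer$pad[1L], layer$pad[2L])
      list(dx = g$dx, grads = list(W = g$dw, b = g$db))
    },
    relu = list(dx = dy * cache, grads = list()),
    bn = {
      d <- cache$d
      n <- d[1L] * d[2L] * d[4L]
      dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), n, d[3L])
      dgamma <- colSums(dym * cache$xh)
      dbeta <- colSums(dym)
      dxh <- sweep(dym, 2L, layer$par$gamma, "*")
      if (cache$train) {
        # batch statistics depend on x
        dxm <- sweep(n * dxh, 2L, colSums(dxh), "-") -
          cache$xh * rep(colSums(dxh * cache$xh), each = n)
        dxm <- sweep(dxm, 2L, cache$ivar / n, "*")
      } else {
        dxm <- sweep(dxh, 2L, cache$ivar, "*")
      }
      dx <- aperm(array(dxm, c(d[1L], d[2L], d[4L], d[3L])), c(1L, 2L, 4L, 3L))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    maxpool = list(dx = cpp_maxpool_backward(cache$argmax, cache$xdim, dy),
                   grads = list()),
    avgpool = list(dx = cpp_avgpool_backward(cache, layer$k, layer$stride,
                                             layer$pad, dy),
                   grads = list()),
    gap = {
      d <- cache
      dx <- array(rep(as.numeric(dy) / (d[1L] * d[2L]), each = d[1L] * d[2L]),
                  dim = d)
      list(dx = dx, grads = list())
    },
    dropout = {
      if (is.null(cache)) list(dx = dy, grads = list())
      else list(dx = dy * cache, grads = list())
    },
    linear = {
      list(dx = crossprod(layer$par$W, dy),
           grads = list(W = tcrossprod(dy, cache), b = rowSums(dy)))
    },
    scat = scat_layer_backward(layer, cache, dy),
    stop("unknown layer type: ", layer$type)
  )
}

# Sequential composition ----------------------------------------------------

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train = train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

seq_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[[i]] <- r$grads
  }
  list(dx = dy, grads = grads)
}

seq_params <- function(layers) lapply(layers, function(l) l$par)

seq_set_params <- function(layers, tree) {
  for (i in seq_along(layers)) layers[[i]]$par <- tree[[i]]
  layers
}
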