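#' Softmax over the spatial positions of a feature map
#'
#' Normalizes logits into a spatial attention distribution: for each
#' attention channel (and each sample, if a batch dimension is present) the
#' weights over all `height x width` positions are non-negative and sum to
#' one. Numerically stabilized by subtracting the per-map maximum, so the
#' result is invariant to adding a constant to all logits.
#'
#' @param logits A numeric matrix `(H, W)` or array `(H, W, A)` /
#'   `(H, W, A, N)` of attention logits.
#' @return An array of the same shape whose entries are non-negative and sum
#'   to 1 over the first two (spatial) dimensions.
#' @examples
#' spatial_softmax(matrix(0, 2, 2))          # uniform 0.25
#' spatial_softmax(matrix(c(0, 0, 0, log(3)), 2, 2))
#' @export
spatial_softmax <- function(logits) {
  if (!is.numeric(logits) || length(logits) == 0L) {
    stop("logits must be a non-empty numeric array", call. = FALSE)
  }
  check_finite(logits, "logits")
  d0 <- dim(logits)
  x <- as_feature_map(logits)
  d <- dim(x)
  m <- matrix(x, d[1L] * d[2L], d[3L] * d[4L])
  m <- exp(sweep(m, 2L, apply(m, 2L, max), "-"))
  m <- sweep(m, 2L, colSums(m), "/")
  out <- array(m, dim = d)
  if (is.null(d0)) dim(out) <- NULL else dim(out) <- d0
  out
}

# Softmax over the channel axis (per pixel, per sample) of an (H,W,C,N) array.
channel_softmax4 <- function(x) {
  d <- dim(x)
  xp <- aperm(x, c(3L, 1L, 2L, 4L))
  m <- matrix(xp, d[3L], d[1L] * d[2L] * d[4L])
  m <- exp(sweep(m, 2L, apply(m, 2L, max), "-"))
  m <- sweep(m, 2L, colSums(m), "/")
  aperm(array(m, dim = c(d[3L], d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
}

#' SCAT parameter set
#'
#' Builds the learnable parameters of the spatial convolutional attention
#' (SCAT) operator: a 1x1 convolution reducing `channels` to
#' `max(1, channels / reduction_ratio)` channels, followed by a second 1x1
#' convolution producing attention logits, which are softmax-normalized and
#' applied element-wise to the feature map. Weights are Kaiming-uniform
#' draws from the current RNG stream, so wrap in `set.seed()` for
#' reproducibility.
#'
#' @param channels Number of feature-map channels the operator is applied to.
#' @param reduction_ratio Channel reduction factor of the first 1x1
#'   convolution (default 4).
#' @param n_attn Number of attention channels (default 1: a single spatial
#'   map broadcast over all feature channels). Must divide `channels`, or
#'   equal `channels` when `attn_axis = "channel"`.
#' @param attn_axis `"spatial"` (default): softmax over the `H x W`
#'   positions of each attention channel. `"channel"`: softmax across
#'   channels at each pixel.
#' @return An object of class `scat_params`.
#' @export
scat_params <- function(channels, reduction_ratio = 4L, n_attn = 1L,
                        attn_axis = c("spatial", "channel")) {
  attn_axis <- match.arg(attn_axis)
  channels <- as.integer(channels)
  if (channels < 1L) stop("channels must be >= 1", call. = FALSE)
  if (attn_axis == "channel") n_attn <- channels
  n_attn <- as.integer(n_attn)
  if (channels %% n_attn != 0L) {
    stop("n_attn (", n_attn, ") must divide channels (", channels, ")",
         call. = FALSE)
  }
  reduced <- max(1L, channels %/% as.integer(reduction_ratio))
  structure(list(
    channels = channels, reduced = reduced, n_attn = n_attn,
    attn_axis = attn_axis, reduction_ratio = as.integer(reduction_ratio),
    reduce_weights = kaiming_uniform(c(1L, 1L, channels, reduced), channels),
    reduce_bias = numeric(reduced),
    # zero-init logits: attention starts uniform, so the operator starts as
    # the identity and cannot blow up activations at initialization
    attn_weights = array(0, c(1L, 1L, reduced, n_attn)),
    attn_bias = numeric(n_attn)
  ), class = "scat_params")
}

# Shared forward computation for the functional API and the layer.
scat_compute <- function(x, p) {
  d <- dim(x)
  if (d[3L] != p$channels) {
    stop("SCAT configured for ", p$channels, " channels, got ", d[3L],
         call. = FALSE)
  }
  r <- cpp_conv2d_forward(x, p$reduce_weights, p$reduce_bias, 1L, 1L, 0L, 0L)
  l <- cpp_conv2d_forward(r, p$attn_weights, p$attn_bias, 1L, 1L, 0L, 0L)
  if (p$attn_axis == "spatial") {
    a <- spatial_softmax(l)
    scale <- d[1L] * d[2L]           # uniform attention == identity
  } else {
    a <- channel_softmax4(l)
    scale <- p$n_attn
  }
  wgt <- a * scale
  group <- rep(seq_len(p$n_attn), each = d[3L] %/% p$n_attn)
  wfull <- wgt[, , group, , drop = FALSE]
  list(y = x * wfull, r = r, a = a, wgt = wgt, wfull = wfull,
       scale = scale, group = group)
}

#' Apply the SCAT operator to a feature map
#'
#' Reweights a feature map by a learned attention distribution. The
#' attention weights are rescaled by the number of positions on the softmax
#' axis so that a *uniform* attention map leaves the input unchanged
#' (identity limit); in particular, zeroed `attn_weights` give
#' `scat_forward(x, p) == x`.
#'
#' @param x A feature map: matrix `(H, W)`, array `(H, W, C)` or batch
#'   `(H, W, C, N)`.
#' @param p A [scat_params()] object whose `channels` matches `x`.
#' @return An array of the same shape as `x`.
#' @export
scat_forward <- function(x, p) {
  stopifnot(inherits(p, "scat_params"))
  d0 <- dim(x)
  x4 <- as_feature_map(x)
  check_finite(x4, "feature map")
  y <- scat_compute(x4, p)$y
  if (is.null(d0)) dim(y) <- NULL else dim(y) <- d0
  y
}

# SCAT as a differentiable layer -------------------------------------------

layer_scat <- function(channels, reduction_ratio = 4L, n_attn = 1L,
                       attn_axis = "spatial") {
  p <- scat_params(channels, reduction_ratio, n_attn, attn_axis)
  new_layer("scat",
            par = list(Wr = p$reduce_weights, br = p$reduce_bias,
                       Wa = p$attn_weights, ba = p$attn_bias),
            channels = p$channels, reduced = p$reduced, n_attn = p$n_attn,
            attn_axis = p$attn_axis, reduction_ratio = p$reduction_ratio)
}

layer_as_scat_params <- function(layer) {
  structure(list(
    channels = layer$channels, reduced = layer$reduced, n_attn = layer$n_attn,
    attn_axis = layer$attn_axis, reduction_ratio = layer$reduction_ratio,
    reduce_weights = layer$par$Wr, reduce_bias = layer$par$br,
    attn_weights = layer$par$Wa, attn_bias = layer$par$ba
  ), class = "scat_params")
}

scat_layer_forward <- function(layer, x) {
  cc <- scat_compute(x, layer_as_scat_params(layer))
  list(y = cc$y, cache = list(x = x, r = cc$r, a = cc$a, wfull = cc$wfull,
                              scale = cc$scale, group = cc$group))
}

scat_layer_backward <- function(layer, cache, dy) {
  d <- dim(cache$x)
  A <- layer$n_attn
  dx_direct <- dy * cache$wfull

  # Gradient w.r.t. the (rescaled) attention weights, pooled per group.
  dwfull <- dy * cache$x
  if (A == d[3L]) {
    dwgt <- dwfull
  } else {
    gsz <- d[3L] %/% A
    dwgt <- array(0, dim = c(d[1L], d[2L], A, d[4L]))
    for (g in seq_len(A)) {
      idx <- ((g - 1L) * gsz + 1L):(g * gsz)
      dwgt[, , g, ] <- apply(dwfull[, , idx, , drop = FALSE], c(1L, 2L, 4L), sum)
    }
  }
  da <- dwgt * cache$scale

  # Softmax backward on the normalization axis.
  a <- cache$a
  if (layer$attn_axis == "spatial") {
    am <- matrix(a, d[1L] * d[2L], A * d[4L])
    dm <- matrix(da, d[1L] * d[2L], A * d[4L])
    dl <- am * sweep(dm, 2L, colSums(am * dm), "-")
    dl <- array(dl, dim = c(d[1L], d[2L], A, d[4L]))
  } else {
    ap <- aperm(a, c(3L, 1L, 2L, 4L))
    dp <- aperm(da, c(3L, 1L, 2L, 4L))
    am <- matrix(ap, A, d[1L] * d[2L] * d[4L])
    dm <- matrix(dp, A, d[1L] * d[2L] * d[4L])
    dl <- am * sweep(dm, 2L, colSums(am * dm), "-")
    dl <- aperm(array(dl, dim = c(A, d[1L], d[2L], d[4L])), c(2L, 3L, 1L, 4L))
  }

  ga <- cpp_conv2d_backward(cache$r, layer$par$Wa, dl, 1L, 1L, 0L, 0L)
  gr <- cpp_conv2d_backward(cache$x, layer$par$Wr, ga$dx, 1L, 1L, 0L, 0L)
  list(dx = dx_direct + gr$dx,
       grads = list(Wr = gr$dw, br = gr$db, Wa = ga$dw, ba = ga$db))
}
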