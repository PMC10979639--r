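#' Configuration of the SCAT-inception classifier
#'
#' The default architecture stacks, after a small convolutional stem,
#' 3 SCAT-A units, 2 SCAT-B units, 4 C units, 1 D (grid-reduction) unit and
#' 1 E unit — 11 inception units in total — followed by global average
#' pooling, dropout and a linear classification head.
#'
#' @param n_a,n_b,n_c,n_d,n_e Counts of each inception variant
#'   (defaults 3, 2, 4, 1, 1).
#' @param stem_channels Output channels of the stem (default 32); the stem
#'   is two stride-2 3x3 convolutions plus a stride-2 max-pool, reducing
#'   spatial resolution 8-fold before the first inception unit.
#' @param input_size `(height, width)` of the grayscale input slices
#'   (default `c(128, 128)`).
#' @param n_classes Number of output classes (2: GBM vs MET).
#' @param dropout_rate Dropout before the linear head (default 0.5).
#' @param width_multiplier Scales all channel counts; `< 1` gives the
#'   desk-scale models used in tests (default 1).
#' @param attn_axis Softmax axis of the SCAT operators.
#' @return A `model_config` object.
#' @export
model_config <- function(n_a = 3L, n_b = 2L, n_c = 4L, n_d = 1L, n_e = 1L,
                         stem_channels = 32L, input_size = c(128L, 128L),
                         n_classes = 2L, dropout_rate = 0.5,
                         width_multiplier = 1, attn_axis = "spatial") {
  counts <- as.integer(c(n_a, n_b, n_c, n_d, n_e))
  if (any(counts < 0L) || sum(counts) < 1L) {
    stop("unit counts must be non-negative with at least one unit",
         call. = FALSE)
  }
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (width_multiplier <= 0) stop("width_multiplier must be > 0", call. = FALSE)
  structure(list(n_a = counts[1L], n_b = counts[2L], n_c = counts[3L],
                 n_d = counts[4L], n_e = counts[5L],
                 stem_channels = as.integer(stem_channels),
                 input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 width_multiplier = width_multiplier,
                 attn_axis = attn_axis),
            class = "model_config")
}

scale_ch <- function(ch, m) max(1L, as.integer(round(ch * m)))

#' Build the SCAT-inception network
#'
#' Assembles stem, inception units (in the order A..., B..., C..., D, E) and
#' classification head, with all weights initialized Kaiming-uniform from
#' `seed`, so two builds from the same configuration and seed are identical.
#'
#' @param cfg A [model_config()].
#' @param seed Integer initialization seed.
#' @return A `scn_model` object for [forward()] / [train_model()].
#' @export
build_network <- function(cfg = model_config(), seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  set.seed(as.integer(seed))
  m <- cfg$width_multiplier
  c1 <- scale_ch(cfg$stem_channels / 2, m)
  c2 <- scale_ch(cfg$stem_channels, m)
  stem <- c(conv_relu(1L, c1, 3L, 3L, 2L),
            conv_relu(c1, c2, 3L, 3L, 2L),
            list(layer_maxpool(3L, 2L, 1L)))

  variants <- c(rep("SCAT_A", cfg$n_a), rep("SCAT_B", cfg$n_b),
                rep("C", cfg$n_c), rep("D", cfg$n_d), rep("E", cfg$n_e))
  units <- vector("list", length(variants))
  ch <- c2
  for (i in seq_along(variants)) {
    spec <- block_spec(variants[i], in_channels = ch,
                       attn_axis = cfg$attn_axis)
    units[[i]] <- build_block(spec)
    ch <- spec$out_channels
  }

  head <- list(gap = layer_gap(),
               dropout = layer_dropout(cfg$dropout_rate),
               linear = layer_linear(ch, cfg$n_classes))
  structure(list(cfg = cfg, seed = as.integer(seed), stem = stem,
                 units = units, head = head, feature_channels = ch),
            class = "scn_model")
}

#' @export
print.scn_model <- function(x, ...) {
  cfg <- x$cfg
  cat("SCAT-inception network\n")
  cat(sprintf("  units: %d (A=%d B=%d C=%d D=%d E=%d), stem %d ch, width x%g\n",
              length(x$units), cfg$n_a, cfg$n_b, cfg$n_c, cfg$n_d, cfg$n_e,
              scale_ch(cfg$stem_channels, cfg$width_multiplier),
              cfg$width_multiplier))
  cat(sprintf("  input %dx%d -> %d features -> %d classes; dropout %.2f; %d parameters\n",
              cfg$input_size[1L], cfg$input_size[2L], x$feature_channels,
              cfg$n_classes, cfg$dropout_rate, count_params(x)))
  invisible(x)
}

#' Number of inception units in a built model
#' @param model A `scn_model`.
#' @return Integer count of inception units.
#' @export
n_inception_units <- function(model) length(model$units)

#' Total number of trainable parameters
#' @param model A `scn_model`.
#' @return Integer number of scalar weights and biases.
#' @export
count_params <- function(model) tree_sum(model_params(model))

# Reset all batch-norm running statistics (fresh-training state).
bn_reset_model <- function(model) {
  walk <- function(layers) lapply(layers, function(l) {
    if (inherits(l, "scn_layer") && l$type == "bn") bn_reset(l)
  })
  walk(model$stem)
  for (u in model$units) {
    for (br in u$branches) walk(br)
  }
  invisible(model)
}

model_params <- function(model) {
  list(stem = seq_params(model$stem),
       units = lapply(model$units, block_params),
       head = list(linear = model$head$linear$par))
}

model_set_params <- function(model, tree) {
  model$stem <- seq_set_params(model$stem, tree$stem)
  for (i in seq_along(model$units)) {
    model$units[[i]] <- block_set_params(model$units[[i]], tree$units[[i]])
  }
  model$head$linear$par <- tree$head$linear
  model
}

model_fwd <- function(model, x, train = FALSE) {
  s <- seq_forward(model$stem, x, train = train)
  h <- s$y
  ucaches <- vector("list", length(model$units))
  for (i in seq_along(model$units)) {
    r <- block_fwd(model$units[[i]], h, train = train)
    h <- r$y
    ucaches[[i]] <- r$cache
  }
  g <- layer_forward(model$head$gap, h)
  d <- layer_forward(model$head$dropout, g$y, train = train)
  l <- layer_forward(model$head$linear, d$y)
  list(logits = l$y,   # (n_classes, N)
       caches = list(stem = s$caches, units = ucaches,
                     gap = g$cache, dropout = d$cache, linear = l$cache))
}

model_bwd <- function(model, caches, dlogits) {
  r <- layer_backward(model$head$linear, caches$linear, dlogits)
  glin <- r$grads
  r <- layer_backward(model$head$dropout, caches$dropout, r$dx)
  r <- layer_backward(model$head$gap, caches$gap, r$dx)
  dy <- r$dx
  ugrads <- vector("list", length(model$units))
  for (i in rev(seq_along(model$units))) {
    b <- block_bwd(model$units[[i]], caches$units[[i]], dy)
    dy <- b$dx
    ugrads[[i]] <- b$grads
  }
  s <- seq_backward(model$stem, caches$stem, dy)
  list(grads = list(stem = s$grads, units = ugrads,
                    head = list(linear = glin)))
}

#' Forward pass of the classifier
#'
#' Deterministic in evaluation mode (dropout off): identical inputs give
#' identical logits. The model does not resize inputs; by default a batch
#' whose spatial size differs from the configured `input_size` is an error
#' (`strict = FALSE` lifts the check — global average pooling makes the
#' head independent of spatial size).
#'
#' @param model A `scn_model`.
#' @param batch Grayscale images: `(H, W)` matrix, `(H, W, N)` or
#'   `(H, W, 1, N)` array, values finite.
#' @param train Logical; `TRUE` enables dropout (stochastic).
#' @param strict Enforce `cfg$input_size` on the batch (default `TRUE`).
#' @return An `N x n_classes` matrix of logits (column 1 = GBM).
#' @export
forward <- function(model, batch, train = FALSE, strict = TRUE) {
  stopifnot(inherits(model, "scn_model"))
  x <- as_batch(batch)
  check_finite(x, "batch")
  if (strict && !all(dim(x)[1:2] == model$cfg$input_size)) {
    stop("batch is ", dim(x)[1L], "x", dim(x)[2L], " but the model expects ",
         model$cfg$input_size[1L], "x", model$cfg$input_size[2L],
         " (no silent resize)", call. = FALSE)
  }
  t(model_fwd(model, x, train = train)$logits)
}

# (H,W) / (H,W,N) / (H,W,1,N) -> (H,W,1,N); images are single-channel.
as_batch <- function(batch) {
  d <- dim(batch)
  if (is.null(d)) stop("batch must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) dim(batch) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(batch) <- c(d[1L], d[2L], 1L, d[3L])
  else if (length(d) == 4L) {
    if (d[3L] != 1L) stop("batch must be single-channel", call. = FALSE)
  } else stop("batch must have 2-4 dimensions", call. = FALSE)
  storage.mode(batch) <- "double"
  batch
}
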