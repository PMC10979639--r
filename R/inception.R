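# Inception unit variants.
#
# Five variants assembled from multi-scale convolution branches, following
# the classic inception lineage: A and B are 5-branch multi-scale blocks
# (1x1 / 3x3 / 5x5 / asymmetric / pooled) with a SCAT operator applied to
# the concatenated output; C uses asymmetric 1x3/3x1 factorized branches;
# D is the stride-2 grid-reduction block; E is the widened filter bank at
# the coarsest resolution. Same-padding throughout, stride 1 except in D.

#' Declarative specification of one inception unit
#'
#' @param variant One of `"SCAT_A"`, `"SCAT_B"`, `"C"`, `"D"`, `"E"`.
#'   SCAT attention is present exactly in the `SCAT_A` / `SCAT_B` variants;
#'   `D` is the only downsampling (stride-2) variant.
#' @param in_channels Channels of the incoming feature map.
#' @param branch_channels Optional integer vector of per-branch output
#'   widths (5 entries for A/B/C/E, 2 for D excluding its pooled
#'   pass-through branch). Default: each branch gets
#'   `max(1, floor(in_channels / 4))`.
#' @param attn_axis Softmax axis for the SCAT operator of A/B blocks.
#' @param reduction_ratio SCAT channel reduction (A/B blocks only).
#' @return A `block_spec` object; `out_channels` is the sum over branches.
#' @export
block_spec <- function(variant = c("SCAT_A", "SCAT_B", "C", "D", "E"),
                       in_channels, branch_channels = NULL,
                       attn_axis = "spatial", reduction_ratio = 4L) {
  variant <- match.arg(variant)
  in_channels <- as.integer(in_channels)
  if (in_channels < 1L) stop("in_channels must be >= 1", call. = FALSE)
  n_br <- if (variant == "D") 2L else 5L
  if (is.null(branch_channels)) {
    branch_channels <- rep(max(1L, in_channels %/% 4L), n_br)
  }
  branch_channels <- as.integer(branch_channels)
  if (length(branch_channels) != n_br || any(branch_channels < 1L)) {
    stop(variant, " blocks take ", n_br,
         " positive branch widths (pool pass-through excluded for D)",
         call. = FALSE)
  }
  kernel_menu <- switch(variant,
    SCAT_A = c("1x1", "3x3", "5x5", "pool", "1x3"),
    SCAT_B = c("1x1", "3x3", "3x3x2", "pool", "3x1"),
    C = c("1x1", "1x3-3x1", "3x1-1x3", "pool", "3x3"),
    D = c("3x3s2", "3x3-3x3s2", "pool"),
    E = c("1x1", "1x3", "3x1", "pool", "5x5"))
  downsamples <- variant == "D"
  out_channels <- sum(branch_channels) + if (downsamples) in_channels else 0L
  structure(list(variant = variant, in_channels = in_channels,
                 branch_channels = branch_channels, kernel_menu = kernel_menu,
                 has_scat = variant %in% c("SCAT_A", "SCAT_B"),
                 downsamples = downsamples, out_channels = out_channels,
                 attn_axis = attn_axis,
                 reduction_ratio = as.integer(reduction_ratio)),
            class = "block_spec")
}

# A branch is a sequence of conv/pool layers; convs use same-padding and
# are followed by batch normalization and ReLU (inception-family practice;
# without normalization a stack of 11 thin multi-branch units does not
# train reliably).
conv_relu <- function(cin, cout, kh, kw = kh, stride = 1L) {
  list(layer_conv2d(cin, cout, kh, kw, stride), layer_batchnorm(cout),
       layer_relu())
}

build_branches <- function(spec) {
  cin <- spec$in_channels
  bw <- spec$branch_channels
  switch(spec$variant,
    SCAT_A = list(
      conv_relu(cin, bw[1L], 1L),
      c(conv_relu(cin, bw[2L], 1L), conv_relu(bw[2L], bw[2L], 3L)),
      c(conv_relu(cin, bw[3L], 1L), conv_relu(bw[3L], bw[3L], 5L)),
      c(list(layer_avgpool(3L, 1L, 1L)), conv_relu(cin, bw[4L], 1L)),
      c(conv_relu(cin, bw[5L], 1L), conv_relu(bw[5L], bw[5L], 1L, 3L))),
    SCAT_B = list(
      conv_relu(cin, bw[1L], 1L),
      c(conv_relu(cin, bw[2L], 1L), conv_relu(bw[2L], bw[2L], 3L)),
      c(conv_relu(cin, bw[3L], 1L), conv_relu(bw[3L], bw[3L], 3L),
        conv_relu(bw[3L], bw[3L], 3L)),
      c(list(layer_avgpool(3L, 1L, 1L)), conv_relu(cin, bw[4L], 1L)),
      c(conv_relu(cin, bw[5L], 1L), conv_relu(bw[5L], bw[5L], 3L, 1L))),
    C = list(
      conv_relu(cin, bw[1L], 1L),
      c(conv_relu(cin, bw[2L], 1L), conv_relu(bw[2L], bw[2L], 1L, 3L),
        conv_relu(bw[2L], bw[2L], 3L, 1L)),
      c(conv_relu(cin, bw[3L], 1L), conv_relu(bw[3L], bw[3L], 3L, 1L),
        conv_relu(bw[3L], bw[3L], 1L, 3L)),
      c(list(layer_avgpool(3L, 1L, 1L)), conv_relu(cin, bw[4L], 1L)),
      c(conv_relu(cin, bw[5L], 1L), conv_relu(bw[5L], bw[5L], 3L))),
    D = list(
      c(conv_relu(cin, bw[1L], 1L), conv_relu(bw[1L], bw[1L], 3L, 3L, 2L)),
      c(conv_relu(cin, bw[2L], 1L), conv_relu(bw[2L], bw[2L], 3L),
        conv_relu(bw[2L], bw[2L], 3L, 3L, 2L)),
      list(layer_maxpool(3L, 2L, 1L))),
    E = list(
      conv_relu(cin, bw[1L], 1L),
      c(conv_relu(cin, bw[2L], 1L), conv_relu(bw[2L], bw[2L], 1L, 3L)),
      c(conv_relu(cin, bw[3L], 1L), conv_relu(bw[3L], bw[3L], 3L, 1L)),
      c(list(layer_avgpool(3L, 1L, 1L)), conv_relu(cin, bw[4L], 1L)),
      c(conv_relu(cin, bw[5L], 1L), conv_relu(bw[5L], bw[5L], 5L))))
}

#' Build an inception unit from its specification
#'
#' Instantiates the parallel branches (Kaiming-uniform initialized from the
#' current RNG stream) and, for the SCAT variants, the attention operator
#' applied to the concatenated branch output.
#'
#' @param spec A [block_spec()].
#' @return An `inception_block` object usable with [block_forward()].
#' @export
build_block <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  scat <- NULL
  if (spec$has_scat) {
    scat <- layer_scat(spec$out_channels, spec$reduction_ratio,
                       attn_axis = spec$attn_axis)
  }
  structure(list(spec = spec, branches = build_branches(spec), scat = scat),
            class = "inception_block")
}

concat_channels <- function(parts) {
  d1 <- dim(parts[[1L]])
  chans <- vapply(parts, function(p) dim(p)[3L], integer(1))
  out <- array(0, dim = c(d1[1L], d1[2L], sum(chans), d1[4L]))
  at <- 0L
  for (p in parts) {
    cp <- dim(p)[3L]
    out[, , (at + 1L):(at + cp), ] <- p
    at <- at + cp
  }
  out
}

block_fwd <- function(block, x, train = FALSE) {
  if (dim(x)[3L] != block$spec$in_channels) {
    stop("block expects ", block$spec$in_channels, " channels, got ",
         dim(x)[3L], call. = FALSE)
  }
  runs <- lapply(block$branches, seq_forward, x = x, train = train)
  y <- concat_channels(lapply(runs, `[[`, "y"))
  scat_cache <- NULL
  if (!is.null(block$scat)) {
    r <- layer_forward(block$scat, y, train = train)
    scat_cache <- r$cache
    y <- r$y
  }
  list(y = y,
       cache = list(branch_caches = lapply(runs, `[[`, "caches"),
                    branch_channels = vapply(runs, function(r) dim(r$y)[3L],
                                             integer(1)),
                    scat_cache = scat_cache))
}

block_bwd <- function(block, cache, dy) {
  scat_grads <- list()   # congruent with block_params() for non-SCAT blocks
  if (!is.null(block$scat)) {
    r <- layer_backward(block$scat, cache$scat_cache, dy)
    scat_grads <- r$grads
    dy <- r$dx
  }
  at <- 0L
  dx <- NULL
  branch_grads <- vector("list", length(block$branches))
  for (i in seq_along(block$branches)) {
    cp <- cache$branch_channels[i]
    dpart <- dy[, , (at + 1L):(at + cp), , drop = FALSE]
    at <- at + cp
    r <- seq_backward(block$branches[[i]], cache$branch_caches[[i]], dpart)
    branch_grads[[i]] <- r$grads
    dx <- if (is.null(dx)) r$dx else dx + r$dx
  }
  list(dx = dx, grads = list(branches = branch_grads, scat = scat_grads))
}

block_params <- function(block) {
  list(branches = lapply(block$branches, seq_params),
       scat = if (is.null(block$scat)) list() else block$scat$par)
}

block_set_params <- function(block, tree) {
  for (i in seq_along(block$branches)) {
    block$branches[[i]] <- seq_set_params(block$branches[[i]],
                                          tree$branches[[i]])
  }
  if (!is.null(block$scat)) block$scat$par <- tree$scat
  block
}

#' Run a feature map through an inception unit
#'
#' Branches are computed independently on the same input and concatenated
#' along the channel axis in declared branch order; SCAT variants then
#' reweight the concatenated map.
#'
#' @param block An `inception_block` from [build_block()].
#' @param x A feature map (matrix, `(H,W,C)` array, or `(H,W,C,N)` batch).
#' @return The output feature map, `(H, W, out_channels, N)`.
#' @export
block_forward <- function(block, x) {
  stopifnot(inherits(block, "inception_block"))
  block_fwd(block, as_feature_map(x), train = FALSE)$y
}
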