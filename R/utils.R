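# Internal helpers shared across modules.

# Coerce a slice / image to an (H, W, C, N) activation array.
as_feature_map <- function(x) {
  if (is.matrix(x)) {
    dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
    return(x)
  }
  d <- dim(x)
  if (is.null(d)) stop("feature map must be a matrix or array", call. = FALSE)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 4L) stop("feature map must have 2-4 dimensions", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# Map a function over congruent nested lists of numeric arrays (a
# parameter/gradient "tree"); preserves structure and dim attributes.
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1L]]
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) {
      out[[i]] <- do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = function(p) length(p)) {
  if (is.list(tree)) sum(vapply(tree, tree_sum, numeric(1), f = f)) else f(tree)
}

# Derive a stream of independent 31-bit seeds from one master seed.
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max %/% 2L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
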