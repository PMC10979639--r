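# Region dataset construction and augmentation.
#
# Three region datasets are built per cohort — core, edema, overall
# (core + edema) — by cropping each slice to the bounding box of the
# region mask, padding to square, resizing to the network input size and
# min-max normalizing. Augmentation multiplies the corpus by a fixed
# factor with seeded random rotation, translation and contrast jitter;
# originals are always retained.

#' Min-max normalize an image to the unit interval
#'
#' Constant images map to all zeros. The per-image mean of the normalized
#' image is recorded in the `"center_mean"` attribute; batch assembly
#' subtracts it (data centering), so the network sees zero-mean inputs.
#'
#' @param image Finite numeric matrix.
#' @return The rescaled matrix with attribute `center_mean`.
#' @export
normalize_and_center <- function(image) {
  check_finite(image, "image")
  rng <- range(image)
  out <- if (rng[2L] > rng[1L]) (image - rng[1L]) / (rng[2L] - rng[1L])
         else image * 0
  attr(out, "center_mean") <- mean(out)
  out
}

#' Bilinear resize
#'
#' @param img Numeric matrix.
#' @param out_h,out_w Output size.
#' @return Resized matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w = out_h) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # pixel-center alignment
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h - 0.5, 0), h - 1)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w - 0.5, 0), w - 1)
  y0 <- floor(ys); x0 <- floor(xs)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- ys - y0; fx <- xs - x0
  a <- img[y0 + 1, x0 + 1, drop = FALSE] * outer(1 - fy, 1 - fx)
  b <- img[y0 + 1, x1 + 1, drop = FALSE] * outer(1 - fy, fx)
  cc <- img[y1 + 1, x0 + 1, drop = FALSE] * outer(fy, 1 - fx)
  d <- img[y1 + 1, x1 + 1, drop = FALSE] * outer(fy, fx)
  a + b + cc + d
}

# Bilinear sampling at arbitrary (row, col) coordinates, 1-based, with
# constant fill outside the frame.
sample_bilinear <- function(img, rows, cols, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  inside <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  r <- pmin(pmax(rows, 1), h); cl <- pmin(pmax(cols, 1), w)
  r0 <- floor(r); c0 <- floor(cl)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- r - r0; fc <- cl - c0
  v <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
       img[cbind(r0, c1)] * (1 - fr) * fc +
       img[cbind(r1, c0)] * fr * (1 - fc) +
       img[cbind(r1, c1)] * fr * fc
  v[!inside] <- fill
  v
}

#' Rotate and translate an image about its center
#'
#' @param img Numeric matrix.
#' @param angle Rotation in degrees (counter-clockwise).
#' @param dx,dy Translation in pixels (columns, rows).
#' @param fill Value for pixels sampled outside the frame.
#' @return Transformed matrix of the same size.
#' @export
affine_transform <- function(img, angle = 0, dx = 0, dy = 0, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- angle * pi / 180
  rows <- matrix(rep(seq_len(h), times = w), h)
  cols <- matrix(rep(seq_len(w), each = h), h)
  ry <- rows - cy - dy
  rx <- cols - cx - dx
  src_r <- cos(th) * ry + sin(th) * rx + cy
  src_c <- -sin(th) * ry + cos(th) * rx + cx
  matrix(sample_bilinear(img, as.numeric(src_r), as.numeric(src_c), fill), h, w)
}

region_mask <- function(case, region, s) {
  switch(region,
         core = case$core_masks[[s]],
         edema = case$edema_masks[[s]],
         overall = case$core_masks[[s]] | case$edema_masks[[s]],
         stop("region must be one of 'core', 'edema', 'overall'",
              call. = FALSE))
}

#' Build region slice records for one case
#'
#' Crops each of the case's 3 slices to the bounding box of the requested
#' region mask (`overall` = core + edema), expands to a square window
#' (clipped at frame borders, zero-padded past them), resizes to
#' `size x size` and min-max normalizes.
#'
#' @param case A `case_record`.
#' @param region `"core"`, `"edema"` or `"overall"`.
#' @param size Output side length (default 128).
#' @param margin Extra pixels around the mask bounding box (default 2).
#' @param mask_out If `TRUE`, zero pixels outside the region mask before
#'   cropping.
#' @return A list of 3 `slice_record`s: `case_id`, `class_label`, `region`,
#'   `slice`, `image` (normalized), `provenance = "original"`, and the
#'   crop bookkeeping (`mask_bbox` = raw row/col extremes of the mask,
#'   `bbox` = square crop window actually used).
#' @export
extract_region <- function(case, region = c("overall", "core", "edema"),
                           size = 128L, margin = 2L, mask_out = FALSE) {
  region <- match.arg(region)
  stopifnot(inherits(case, "case_record"))
  lapply(1:3, function(s) {
    msk <- region_mask(case, region, s)
    if (!any(msk)) {
      stop("empty ", region, " mask in case ", case$case_id, " slice ", s,
           call. = FALSE)
    }
    img <- case$slices[[s]]
    if (mask_out) img <- img * msk
    idx <- which(msk, arr.ind = TRUE)
    rb <- range(idx[, 1L]); cb <- range(idx[, 2L])
    r0 <- rb[1L] - margin; r1 <- rb[2L] + margin
    c0 <- cb[1L] - margin; c1 <- cb[2L] + margin
    # expand the shorter side symmetrically to a square window
    side <- max(r1 - r0, c1 - c0)
    r0 <- r0 - (side - (r1 - r0)) %/% 2L; r1 <- r0 + side
    c0 <- c0 - (side - (c1 - c0)) %/% 2L; c1 <- c0 + side
    crop <- matrix(0, side + 1L, side + 1L)
    rr <- max(r0, 1L):min(r1, nrow(img))
    cc <- max(c0, 1L):min(c1, ncol(img))
    crop[rr - r0 + 1L, cc - c0 + 1L] <- img[rr, cc]
    image <- normalize_and_center(resize_bilinear(crop, size, size))
    structure(list(case_id = case$case_id, class_label = case$class_label,
                   region = region, slice = s, image = image,
                   provenance = "original", seed_used = NA_integer_,
                   mask_bbox = c(rb, cb), bbox = c(r0, r1, c0, c1)),
              class = "slice_record")
  })
}

#' Region slice records for a whole cohort
#'
#' @param cohort An `scn_cohort`.
#' @inheritParams extract_region
#' @return A flat list of `slice_record`s (3 per case).
#' @export
extract_region_dataset <- function(cohort, region = "overall", size = 128L,
                                   margin = 2L, mask_out = FALSE) {
  stopifnot(inherits(cohort, "scn_cohort"))
  do.call(c, lapply(cohort$cases, extract_region, region = region,
                    size = size, margin = margin, mask_out = mask_out))
}

#' Augmentation configuration
#'
#' Defaults follow the pipeline's stated world: the corpus is multiplied by
#' `factor` (originals retained, `factor - 1` variants each), with random
#' rotation, integer translation and linear contrast jitter around the
#' image mean; grayscale contrast jitter stands in for "color contrast"
#' transforms.
#'
#' @param factor Total multiplication factor (default 3).
#' @param rotation_range Max |rotation| in degrees (default 15).
#' @param translation_range Max |shift| in pixels (default 8).
#' @param contrast_range Multiplicative contrast factor range
#'   (default `c(0.8, 1.2)`).
#' @param seed Master augmentation seed.
#' @return An `augment_config` object.
#' @export
augment_config <- function(factor = 3L, rotation_range = 15,
                           translation_range = 8,
                           contrast_range = c(0.8, 1.2), seed = 1L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1", call. = FALSE)
  structure(list(factor = factor, rotation_range = rotation_range,
                 translation_range = translation_range,
                 contrast_range = contrast_range, seed = as.integer(seed)),
            class = "augment_config")
}

augment_one <- function(rec, vseed, cfg) {
  set.seed(vseed)
  angle <- runif(1, -cfg$rotation_range, cfg$rotation_range)
  dx <- round(runif(1, -cfg$translation_range, cfg$translation_range))
  dy <- round(runif(1, -cfg$translation_range, cfg$translation_range))
  ct <- runif(1, cfg$contrast_range[1L], cfg$contrast_range[2L])
  img <- affine_transform(rec$image, angle, dx, dy, fill = 0)
  img <- pmin(pmax(mean(img) + ct * (img - mean(img)), 0), 1)
  attr(img, "center_mean") <- mean(img)
  rec$image <- img
  rec$provenance <- "augmented"
  rec$seed_used <- vseed
  rec
}

#' Augment a set of slice records
#'
#' Output size is exactly `factor x` the input size: each original is kept
#' (provenance `"original"`) followed by `factor - 1` transformed variants,
#' each recording the seed that produced it. Case ids, class labels and
#' region tags are never changed. Deterministic given `cfg$seed`.
#'
#' @param slices List of `slice_record`s.
#' @param cfg An [augment_config()].
#' @return List of `factor * length(slices)` records.
#' @export
augment_dataset <- function(slices, cfg = augment_config()) {
  stopifnot(inherits(cfg, "augment_config"))
  if (cfg$factor == 1L || length(slices) == 0L) return(slices)
  nv <- cfg$factor - 1L
  vseeds <- matrix(derive_seeds(cfg$seed, length(slices) * nv), ncol = nv)
  out <- vector("list", cfg$factor * length(slices))
  j <- 0L
  for (i in seq_along(slices)) {
    out[[j <- j + 1L]] <- slices[[i]]
    for (v in seq_len(nv)) {
      out[[j <- j + 1L]] <- augment_one(slices[[i]], vseeds[i, v], cfg)
    }
  }
  out
}
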