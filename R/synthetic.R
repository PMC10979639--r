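# Synthetic lesion phantoms.
#
# Stand-in for a private clinical ceT1W dataset: per-case sets of 3 axial
# slices with nested core/edema masks. GBM-like lesions are irregular and
# ring-enhancing (bright rim around a dark necrotic center, broad edema
# halo); MET-like lesions are near-circular and homogeneously enhancing.
# Boundary irregularity is realized as a low-order random harmonic
# perturbation of the lesion radius — an emulation choice, not a claim
# about tumor geometry.

#' Appearance parameters of one lesion phenotype
#'
#' Defaults encode the two phenotypes: `"GBM"` has `rim_intensity >
#' center_intensity` (ring enhancement) and positive boundary
#' irregularity; `"MET"` is homogeneous (`center_intensity ==
#' rim_intensity`) and near-circular. All intensities are in `[0, 1]`
#' (fractions of the display range); radii are in pixels.
#'
#' @param class_label `"GBM"` or `"MET"`.
#' @param core_radius_range Length-2 range of the mean core radius (pixels).
#' @param rim_intensity,center_intensity,edema_intensity,background_intensity
#'   Mean intensities of the enhancing rim, lesion center, edema halo and
#'   brain background.
#' @param boundary_irregularity Amplitude of the harmonic radius
#'   perturbation (0 = perfect circle).
#' @param edema_halo_ratio Outer edema radius as a multiple of the core
#'   radius (> 1).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @return A `phenotype_params` object.
#' @export
phenotype_params <- function(class_label = c("GBM", "MET"),
                             core_radius_range = NULL,
                             rim_intensity = 0.85,
                             center_intensity = NULL,
                             edema_intensity = 0.55,
                             background_intensity = 0.15,
                             boundary_irregularity = NULL,
                             edema_halo_ratio = NULL,
                             noise_sd = 0.02) {
  class_label <- match.arg(class_label)
  if (class_label == "GBM") {
    core_radius_range <- core_radius_range %||% c(10, 18)
    center_intensity <- center_intensity %||% 0.25
    boundary_irregularity <- boundary_irregularity %||% 0.25
    edema_halo_ratio <- edema_halo_ratio %||% 1.8
  } else {
    core_radius_range <- core_radius_range %||% c(8, 14)
    center_intensity <- center_intensity %||% rim_intensity
    boundary_irregularity <- boundary_irregularity %||% 0.02
    edema_halo_ratio <- edema_halo_ratio %||% 1.6
  }
  if (edema_halo_ratio <= 1) stop("edema_halo_ratio must be > 1", call. = FALSE)
  if (noise_sd < 0 || boundary_irregularity < 0) {
    stop("noise_sd and boundary_irregularity must be >= 0", call. = FALSE)
  }
  structure(list(class_label = class_label,
                 core_radius_range = core_radius_range,
                 rim_intensity = rim_intensity,
                 center_intensity = center_intensity,
                 edema_intensity = edema_intensity,
                 background_intensity = background_intensity,
                 boundary_irregularity = boundary_irregularity,
                 edema_halo_ratio = edema_halo_ratio,
                 noise_sd = noise_sd),
            class = "phenotype_params")
}

box_blur <- function(img) {
  x <- array(img, dim = c(nrow(img), ncol(img), 1L, 1L))
  matrix(cpp_avgpool_forward(x, 3L, 1L, 1L), nrow(img), ncol(img))
}

#' Generate one synthetic case: 3 slices with core and edema masks
#'
#' Fully reproducible from `seed`. The lesion is placed off-center with
#' jitter; each of the 3 slices perturbs the radius and harmonic phases
#' slightly, emulating adjacent axial slices through one lesion. Masks are
#' nested and disjoint: `core` is the lesion interior, `edema` the
#' surrounding halo annulus.
#'
#' @param params A [phenotype_params()].
#' @param seed Integer seed.
#' @param image_size Side length of the square slice (default 128).
#' @return A `case_record`: `slices`, `core_masks`, `edema_masks` (lists of
#'   3 matrices), `class_label`, `seed`.
#' @export
generate_case <- function(params, seed, image_size = 128L) {
  stopifnot(inherits(params, "phenotype_params"))
  image_size <- as.integer(image_size)
  max_extent <- params$core_radius_range[2L] * 1.5 * params$edema_halo_ratio
  if (max_extent >= image_size / 2) {
    stop("lesion radii exceed the image size: reduce core_radius_range or ",
         "edema_halo_ratio, or enlarge image_size", call. = FALSE)
  }
  set.seed(as.integer(seed))

  cx <- image_size / 2 + runif(1, -0.12, 0.12) * image_size
  cy <- image_size / 2 + runif(1, -0.12, 0.12) * image_size
  r0 <- runif(1, params$core_radius_range[1L], params$core_radius_range[2L])
  gain <- runif(1, 0.95, 1.05)       # per-case intensity variation
  harmonics <- 2:5
  amp <- runif(length(harmonics), -1, 1) * params$boundary_irregularity /
    sqrt(length(harmonics))

  xs <- matrix(rep(seq_len(image_size), each = image_size), image_size)
  ys <- matrix(rep(seq_len(image_size), times = image_size), image_size)
  dx <- xs - cx; dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)

  slices <- core_masks <- edema_masks <- vector("list", 3L)
  for (s in 1:3) {
    rs <- r0 * runif(1, 0.92, 1.08)
    phase <- runif(length(harmonics), 0, 2 * pi)
    pert <- Reduce(`+`, Map(function(k, a, ph) a * cos(k * th + ph),
                            harmonics, amp, phase))
    rb <- rs * pmax(1 + pert, 0.35)
    core <- rr <= rb
    edema <- rr > rb & rr <= params$edema_halo_ratio * rb

    img <- matrix(params$background_intensity, image_size, image_size)
    img[edema] <- params$edema_intensity * gain
    inner <- core & (rr <= 0.55 * rb)
    img[core] <- params$rim_intensity * gain
    img[inner] <- params$center_intensity * gain
    img <- box_blur(img)
    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(image_size^2, 0, params$noise_sd),
                          image_size)
    }
    slices[[s]] <- pmin(pmax(img, 0), 1)
    core_masks[[s]] <- core
    edema_masks[[s]] <- edema
  }
  structure(list(case_id = NA_character_, class_label = params$class_label,
                 slices = slices, core_masks = core_masks,
                 edema_masks = edema_masks, image_size = image_size,
                 seed = as.integer(seed)),
            class = "case_record")
}

#' Generate a two-class cohort of synthetic cases
#'
#' Per-case seeds are derived deterministically from `seed`, so the whole
#' cohort is reproducible. With `out_dir` set, each slice and its two masks
#' are written as NIfTI (`.nii.gz`) files plus a `manifest.csv`; otherwise
#' the cohort stays in memory.
#'
#' @param n_gbm,n_met Number of GBM-like and MET-like cases.
#' @param seed Master seed.
#' @param out_dir Optional output directory for NIfTI files and manifest.
#' @param image_size Slice side length (default 128).
#' @param gbm_params,met_params Phenotypes; defaults from
#'   [phenotype_params()].
#' @return An `scn_cohort`: `$cases` (list of `case_record`) and
#'   `$manifest` (one row per slice: `case_id`, `class_label`, `slice`,
#'   `split`, `slice_path`, `core_mask_path`, `edema_mask_path`).
#' @export
generate_cohort <- function(n_gbm, n_met, seed = 1L, out_dir = NULL,
                            image_size = 128L,
                            gbm_params = phenotype_params("GBM"),
                            met_params = phenotype_params("MET")) {
  n_gbm <- as.integer(n_gbm); n_met <- as.integer(n_met)
  if (is.na(n_gbm) || is.na(n_met) || n_gbm < 0L || n_met < 0L) {
    stop("n_gbm and n_met must be non-negative integers", call. = FALSE)
  }
  n <- n_gbm + n_met
  labels <- c(rep("GBM", n_gbm), rep("MET", n_met))
  seeds <- derive_seeds(seed, n)
  ids <- sprintf("%s_%03d", labels,
                 c(seq_len(n_gbm), seq_len(n_met)))

  cases <- vector("list", n)
  rows <- vector("list", n)
  write_files <- !is.null(out_dir)
  if (write_files) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  for (i in seq_len(n)) {
    p <- if (labels[i] == "GBM") gbm_params else met_params
    cs <- generate_case(p, seeds[i], image_size)
    cs$case_id <- ids[i]
    cases[[i]] <- cs
    paths <- matrix(NA_character_, 3L, 3L)
    if (write_files) {
      for (s in 1:3) {
        paths[s, ] <- file.path(out_dir, sprintf(
          "%s_s%d_%s.nii.gz", ids[i], s, c("img", "core", "edema")))
        write_nifti(cs$slices[[s]], paths[s, 1L])
        write_nifti(cs$core_masks[[s]] * 1, paths[s, 2L], datatype = "int16")
        write_nifti(cs$edema_masks[[s]] * 1, paths[s, 3L], datatype = "int16")
      }
    }
    rows[[i]] <- data.frame(case_id = ids[i], class_label = labels[i],
                            slice = 1:3, split = NA_character_,
                            slice_path = paths[, 1L],
                            core_mask_path = paths[, 2L],
                            edema_mask_path = paths[, 3L],
                            stringsAsFactors = FALSE)
  }
  manifest <- if (n > 0L) do.call(rbind, rows) else
    data.frame(case_id = character(), class_label = character(),
               slice = integer(), split = character(),
               slice_path = character(), core_mask_path = character(),
               edema_mask_path = character(), stringsAsFactors = FALSE)
  if (write_files) {
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  structure(list(cases = cases, manifest = manifest, seed = as.integer(seed)),
            class = "scn_cohort")
}

#' Load a cohort previously written by [generate_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the NIfTI files.
#' @return An `scn_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv in ", dir, call. = FALSE)
  manifest <- read.csv(mf, stringsAsFactors = FALSE)
  manifest$split <- as.character(manifest$split)
  ids <- unique(manifest$case_id)
  cases <- lapply(ids, function(id) {
    sub <- manifest[manifest$case_id == id, ]
    sub <- sub[order(sub$slice), ]
    structure(list(
      case_id = id, class_label = sub$class_label[1L],
      slices = lapply(sub$slice_path, read_nifti),
      core_masks = lapply(sub$core_mask_path,
                          function(p) read_nifti(p) > 0.5),
      edema_masks = lapply(sub$edema_mask_path,
                           function(p) read_nifti(p) > 0.5),
      image_size = nrow(read_nifti(sub$slice_path[1L])),
      seed = NA_integer_), class = "case_record")
  })
  structure(list(cases = cases, manifest = manifest, seed = NA_integer_),
            class = "scn_cohort")
}

#' Threshold rule on the rim/center intensity ratio
#'
#' The trivial classifier that separates noise-free default phenotypes
#' perfectly: ring-enhancing (GBM-like) lesions have a bright rim around a
#' dark center, so the ratio of mean rim intensity to mean center intensity
#' exceeds 1; homogeneous (MET-like) lesions sit near 1. Used as the
#' separability check of the generator, not as a serious classifier.
#'
#' @param case A `case_record`.
#' @param threshold Ratio above which a case is called GBM (default 1.3).
#' @return A list with the per-slice ratios and the predicted label.
#' @export
ring_ratio_predict <- function(case, threshold = 1.3) {
  ratios <- vapply(1:3, function(s) {
    core <- case$core_masks[[s]]
    img <- case$slices[[s]]
    idx <- which(core, arr.ind = TRUE)
    ctr <- colMeans(idx)
    r <- sqrt((idx[, 1L] - ctr[1L])^2 + (idx[, 2L] - ctr[2L])^2)
    rmax <- stats::quantile(r, 0.95)
    inner <- r <= 0.45 * rmax
    outer <- r >= 0.75 * rmax
    mean(img[core][outer]) / mean(img[core][inner])
  }, numeric(1))
  list(ratios = ratios,
       label = if (mean(ratios) > threshold) "GBM" else "MET")
}
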