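# Region extraction, normalization, augmentation.

test_that("normalize_and_center applies the min-max formula", {
  img <- matrix(c(10, 12, 15, 20), 2)
  expect_equal(unclass(normalize_and_center(img)),
               (img - 10) / 10, ignore_attr = TRUE)
  # constant image -> all zeros
  expect_equal(as.numeric(normalize_and_center(matrix(7, 3, 3))), rep(0, 9))
  # range contract on random input
  set.seed(1)
  out <- normalize_and_center(matrix(rnorm(100), 10))
  expect_equal(range(out), c(0, 1))
  expect_equal(attr(out, "center_mean"), mean(out))
  expect_error(normalize_and_center(matrix(c(1, NA), 1)), "non-finite")
})

# hand-built case with rectangular masks at known coordinates
box_case <- function(core_rows = 40:59, core_cols = 50:69) {
  img <- matrix(0.1, 128, 128)
  core <- matrix(FALSE, 128, 128)
  core[core_rows, core_cols] <- TRUE
  edema <- matrix(FALSE, 128, 128)
  edema[(min(core_rows) - 10):(max(core_rows) + 10),
        (min(core_cols) - 10):(max(core_cols) + 10)] <- TRUE
  edema <- edema & !core
  img[edema] <- 0.5; img[core] <- 0.9
  structure(list(case_id = "box_001", class_label = "GBM",
                 slices = list(img, img, img),
                 core_masks = list(core, core, core),
                 edema_masks = list(edema, edema, edema),
                 image_size = 128L, seed = 0L), class = "case_record")
}

test_that("extract_region crops the mask bounding box", {
  cs <- box_case()
  recs <- extract_region(cs, "core", size = 64)
  expect_length(recs, 3L)
  expect_identical(recs[[1]]$mask_bbox, c(40L, 59L, 50L, 69L))
  # overall crop covers at least the core crop
  ov <- extract_region(cs, "overall", size = 64)
  area <- function(r) (r$bbox[2] - r$bbox[1]) * (r$bbox[4] - r$bbox[3])
  expect_gte(area(ov[[1]]), area(recs[[1]]))
  expect_identical(recs[[1]]$region, "core")
  expect_identical(dim(recs[[1]]$image), c(64L, 64L))
})

test_that("crop offsets match a brute-force mask scan", {
  set.seed(51)
  for (rep in 1:5) {
    cs <- generate_case(phenotype_params(sample(c("GBM", "MET"), 1)),
                        seed = 100 + rep)
    cs$case_id <- "scan"
    region <- sample(c("core", "edema", "overall"), 1)
    rec <- extract_region(cs, region, size = 32)[[2]]
    msk <- switch(region, core = cs$core_masks[[2]],
                  edema = cs$edema_masks[[2]],
                  overall = cs$core_masks[[2]] | cs$edema_masks[[2]])
    # independent scan: loop over all pixels
    rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
    for (r in 1:nrow(msk)) for (cc in 1:ncol(msk)) if (msk[r, cc]) {
      rmin <- min(rmin, r); rmax <- max(rmax, r)
      cmin <- min(cmin, cc); cmax <- max(cmax, cc)
    }
    expect_identical(rec$mask_bbox, as.integer(c(rmin, rmax, cmin, cmax)))
  }
})

test_that("an empty region mask is a data error naming the case", {
  cs <- box_case()
  cs$core_masks <- lapply(cs$core_masks, function(m) m & FALSE)
  expect_error(extract_region(cs, "core"), "box_001")
})

test_that("augmentation obeys the count law and keeps provenance", {
  cohort <- tiny_cohort(2, 2, seed = 61)
  slices <- extract_region_dataset(cohort, "overall", size = 32)
  cfg <- augment_config(factor = 3, seed = 7)
  out <- augment_dataset(slices, cfg)
  expect_length(out, 3L * length(slices))
  expect_identical(sum(vapply(out, `[[`, character(1), "provenance") ==
                         "original"), length(slices))
  # tags are never changed
  expect_identical(unique(vapply(out, `[[`, character(1), "region")),
                   "overall")
  expect_setequal(vapply(out, `[[`, character(1), "case_id"),
                  vapply(slices, `[[`, character(1), "case_id"))
  # factor 1 is the identity
  expect_identical(augment_dataset(slices, augment_config(factor = 1)),
                   slices)
  # seeded determinism is bitwise
  expect_identical(augment_dataset(slices, cfg),
                   out)
  expect_false(identical(augment_dataset(slices, augment_config(factor = 3,
                                                                seed = 8)),
                         out))
})

test_that("default-range transforms keep >= 90% of lesion pixels in frame", {
  cohort <- tiny_cohort(2, 2, seed = 71)
  cfg <- augment_config(seed = 3)
  set.seed(9)
  for (cs in cohort$cases) {
    lesion <- (cs$core_masks[[1]] | cs$edema_masks[[1]]) * 1
    for (i in 1:3) {
      angle <- runif(1, -cfg$rotation_range, cfg$rotation_range)
      dx <- round(runif(1, -cfg$translation_range, cfg$translation_range))
      dy <- round(runif(1, -cfg$translation_range, cfg$translation_range))
      moved <- affine_transform(lesion, angle, dx, dy)
      expect_gte(sum(moved), 0.9 * sum(lesion))
    }
  }
})

test_that("affine_transform and resize_bilinear have exact identity limits", {
  set.seed(81)
  img <- matrix(runif(64 * 64), 64)
  expect_identical(resize_bilinear(img, 64, 64), img)
  expect_equal(affine_transform(img, 0, 0, 0), img, tolerance = 1e-12)
  # pure translation moves content exactly for integer shifts
  sh <- affine_transform(img, 0, dx = 3, dy = -2)
  expect_equal(sh[10, 10], img[12, 7], tolerance = 1e-12)
})
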