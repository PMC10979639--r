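# Fold construction, confusion metrics, ROC/AUC, aggregation.

test_that("make_folds partitions 251 cases into sizes {51,50,50,50,50}", {
  mf <- fake_manifest(127, 124)
  fs <- make_folds(mf, k = 5, seed = 1)
  sizes <- sort(vapply(fs$folds, length, integer(1)), decreasing = TRUE)
  expect_identical(sizes, c(51L, 50L, 50L, 50L, 50L))
  all_ids <- unlist(fs$folds)
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_setequal(all_ids, unique(mf$case_id))
  # stratification: per-fold class counts within 1 of proportional
  for (f in fs$folds) {
    n_gbm <- sum(grepl("^GBM", f))
    expect_lte(abs(n_gbm - length(f) * 127 / 251), 1)
  }
})

test_that("make_folds with 5 GBM + 5 MET and k = 5 gives 1 + 1 per fold", {
  fs <- make_folds(fake_manifest(5, 5), k = 5, seed = 3)
  for (f in fs$folds) {
    expect_length(f, 2L)
    expect_identical(sum(grepl("^GBM", f)), 1L)
  }
  expect_error(make_folds(fake_manifest(2, 1), k = 5), "folds")
})

test_that("split_fixed reproduces a stratified 207/44 partition", {
  mf <- fake_manifest(127, 124)
  sp <- split_fixed(mf, n_train = 207, seed = 2)
  expect_length(sp$train, 207L)
  expect_length(sp$test, 44L)
  expect_length(intersect(sp$train, sp$test), 0L)
  # proportional stratification: 105 GBM / 102 MET in training
  expect_identical(sum(grepl("^GBM", sp$train)), 105L)
  expect_identical(sum(grepl("^MET", sp$train)), 102L)
})

test_that("confusion_counts matches enumeration", {
  cc <- confusion_counts(c("GBM", "MET"), c("GBM", "MET"))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(c("GBM", "GBM", "MET", "MET"),
                          c("MET", "GBM", "GBM", "MET"))
  expect_identical(c(cc2$TP, cc2$FN, cc2$FP, cc2$TN), c(1L, 1L, 1L, 1L))
  expect_error(confusion_counts("GBM", c("GBM", "MET")), "length")
  expect_error(confusion_counts("GBM", "tumor"), "labels")
})

test_that("confusion_counts equals a per-sample loop tally on random data", {
  set.seed(91)
  truth <- sample(c("GBM", "MET"), 100, replace = TRUE)
  pred <- sample(c("GBM", "MET"), 100, replace = TRUE)
  cc <- confusion_counts(truth, pred)
  tp <- tn <- fp <- fn <- 0L
  for (i in 1:100) {
    if (truth[i] == "GBM" && pred[i] == "GBM") tp <- tp + 1L
    if (truth[i] == "MET" && pred[i] == "MET") tn <- tn + 1L
    if (truth[i] == "MET" && pred[i] == "GBM") fp <- fp + 1L
    if (truth[i] == "GBM" && pred[i] == "MET") fn <- fn + 1L
  }
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
  # composed metrics agree with a direct per-sample computation
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, mean(truth == pred))
  expect_equal(m$sensitivity, mean(pred[truth == "GBM"] == "GBM"))
  expect_equal(m$specificity, mean(pred[truth == "MET"] == "MET"))
})

test_that("compute_metrics applies the three ratio formulas", {
  cc <- structure(list(TP = 3L, TN = 2L, FP = 2L, FN = 1L),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_identical(m$n, 8L)
  perfect <- compute_metrics(confusion_counts(c("GBM", "MET"),
                                              c("GBM", "MET")))
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
})

test_that("degenerate class sets give NA with a warning, never silent 0", {
  cc <- structure(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L),
                  class = "confusion_counts")
  expect_warning(m <- compute_metrics(cc), "sensitivity")
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
})

test_that("roc_auc matches closed forms and pair-counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c("GBM", "GBM", "MET", "MET")), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c("GBM", "MET"), 3)), 0.5)
  # 8 scores with a tie vs brute-force enumeration over pos-neg pairs
  scores <- c(0.9, 0.7, 0.7, 0.55, 0.5, 0.4, 0.3, 0.1)
  labels <- c("GBM", "GBM", "MET", "GBM", "MET", "MET", "GBM", "MET")
  brute <- 0; np <- 0
  for (i in which(labels == "GBM")) for (j in which(labels == "MET")) {
    np <- np + 1
    brute <- brute + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  expect_equal(roc_auc(scores, labels), brute / np)
  expect_error(roc_auc(1:3, rep("GBM", 3)), "both classes")
})

test_that("roc_auc is invariant under strictly monotone transforms", {
  set.seed(101)
  for (rep in 1:5) {
    scores <- rnorm(30)
    labels <- sample(c("GBM", "MET"), 30, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    a <- roc_auc(scores, labels)
    expect_equal(roc_auc(exp(scores), labels), a)
    expect_equal(roc_auc(scores * 3 - 100, labels), a)
  }
})

test_that("roc_points starts at (0,0) and ends at (1,1)", {
  set.seed(102)
  pts <- roc_points(runif(20), sample(c("GBM", "MET"), 20, replace = TRUE,
                                      prob = c(0.6, 0.4)))
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("aggregate_folds reproduces printed five-fold row averages", {
  # worked examples: the printed per-fold accuracies of three region models
  core <- c(92.3, 91.6, 93.4, 90.8, 93.5)
  overall <- c(89.8, 88.7, 90.4, 87.5, 82.5)
  edema <- c(87.5, 85.4, 83.2, 86.7, 84.5)
  expect_equal(round(aggregate_folds(core)$mean[["accuracy"]], 1), 92.3)
  expect_equal(round(aggregate_folds(overall)$mean[["accuracy"]], 1), 87.8)
  expect_equal(round(aggregate_folds(edema)$mean[["accuracy"]], 1), 85.5)
  # exact means before display rounding
  expect_equal(aggregate_folds(core)$mean[["accuracy"]], mean(core))
})

test_that("aggregate_folds: population variance, permutation invariance", {
  mk <- function(a) suppressWarnings(compute_metrics(structure(
    list(TP = round(a * 10), TN = 0L, FP = 0L, FN = 10 - round(a * 10)),
    class = "confusion_counts")))
  reps <- lapply(c(0.6, 0.8, 1.0), mk)
  s1 <- aggregate_folds(reps)
  s2 <- aggregate_folds(rev(reps))
  expect_equal(s1$mean, s2$mean)
  accs <- c(0.6, 0.8, 1.0)
  expect_equal(s1$variance[["accuracy"]], mean((accs - mean(accs))^2))
  same <- aggregate_folds(lapply(rep(0.8, 5), mk))
  expect_equal(same$variance[["accuracy"]], 0)
  expect_error(aggregate_folds(list()), "no reports")
})

test_that("case_level_predict takes the majority of thresholded votes", {
  expect_identical(case_level_predict(c(0.9, 0.8, 0.1)), "GBM")
  expect_identical(case_level_predict(c(0.2, 0.3, 0.1)), "MET")
  expect_identical(case_level_predict(c(0.6, 0.4, 0.7)), "GBM")
  expect_identical(case_level_predict(c(0.6, 0.4, 0.3), threshold = 0.35),
                   "GBM")
})
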