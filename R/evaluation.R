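# Cross-validation splitting and diagnostic metrics.
#
# Convention throughout: GBM is the positive class, MET the negative class.
# Splitting is always at case level — the 3 slices of a case move together —
# so no patient ever contributes to both sides of a split.

manifest_cases <- function(x) {
  manifest <- if (inherits(x, "scn_cohort")) x$manifest else x
  u <- unique(manifest[, c("case_id", "class_label")])
  if (anyDuplicated(u$case_id)) {
    stop("case ids must map to a single class label", call. = FALSE)
  }
  u
}

#' Stratified case-level k-fold partition
#'
#' Cases are shuffled within class and dealt round-robin, with the dealing
#' offset carried across classes so fold sizes are as equal as possible;
#' per-fold class counts are within one case of the cohort proportion.
#'
#' @param x An `scn_cohort` or a manifest data frame with `case_id` and
#'   `class_label` columns.
#' @param k Number of folds (default 5).
#' @param seed Shuffling seed.
#' @return A `fold_split`: `$folds` is a list of `k` disjoint case-id
#'   vectors whose union is all cases.
#' @export
make_folds <- function(x, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  u <- manifest_cases(x)
  if (nrow(u) < k) {
    stop("cannot make ", k, " folds from ", nrow(u), " cases", call. = FALSE)
  }
  set.seed(as.integer(seed))
  assign_fold <- integer(nrow(u))
  offset <- 0L
  for (cl in sort(unique(u$class_label))) {
    idx <- which(u$class_label == cl)
    idx <- idx[sample.int(length(idx))]
    assign_fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds <- lapply(seq_len(k), function(f) u$case_id[assign_fold == f])
  structure(list(k = k, folds = folds, seed = as.integer(seed)),
            class = "fold_split")
}

#' Stratified fixed-size train/test split of cases
#'
#' Complements [make_folds()]: a single split with a fixed training
#' fraction (or count), mirroring a fixed train/test partition such as
#' 207/44 cases.
#'
#' @param x An `scn_cohort` or manifest data frame.
#' @param n_train Number of training cases (alternative to `train_frac`).
#' @param train_frac Training fraction of cases.
#' @param seed Shuffling seed.
#' @return A list with `train` and `test` case-id vectors.
#' @export
split_fixed <- function(x, n_train = NULL, train_frac = NULL, seed = 1L) {
  u <- manifest_cases(x)
  n <- nrow(u)
  if (is.null(n_train)) {
    if (is.null(train_frac)) stop("give n_train or train_frac", call. = FALSE)
    n_train <- round(train_frac * n)
  }
  n_train <- as.integer(n_train)
  if (n_train < 1L || n_train >= n) {
    stop("n_train must be in [1, n_cases)", call. = FALSE)
  }
  frac <- n_train / n
  set.seed(as.integer(seed))
  classes <- sort(unique(u$class_label))
  per_class <- vapply(classes, function(cl) sum(u$class_label == cl),
                      integer(1))
  take <- round(per_class * frac)
  # fix rounding drift on the largest class
  take[which.max(per_class)] <- take[which.max(per_class)] +
    (n_train - sum(take))
  train <- unlist(lapply(seq_along(classes), function(i) {
    ids <- u$case_id[u$class_label == classes[i]]
    sample(ids, take[i])
  }))
  list(train = train, test = setdiff(u$case_id, train))
}

#' Confusion counts with GBM as the positive class
#'
#' @param y_true,y_pred Character vectors over `{"GBM", "MET"}` of equal
#'   length.
#' @return A `confusion_counts` object: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (!all(c(y_true, y_pred) %in% c("GBM", "MET"))) {
    stop("labels must be 'GBM' or 'MET'", call. = FALSE)
  }
  structure(list(TP = sum(y_true == "GBM" & y_pred == "GBM"),
                 TN = sum(y_true == "MET" & y_pred == "MET"),
                 FP = sum(y_true == "MET" & y_pred == "GBM"),
                 FN = sum(y_true == "GBM" & y_pred == "MET")),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+FN+TN+FP), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP). A metric whose denominator is zero (a class
#' absent from the evaluated set) is reported as `NA` with a warning,
#' never silently as 0.
#'
#' @param cc A [confusion_counts()] object.
#' @param auc Optional AUC to carry in the report.
#' @return A `metrics_report`: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `n`.
#' @export
compute_metrics <- function(cc, auc = NA_real_) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0L) stop("no evaluated units", call. = FALSE)
  sens <- if (cc$TP + cc$FN > 0L) cc$TP / (cc$TP + cc$FN) else {
    warning("no positive (GBM) cases: sensitivity undefined", call. = FALSE)
    NA_real_
  }
  spec <- if (cc$TN + cc$FP > 0L) cc$TN / (cc$TN + cc$FP) else {
    warning("no negative (MET) cases: specificity undefined", call. = FALSE)
    NA_real_
  }
  structure(list(accuracy = (cc$TP + cc$TN) / n, sensitivity = sens,
                 specificity = spec, auc = auc, n = n),
            class = "metrics_report")
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the fraction of
#' (positive, negative) pairs where the positive scores higher, ties
#' counting one half — hence invariant under strictly monotone transforms
#' of the scores.
#'
#' @param scores Numeric scores, larger = more GBM-like.
#' @param labels Labels over `{"GBM", "MET"}`; both classes must be present.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  pos <- labels == "GBM"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)   # average ranks handle ties as 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points from a threshold sweep
#'
#' @inheritParams roc_auc
#' @return A data frame of `(threshold, fpr, tpr)` rows, one per unique
#'   score plus the two trivial endpoints.
#' @export
roc_points <- function(scores, labels) {
  pos <- labels == "GBM"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(threshold = th,
             fpr = vapply(th, function(t) sum(scores >= t & !pos) / n0,
                          numeric(1)),
             tpr = vapply(th, function(t) sum(scores >= t & pos) / n1,
                          numeric(1)))
}

#' Aggregate per-fold metric reports
#'
#' Arithmetic mean and population variance (denominator `n`) of each
#' metric across folds; permutation-invariant in fold order. Rounding is
#' left to display.
#'
#' @param reports A list of [compute_metrics()] reports, or a plain
#'   numeric vector which is treated as per-fold accuracies.
#' @return A `fold_summary` with `mean` and `variance` named vectors.
#' @export
aggregate_folds <- function(reports) {
  if (is.numeric(reports)) {
    reports <- lapply(reports, function(a) {
      structure(list(accuracy = a, sensitivity = NA_real_,
                     specificity = NA_real_, auc = NA_real_, n = NA_integer_),
                class = "metrics_report")
    })
  }
  if (length(reports) == 0L) stop("no reports to aggregate", call. = FALSE)
  metrics <- c("accuracy", "sensitivity", "specificity", "auc")
  tab <- vapply(reports, function(r) unlist(r[metrics]), numeric(4))
  pop_var <- function(v) mean((v - mean(v))^2)
  structure(list(
    mean = apply(tab, 1L, function(v) if (all(is.na(v))) NA_real_
                 else mean(v, na.rm = TRUE)),
    variance = apply(tab, 1L, function(v) if (anyNA(v)) NA_real_
                     else pop_var(v)),
    n_folds = length(reports)), class = "fold_summary")
}

#' Fuse slice probabilities into one case prediction
#'
#' Majority vote of the thresholded slice predictions; an odd slice count
#' (3 per case) guarantees no ties.
#'
#' @param slice_probs Numeric vector of per-slice GBM probabilities for one
#'   case.
#' @param threshold Decision threshold (default 0.5).
#' @return `"GBM"` or `"MET"`.
#' @export
case_level_predict <- function(slice_probs, threshold = 0.5) {
  votes <- slice_probs >= threshold
  if (sum(votes) > length(votes) / 2) "GBM" else "MET"
}
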