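# Optimization and cross-validation orchestration.

#' Training configuration
#'
#' Defaults are the pipeline's reference hyperparameters: Adam with
#' learning rate 0.01 for 250 epochs and dropout 0.5. Desk-scale test runs
#' override `epochs`, `batch_size` and the model width, never the
#' optimizer semantics.
#'
#' @param epochs Number of passes over the training set (default 250).
#' @param learning_rate Adam step size (default 0.01).
#' @param optimizer Only `"adam"` is implemented.
#' @param batch_size Minibatch size (default 16).
#' @param seed Seed controlling shuffling, dropout and initialization of
#'   derived runs.
#' @param region Which region dataset to train on.
#' @param threshold Slice-probability decision threshold (default 0.5).
#' @param augment Optional [augment_config()] applied to training folds
#'   only (never to held-out data).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 250L, learning_rate = 0.01,
                         optimizer = "adam", batch_size = 16L, seed = 1L,
                         region = c("overall", "core", "edema"),
                         threshold = 0.5, augment = NULL) {
  region <- match.arg(region)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!identical(optimizer, "adam")) {
    stop("only the adam optimizer is implemented", call. = FALSE)
  }
  if (!is.null(augment)) stopifnot(inherits(augment, "augment_config"))
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 optimizer = optimizer, batch_size = as.integer(batch_size),
                 seed = as.integer(seed), region = region,
                 threshold = threshold, augment = augment),
            class = "train_config")
}

# Softmax cross-entropy on logits (n_classes x N); y in 1..n_classes.
softmax_xent <- function(logits, y) {
  z <- sweep(logits, 2L, apply(logits, 2L, max), "-")
  ez <- exp(z)
  p <- sweep(ez, 2L, colSums(ez), "/")
  n <- ncol(logits)
  picked <- p[cbind(y, seq_len(n))]
  dlogits <- p
  dlogits[cbind(y, seq_len(n))] <- picked - 1
  list(loss = -mean(log(pmax(picked, 1e-12))), dlogits = dlogits / n)
}

slice_labels <- function(slices) {
  vapply(slices, `[[`, character(1), "class_label")
}
slice_cases <- function(slices) {
  vapply(slices, `[[`, character(1), "case_id")
}

# Assemble (H, W, 1, N) tensor with per-image mean centering.
batch_tensor <- function(slices) {
  h <- nrow(slices[[1L]]$image)
  w <- ncol(slices[[1L]]$image)
  x <- array(0, dim = c(h, w, 1L, length(slices)))
  for (i in seq_along(slices)) {
    img <- slices[[i]]$image
    mu <- attr(img, "center_mean") %||% mean(img)
    x[, , 1L, i] <- img - mu
  }
  x
}

check_leakage <- function(train_ids, eval_ids, what = "validation") {
  overlap <- intersect(unique(train_ids), unique(eval_ids))
  if (length(overlap) > 0L) {
    stop("case-level leakage: ", length(overlap), " case(s) on both the ",
         "training and ", what, " side (e.g. ", overlap[1L], ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

adam_init <- function(params) {
  list(m = tree_map(function(p) p * 0, params),
       v = tree_map(function(p) p * 0, params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  c1 <- 1 / (1 - beta1^state$t)
  c2 <- 1 / (1 - beta2^state$t)
  params <- tree_map(function(p, m, v) p - lr * (m * c1) / (sqrt(v * c2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

#' Predict GBM probabilities for slice records
#'
#' Eval-mode forward passes in minibatches; probability is the softmax of
#' the logits on the GBM channel.
#'
#' @param model A trained `scn_model`.
#' @param slices List of `slice_record`s.
#' @param batch_size Minibatch size for the forward passes.
#' @return Numeric vector of GBM probabilities, one per slice.
#' @export
predict_slices <- function(model, slices, batch_size = 64L) {
  n <- length(slices)
  probs <- numeric(n)
  for (at in seq(1L, n, by = batch_size)) {
    idx <- at:min(at + batch_size - 1L, n)
    lg <- forward(model, batch_tensor(slices[idx]), train = FALSE,
                  strict = FALSE)
    z <- lg - apply(lg, 1L, max)
    probs[idx] <- exp(z[, 1L]) / rowSums(exp(z))
  }
  probs
}

#' Train the classifier on slice records
#'
#' Softmax cross-entropy optimized with Adam; the full run (shuffling,
#' dropout masks) is reproducible from `cfg$seed`. Training and
#' validation sets must be case-disjoint — overlap is a hard error, not a
#' warning.
#'
#' @param model An `scn_model` from [build_network()].
#' @param train_slices,val_slices Lists of `slice_record`s; `val_slices`
#'   may be `NULL`.
#' @param cfg A [train_config()].
#' @return A list: `model` (trained), `history` (data frame with one row
#'   per epoch: `epoch`, `loss`, `val_accuracy`).
#' @export
train_model <- function(model, train_slices, val_slices = NULL,
                        cfg = train_config()) {
  stopifnot(inherits(model, "scn_model"), inherits(cfg, "train_config"))
  if (!is.null(val_slices)) {
    check_leakage(slice_cases(train_slices), slice_cases(val_slices))
  }
  x <- batch_tensor(train_slices)
  y <- ifelse(slice_labels(train_slices) == "GBM", 1L, 2L)
  n <- length(train_slices)

  bn_reset_model(model)   # fresh normalization state: seed-reproducible runs
  params <- model_params(model)
  opt <- adam_init(params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_accuracy = numeric())
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    losses <- numeric()
    for (at in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[at:min(at + cfg$batch_size - 1L, n)]
      fw <- model_fwd(model, x[, , , idx, drop = FALSE], train = TRUE)
      ce <- softmax_xent(fw$logits, y[idx])
      bw <- model_bwd(model, fw$caches, ce$dlogits)
      upd <- adam_step(params, bw$grads, opt, cfg$learning_rate)
      params <- upd$params
      opt <- upd$state
      model <- model_set_params(model, params)
      losses <- c(losses, ce$loss)
    }
    val_acc <- NA_real_
    if (!is.null(val_slices)) {
      p <- predict_slices(model, val_slices)
      pred <- ifelse(p >= cfg$threshold, "GBM", "MET")
      val_acc <- mean(pred == slice_labels(val_slices))
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_accuracy = val_acc))
  }
  list(model = model, history = history)
}

# Slice- and case-level reports for a set of held-out slices.
evaluate_slices <- function(model, slices, threshold = 0.5) {
  probs <- predict_slices(model, slices)
  truth <- slice_labels(slices)
  ids <- slice_cases(slices)
  pred <- ifelse(probs >= threshold, "GBM", "MET")
  slice_auc <- tryCatch(roc_auc(probs, truth), error = function(e) NA_real_)
  slice_rep <- compute_metrics(confusion_counts(truth, pred), auc = slice_auc)

  case_ids <- unique(ids)
  case_truth <- vapply(case_ids, function(id) truth[ids == id][1L],
                       character(1))
  case_pred <- vapply(case_ids, function(id)
    case_level_predict(probs[ids == id], threshold), character(1))
  case_scores <- vapply(case_ids, function(id) mean(probs[ids == id]),
                        numeric(1))
  case_auc <- tryCatch(roc_auc(case_scores, case_truth),
                       error = function(e) NA_real_)
  case_rep <- compute_metrics(confusion_counts(case_truth, case_pred),
                              auc = case_auc)
  list(slice = slice_rep, case = case_rep, probs = probs,
       case_scores = setNames(case_scores, case_ids),
       case_truth = setNames(case_truth, case_ids))
}

#' Case-level k-fold cross-validation of the full pipeline
#'
#' For each fold: extract the configured region dataset, augment the
#' training slices (if configured), train a freshly initialized model, and
#' evaluate on the held-out fold at slice and case granularity. Every fold
#' is audited for case leakage before any gradient step.
#'
#' @param cohort An `scn_cohort`.
#' @param model_cfg A [model_config()].
#' @param cfg A [train_config()].
#' @param k Number of folds (default 5).
#' @return A `crossval_result`: `fold_reports` (per fold: `slice`, `case`
#'   reports), `summary_case` and `summary_slice` ([aggregate_folds()]
#'   output), `histories`, `folds`, and the case-level ROC points of the
#'   pooled folds.
#' @export
run_crossval <- function(cohort, model_cfg = model_config(),
                         cfg = train_config(), k = 5L) {
  stopifnot(inherits(cohort, "scn_cohort"))
  slices <- extract_region_dataset(cohort, region = cfg$region,
                                   size = model_cfg$input_size[1L])
  ids <- slice_cases(slices)
  split <- make_folds(cohort, k = k, seed = cfg$seed)
  fold_seeds <- derive_seeds(cfg$seed, k)

  fold_reports <- vector("list", k)
  histories <- vector("list", k)
  pooled_scores <- numeric()
  pooled_truth <- character()
  for (f in seq_len(k)) {
    test_ids <- split$folds[[f]]
    train_ids <- setdiff(unique(ids), test_ids)
    check_leakage(train_ids, test_ids, what = "test")
    tr <- slices[ids %in% train_ids]
    te <- slices[ids %in% test_ids]
    if (!is.null(cfg$augment)) {
      aug <- cfg$augment
      aug$seed <- fold_seeds[f]
      tr <- augment_dataset(tr, aug)
    }
    model <- build_network(model_cfg, seed = fold_seeds[f])
    fit_cfg <- cfg
    fit_cfg$seed <- fold_seeds[f]
    fit <- train_model(model, tr, val_slices = te, cfg = fit_cfg)
    ev <- evaluate_slices(fit$model, te, threshold = cfg$threshold)
    fold_reports[[f]] <- ev[c("slice", "case")]
    histories[[f]] <- fit$history
    pooled_scores <- c(pooled_scores, ev$case_scores)
    pooled_truth <- c(pooled_truth, ev$case_truth)
  }
  structure(list(
    fold_reports = fold_reports,
    summary_case = aggregate_folds(lapply(fold_reports, `[[`, "case")),
    summary_slice = aggregate_folds(lapply(fold_reports, `[[`, "slice")),
    histories = histories, folds = split,
    pooled_auc = roc_auc(pooled_scores, pooled_truth),
    roc = roc_points(pooled_scores, pooled_truth),
    model_cfg = model_cfg, train_cfg = cfg, k = k), class = "crossval_result")
}

#' Evaluate a trained model on an external case set
#'
#' No parameter updates; any overlap between the external cases and the
#' supplied training case ids is a hard leakage error.
#'
#' @param model A trained `scn_model`.
#' @param external Either an `scn_cohort` or a list of `slice_record`s.
#' @param train_case_ids Case ids the model was trained on.
#' @param region,threshold As in training.
#' @return List with `slice` and `case` [compute_metrics()] reports.
#' @export
evaluate_external <- function(model, external, train_case_ids,
                              region = "overall", threshold = 0.5) {
  slices <- if (inherits(external, "scn_cohort")) {
    extract_region_dataset(external, region = region,
                           size = model$cfg$input_size[1L])
  } else external
  check_leakage(train_case_ids, slice_cases(slices), what = "external")
  ev <- evaluate_slices(model, slices, threshold = threshold)
  ev[c("slice", "case")]
}
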