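# Shared fixtures, all generated in code.

# A small noise-free cohort: trivially separable by construction.
tiny_cohort <- function(n_gbm = 3, n_met = 3, seed = 1, noise_sd = 0) {
  generate_cohort(
    n_gbm, n_met, seed = seed,
    gbm_params = phenotype_params("GBM", noise_sd = noise_sd),
    met_params = phenotype_params("MET", noise_sd = noise_sd))
}

# Desk-scale model/training configs for pipeline tests.
tiny_model_cfg <- function(input = 32L) {
  model_config(width_multiplier = 0.1, input_size = c(input, input),
               stem_channels = 16L)
}

# A manifest data frame without any images, for split logic tests.
fake_manifest <- function(n_gbm, n_met) {
  ids <- c(sprintf("GBM_%03d", seq_len(n_gbm)),
           sprintf("MET_%03d", seq_len(n_met)))
  data.frame(case_id = rep(ids, each = 3),
             class_label = rep(c(rep("GBM", n_gbm), rep("MET", n_met)),
                               each = 3),
             slice = rep(1:3, n_gbm + n_met),
             stringsAsFactors = FALSE)
}

# Independent direct-convolution oracle (no im2col, no Armadillo): plain
# quadruple loops over output positions and kernel taps.
brute_conv2d <- function(x, w, b, stride = 1L, pad = NULL) {
  kh <- dim(w)[1L]; kw <- dim(w)[2L]
  if (is.null(pad)) pad <- c(kh %/% 2L, kw %/% 2L)
  H <- dim(x)[1L]; W <- dim(x)[2L]; Cin <- dim(x)[3L]; N <- dim(x)[4L]
  Cout <- dim(w)[4L]
  Ho <- (H + 2 * pad[1L] - kh) %/% stride + 1L
  Wo <- (W + 2 * pad[2L] - kw) %/% stride + 1L
  y <- array(0, c(Ho, Wo, Cout, N))
  for (n in seq_len(N)) for (o in seq_len(Cout)) for (r in seq_len(Ho))
    for (cc in seq_len(Wo)) {
      acc <- b[o]
      for (ci in seq_len(Cin)) for (i in seq_len(kh)) for (j in seq_len(kw)) {
        ir <- (r - 1L) * stride + i - pad[1L]
        jc <- (cc - 1L) * stride + j - pad[2L]
        if (ir >= 1 && ir <= H && jc >= 1 && jc <= W) {
          acc <- acc + x[ir, jc, ci, n] * w[i, j, ci, o]
        }
      }
      y[r, cc, o, n] <- acc
    }
  y
}

# Independent 3x3 stride-1 average pool (count_include_pad, divisor 9).
brute_avgpool3 <- function(x) {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  y <- array(0, dim(x))
  for (n in seq_len(dim(x)[4L])) for (ci in seq_len(dim(x)[3L]))
    for (r in seq_len(H)) for (cc in seq_len(W)) {
      acc <- 0
      for (i in -1:1) for (j in -1:1) {
        ir <- r + i; jc <- cc + j
        if (ir >= 1 && ir <= H && jc >= 1 && jc <= W) {
          acc <- acc + x[ir, jc, ci, n]
        }
      }
      y[r, cc, ci, n] <- acc / 9
    }
  y
}
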