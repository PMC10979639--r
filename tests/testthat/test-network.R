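# Whole-network assembly and forward contract.

test_that("default build contains 11 inception units in the declared order", {
  m <- build_network(model_config(width_multiplier = 0.1), seed = 1)
  expect_identical(n_inception_units(m), 11L)
  variants <- vapply(m$units, function(u) u$spec$variant, character(1))
  expect_identical(variants, c(rep("SCAT_A", 3), rep("SCAT_B", 2),
                               rep("C", 4), "D", "E"))
  # SCAT operators present exactly in the A/B units
  has_scat <- vapply(m$units, function(u) !is.null(u$scat), logical(1))
  expect_identical(has_scat, variants %in% c("SCAT_A", "SCAT_B"))
  # 5 branches in every A/B/C unit
  expect_true(all(vapply(m$units[variants %in% c("SCAT_A", "SCAT_B", "C")],
                         function(u) length(u$branches), integer(1)) == 5L))
})

test_that("head contract: N x 2 logits, eval-mode determinism", {
  cfg <- tiny_model_cfg(32)
  m <- build_network(cfg, seed = 2)
  set.seed(20)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  l1 <- forward(m, x)
  expect_identical(dim(l1), c(4L, 2L))
  expect_true(all(is.finite(l1)))
  expect_identical(l1, forward(m, x))
  # dropout makes training mode stochastic
  set.seed(1); lt1 <- forward(m, x, train = TRUE)
  set.seed(2); lt2 <- forward(m, x, train = TRUE)
  expect_false(identical(lt1, lt2))
})

test_that("seeded builds are identical; different seeds differ", {
  cfg <- tiny_model_cfg(32)
  expect_identical(scatnet:::model_params(build_network(cfg, seed = 5)),
                   scatnet:::model_params(build_network(cfg, seed = 5)))
  expect_false(identical(scatnet:::model_params(build_network(cfg, seed = 5)),
                         scatnet:::model_params(build_network(cfg, seed = 6))))
})

test_that("zero weights give logits equal to the head bias", {
  cfg <- tiny_model_cfg(32)
  m <- build_network(cfg, seed = 3)
  pz <- scatnet:::tree_map(function(p) p * 0, scatnet:::model_params(m))
  pz$head$linear$b <- c(0.7, -0.2)
  m <- scatnet:::model_set_params(m, pz)
  l <- forward(m, matrix(rnorm(32 * 32), 32, 32))
  expect_equal(as.numeric(l), c(0.7, -0.2), tolerance = 1e-12)
})

test_that("input size is enforced unless strict is lifted (GAP head)", {
  m <- build_network(tiny_model_cfg(64), seed = 4)
  expect_error(forward(m, matrix(0, 32, 32)), "no silent resize")
  # global average pooling accepts two different spatial sizes
  l64 <- forward(m, matrix(rnorm(64 * 64), 64, 64))
  l48 <- forward(m, matrix(rnorm(48 * 48), 48, 48), strict = FALSE)
  expect_identical(dim(l64), c(1L, 2L))
  expect_identical(dim(l48), c(1L, 2L))
  expect_true(all(is.finite(c(l64, l48))))
})

test_that("parameter count matches a layer-by-layer hand sum", {
  cfg <- model_config(n_a = 1, n_b = 0, n_c = 0, n_d = 0, n_e = 0,
                      stem_channels = 8, input_size = c(32, 32),
                      width_multiplier = 1)
  m <- build_network(cfg, seed = 1)
  # every conv carries batch norm (2 params/channel); SCAT convs do not
  conv_n <- function(kh, kw, cin, cout) kh * kw * cin * cout + 3 * cout
  # stem: 3x3 (1->4), 3x3 (4->8); one SCAT-A unit at 8 channels, bw = 2
  bw <- 2
  unit <- conv_n(1, 1, 8, bw) +                                # 1x1
    conv_n(1, 1, 8, bw) + conv_n(3, 3, bw, bw) +               # 1x1-3x3
    conv_n(1, 1, 8, bw) + conv_n(5, 5, bw, bw) +               # 1x1-5x5
    conv_n(1, 1, 8, bw) +                                      # pool-1x1
    conv_n(1, 1, 8, bw) + conv_n(1, 3, bw, bw) +               # 1x1-1x3
    (1 * 1 * 10 * 2 + 2) + (1 * 1 * 2 * 1 + 1)                 # SCAT (10 ch)
  hand <- conv_n(3, 3, 1, 4) + conv_n(3, 3, 4, 8) + unit +
    (10 * 2 + 2)                                               # linear head
  expect_identical(count_params(m), hand)
})

test_that("model configuration is validated", {
  expect_error(model_config(n_classes = 1), "n_classes")
  expect_error(model_config(dropout_rate = 1), "dropout_rate")
  expect_error(model_config(width_multiplier = 0), "width_multiplier")
  expect_error(model_config(n_a = -1), "counts")
})

test_that("full-model gradients match a directional finite difference", {
  cfg <- model_config(n_a = 1, n_b = 1, n_c = 1, n_d = 1, n_e = 1,
                      stem_channels = 4, input_size = c(16, 16),
                      dropout_rate = 0)
  m <- build_network(cfg, seed = 2)
  params <- scatnet:::model_params(m)
  set.seed(123)  # move biases off 0 so no activation sits on a ReLU kink
  params <- scatnet:::tree_map(function(p) {
    p[] <- p + rnorm(length(p), 0, 0.05); p
  }, params)
  m <- scatnet:::model_set_params(m, params)
  set.seed(31)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 1, 3))
  y <- c(1L, 2L, 1L)
  loss_of <- function(model) {
    scatnet:::softmax_xent(scatnet:::model_fwd(model, x)$logits, y)$loss
  }
  fw <- scatnet:::model_fwd(m, x)
  ce <- scatnet:::softmax_xent(fw$logits, y)
  grads <- scatnet:::model_bwd(m, fw$caches, ce$dlogits)$grads
  dirt <- scatnet:::tree_map(function(p) {
    d <- p; d[] <- rnorm(length(p)); d
  }, params)
  eps <- 1e-6
  up <- scatnet:::tree_map(function(p, d) p + eps * d, params, dirt)
  dn <- scatnet:::tree_map(function(p, d) p - eps * d, params, dirt)
  fd <- (loss_of(scatnet:::model_set_params(m, up)) -
         loss_of(scatnet:::model_set_params(m, dn))) / (2 * eps)
  analytic <- scatnet:::tree_sum(
    scatnet:::tree_map(function(a, b) sum(a * b), dirt, grads),
    f = function(v) v)
  expect_equal(analytic, fd, tolerance = 1e-5)
})
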