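test_that("engine gradients match central finite differences", {
  set.seed(1)
  x <- fenoct:::ad_param(array(rnorm(6 * 6 * 2), c(6, 6, 2, 1)))
  w <- fenoct:::ad_param(array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3)))
  b <- fenoct:::ad_param(rnorm(3))

  check <- function(forward, params, picks, tol = 1e-5) {
    loss <- forward()
    # forward() builds a fresh graph; run backward on a dedicated build
    fenoct:::ad_zero_grads(params)
    node <- forward(node = TRUE)
    fenoct:::ad_backward(node)
    for (k in seq_along(params)) {
      p <- params[[k]]
      for (i in picks[[k]]) {
        num <- numeric_grad(p, i, function() forward())
        expect_lt(abs(num - p$grad[i]), tol)
      }
    }
    invisible(loss)
  }

  conv_fwd <- function(node = FALSE) {
    n <- fenoct:::nn_mean_sq(fenoct:::nn_conv(x, w, b, 2L))
    if (node) n else n$value
  }
  check(conv_fwd, list(x, w, b), list(c(1, 40), c(5, 30), 2))

  # pooling + bilinear upsampling + leaky ReLU chain
  chain_fwd <- function(node = FALSE) {
    h <- fenoct:::nn_lrelu(fenoct:::nn_conv(x, w, b, 1L))
    h <- fenoct:::nn_up2(fenoct:::nn_pool(h))
    n <- fenoct:::nn_mean_abs(h)
    if (node) n else n$value
  }
  check(chain_fwd, list(x, w, b), list(c(3, 25), c(11, 47), 1))

  # group norm
  gam <- fenoct:::ad_param(runif(2, 0.5, 1.5))
  bet <- fenoct:::ad_param(rnorm(2) * 0.1)
  gn_fwd <- function(node = FALSE) {
    n <- fenoct:::nn_mean_sq(fenoct:::nn_gn(x, gam, bet, 2L))
    if (node) n else n$value
  }
  check(gn_fwd, list(x, gam, bet), list(c(7, 50), 1, 2))

  # spectral pooling
  wll <- fenoct:::ad_param(array(diag(2) + rnorm(4) * 0.1, c(1, 1, 2, 2)))
  bll <- fenoct:::ad_param(rnorm(2) * 0.1)
  wspm_fwd <- function(node = FALSE) {
    n <- fenoct:::nn_mean_sq(fenoct:::nn_wspm(x, wll, bll, 0.65))
    if (node) n else n$value
  }
  check(wspm_fwd, list(x, wll, bll), list(c(9, 33), c(2, 3), 1))
})

test_that("receptive-field block is the identity when its weights are zero", {
  cfg <- tiny_net_config()
  mod <- fe_rfb_module(8L, cfg, seed = 2)
  for (p in mod$params) p$value[] <- 0
  set.seed(3)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  expect_equal(mod$forward(x), x, tolerance = 1e-12)
})

test_that("receptive-field block preserves shape and reaches dilation-5 range", {
  cfg <- tiny_net_config()
  mod <- fe_rfb_module(8L, cfg, seed = 4)
  for (d in c(16L, 24L, 32L)) {
    x <- array(rnorm(d * d * 8), c(d, d, 8, 1))
    expect_equal(dim(mod$forward(x)), dim(x))
  }
  # single-pixel perturbation must reach >= 5 px away (dilation-5 branch)
  set.seed(5)
  x <- array(rnorm(24 * 24 * 8), c(24, 24, 8, 1))
  y0 <- mod$forward(x)
  x2 <- x
  x2[12, 12, 1, 1] <- x2[12, 12, 1, 1] + 1
  dmap <- apply(abs(mod$forward(x2) - y0), c(1, 2), max)
  moved <- which(dmap > 1e-9, arr.ind = TRUE)
  cheb <- pmax(abs(moved[, 1] - 12), abs(moved[, 2] - 12))
  expect_gte(max(cheb), 5)

  # invalid branch fraction is rejected at construction
  expect_error(net_config(base_channels = 8L, gn_groups = 4L,
                          ferfb = ferfb_config(branch_channel_fraction = 1 / 3)),
               "divisible")
})

test_that("the UNet preserves shape and builds deterministically", {
  cfg <- tiny_net_config()
  m <- build_feunet(cfg, seed = 1)
  for (d in c(32L, 48L, 64L)) {
    x <- matrix(rnorm(d * d), d, d)
    expect_equal(dim(feunet_forward(m, x)), c(d, d))
  }
  expect_error(feunet_forward(m, matrix(0, 40, 40)), "divisible by 16")

  m2 <- build_feunet(cfg, seed = 99)
  expect_equal(count_params(m), count_params(m2))
  m3 <- build_feunet(cfg, seed = 1)
  expect_identical(lapply(m$params, function(p) p$value),
                   lapply(m3$params, function(p) p$value))

  # ablation variants drop their structural parameters
  expect_lt(count_params(build_feunet(tiny_net_config(use_wspm = FALSE))),
            count_params(m))
  expect_false(any(grepl("\\.ll\\.",
                         names(build_feunet(tiny_net_config(use_wspm = FALSE))$params))))
  expect_true(all(grepl("\\.c[12]\\.|\\.in\\.|\\.gn|bott|dec|out",
                        names(build_feunet(tiny_net_config(use_ferfb = FALSE))$params))))
})

test_that("gradient reaches every parameter group through the skip wiring", {
  cfg <- tiny_net_config()
  m <- build_feunet(cfg, seed = 6)
  set.seed(7)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  node <- fenoct:::feunet_node(m, fenoct:::ad_const(x))
  loss <- fenoct:::nn_mean_sq(node)
  fenoct:::ad_backward(loss)
  zero_grad <- vapply(m$params, function(p) {
    is.null(p$grad) || all(p$grad == 0)
  }, logical(1))
  expect_false(any(zero_grad),
               info = paste("dead parameters:",
                            paste(names(m$params)[zero_grad], collapse = ", ")))
})

test_that("spectral-path linearity survives inside the full block", {
  # no normalization sits in the spectral path: the wspm submodule of a
  # branch must act linearly on its input for fixed parameters
  cfg <- tiny_net_config()
  set.seed(8)
  wll <- fenoct:::ad_param(array(diag(8) + rnorm(64) * 0.05, c(1, 1, 8, 8)))
  bll <- fenoct:::ad_param(numeric(8))
  wspm_of <- function(x) {
    fenoct:::nn_wspm(fenoct:::ad_const(x), wll, bll,
                     cfg$wspm$lambda_mix)$value
  }
  a <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  b <- array(rnorm(16 * 16 * 8), c(16, 16, 8, 1))
  lhs <- wspm_of(2.5 * a - 1.2 * b)
  rhs <- 2.5 * wspm_of(a) - 1.2 * wspm_of(b)
  expect_lt(max(abs(lhs - rhs)), 1e-5)
})
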