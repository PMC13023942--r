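test_that("learning-rate schedule halves at the stated period", {
  cfg <- full_preset()   # lr 1e-4, halved every 20 epochs
  expect_equal(lr_at_epoch(cfg, 0), 1e-4)
  expect_equal(lr_at_epoch(cfg, 19), 1e-4)
  expect_equal(lr_at_epoch(cfg, 20), 5e-5)
  expect_equal(lr_at_epoch(cfg, 40), 2.5e-5)
  expect_error(train_config(learning_rate = 0), "> 0")
  expect_error(train_config(patch_size = 50), "divisible by 16")
})

test_that("a zero-epoch run returns initialized parameters and no history", {
  truths <- make_dataset(small_phantom_config(seed = 50), 3)
  noisy <- lapply(truths, function(tr) tr$noisy)
  tc <- desk_preset(seed = 2); tc$epochs <- 0L
  cfg <- tiny_net_config()
  fit <- train(noisy[1:2], noisy[3], cfg, tc)
  expect_s3_class(fit, "fenoct_fit")
  expect_equal(nrow(fit$manifest$history), 0)
  init <- build_feunet(fenoct:::apply_ablation(cfg, "full"), seed = 2)
  expect_identical(lapply(fit$model$params, function(p) p$value),
                   lapply(init$params, function(p) p$value))
})

test_that("training is reproducible under a fixed seed", {
  truths <- make_dataset(small_phantom_config(seed = 60), 5)
  noisy <- lapply(truths, function(tr) tr$noisy)
  tc <- desk_preset(seed = 3); tc$epochs <- 1L
  cfg <- tiny_net_config()
  f1 <- train(noisy[1:4], noisy[5], cfg, tc)
  f2 <- train(noisy[1:4], noisy[5], cfg, tc)
  expect_identical(f1$manifest$history$total, f2$manifest$history$total)
  expect_identical(lapply(f1$model$params, function(p) p$value),
                   lapply(f2$model$params, function(p) p$value))
  expect_gt(nrow(f1$manifest$history), 0)
  expect_true(all(is.finite(f1$manifest$history$total)))
})

test_that("denoise pads arbitrary sizes, clips, and is deterministic", {
  m <- build_feunet(tiny_net_config(), seed = 4)
  img <- bscan(matrix(runif(100 * 100), 100, 100), validate = FALSE)
  out1 <- denoise(m, img)
  out2 <- denoise(m, img)
  expect_equal(dim(out1$pixels), c(100L, 100L))
  expect_identical(out1$pixels, out2$pixels)
  expect_true(all(out1$pixels >= 0 & out1$pixels <= 1))
})

test_that("re-denoising a denoised image moves it less than the first pass", {
  truths <- make_dataset(small_phantom_config(seed = 70), 12)
  noisy <- lapply(truths, function(tr) tr$noisy)
  tc <- desk_preset(seed = 5); tc$epochs <- 1L
  fit <- train(noisy[1:8], noisy[9:10], tiny_net_config(), tc)
  deltas <- vapply(truths[11:12], function(tr) {
    d1 <- denoise(fit, tr$noisy)
    d2 <- denoise(fit, d1)
    c(first = mean((d1$pixels - tr$noisy$pixels)^2),
      second = mean((d2$pixels - d1$pixels)^2))
  }, numeric(2))
  expect_true(all(deltas["second", ] < deltas["first", ]))
})

test_that("models round-trip through save/load with a manifest sidecar", {
  m <- build_feunet(tiny_net_config(), seed = 8)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_params, count_params(m))
  expect_equal(nchar(side$md5), 32L)
  reloaded <- load_model(path)
  x <- matrix(runif(32 * 32), 32, 32)
  expect_identical(feunet_forward(m, x), feunet_forward(reloaded$model, x))
})

test_that("per-step loss log and breakdown identity hold during training", {
  truths <- make_dataset(small_phantom_config(seed = 80), 4)
  noisy <- lapply(truths, function(tr) tr$noisy)
  tc <- desk_preset(seed = 6); tc$epochs <- 1L
  log <- tempfile(fileext = ".csv")
  w <- loss_weights()
  fit <- train(noisy[1:3], noisy[4], tiny_net_config(), tc, weights = w,
               log_csv = log)
  steps <- read.csv(log)
  expect_equal(nrow(steps), 3)
  recomputed <- w$lambda1 * steps$l1_pred + w$lambda2 * steps$l2_consistency +
    w$lambda3 * steps$l_freq + w$gamma * steps$l_reg
  expect_equal(steps$total, recomputed, tolerance = 1e-12)
})
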