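test_that("clean phantom generation honors its contract", {
  # single flat layer at a pinned intensity
  cfg <- phantom_config(size = c(32, 32), n_layers = 1L,
                        layer_intensity_range = c(0.5, 0.5), seed = 7)
  flat <- make_clean_phantom(cfg)
  expect_equal(flat$pixels, matrix(0.5, 32, 32))

  # determinism: same config, same seed, bit-identical
  cfg2 <- phantom_config(seed = 11)
  expect_identical(make_clean_phantom(cfg2)$pixels,
                   make_clean_phantom(cfg2)$pixels)

  # 4 layers -> at least 3 distinct plateaus in the row-wise mean
  cfg3 <- phantom_config(size = c(256, 256), n_layers = 4L, seed = 5)
  rm <- rowMeans(make_clean_phantom(cfg3)$pixels)
  d <- abs(diff(rm))
  # plateau = maximal run of near-zero derivative longer than 10 rows
  runs <- rle(d < 1e-3)
  expect_gte(sum(runs$values & runs$lengths > 10), 3)

  expect_error(phantom_config(size = c(33, 32)), "even")
})

test_that("speckle field is unit-mean Gamma with variance 1/shape", {
  clean <- make_clean_phantom(phantom_config(size = c(512, 512),
                                             n_layers = 1L,
                                             layer_intensity_range = c(0.5, 0.5)))
  # degenerate limit: huge shape -> field ~ 1, output ~ clean
  sp_inf <- add_speckle(clean, 1e9, seed = 1)
  expect_lt(max(abs(sp_inf$bscan$pixels - clean$pixels)), 1e-3)

  sp1 <- add_speckle(clean, 1, seed = 2)
  expect_gte(mean(sp1$field), 0.98)
  expect_lte(mean(sp1$field), 1.02)

  sp4 <- add_speckle(clean, 4, seed = 3)
  v <- var(as.numeric(sp4$field))
  expect_gte(v, 0.23)
  expect_lte(v, 0.27)

  expect_error(add_speckle(clean, 0), "> 0")
})

test_that("periodic background is an exact sum of sinusoids at the stated bins", {
  img <- make_clean_phantom(phantom_config(size = c(128, 128), n_layers = 1L,
                                           layer_intensity_range = c(0.5, 0.5)))
  # amplitude 0 leaves the image untouched
  bg0 <- add_periodic_background(img, 0, list(c(64, Inf)), seed = 1)
  expect_equal(bg0$bscan$pixels, img$pixels)

  # rows-only component is constant along columns
  bgr <- add_periodic_background(img, 0.1, list(c(64, Inf)), seed = 2)
  expect_equal(max(apply(bgr$field, 1, sd)), 0)

  # spectral peak of the field sits at the expected centered bin
  bg1 <- add_periodic_background(img, 0.1, list(c(16, Inf)), seed = 3)
  mag <- Mod(fenoct:::fftshift2(fft(bg1$field)))
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  rb <- fenoct:::centered_bins(128)[pk[1]]
  expect_equal(abs(rb), 128 / 16)

  expect_error(add_periodic_background(img, 0.1, list(c(3, Inf))), "4 px")
})

test_that("background field is band-limited", {
  cfg <- phantom_config(seed = 21)
  img <- make_clean_phantom(cfg)
  bg <- add_periodic_background(img, cfg$background_amplitude,
                                cfg$background_periods, seed = 4)
  mag2 <- Mod(fenoct:::fftshift2(fft(bg$field)))^2
  h <- nrow(mag2); w <- ncol(mag2)
  rb <- matrix(fenoct:::centered_bins(h), h, w)
  cb <- matrix(fenoct:::centered_bins(w), h, w, byrow = TRUE)
  # cutoff: 1.5x the highest component frequency plus a 3-bin leakage margin
  fmax <- max(vapply(cfg$background_periods, function(p) {
    max(ifelse(is.finite(p), c(h, w) / p, 0))
  }, numeric(1)))
  cutoff <- 1.5 * fmax + 3
  inside <- sqrt(rb^2 + cb^2) <= cutoff
  expect_gte(sum(mag2[inside]) / sum(mag2), 0.95)
})

test_that("stripes are reproducible full-length bands of the stated count", {
  img <- make_clean_phantom(phantom_config(size = c(64, 64), n_layers = 1L,
                                           layer_intensity_range = c(0.4, 0.4)))
  st0 <- add_stripes(img, 0, 0.3, seed = 1)
  expect_equal(st0$bscan$pixels, img$pixels)
  expect_true(all(st0$mask == 0))

  st3 <- add_stripes(img, 3, 0.3, "horizontal", seed = 5)
  marked <- which(rowSums(st3$mask) > 0)
  bands <- sum(diff(c(-10, marked)) > 1)   # connected row-bands
  expect_equal(bands, 3)
  expect_true(all(st3$mask[marked, ] == 1))   # full-length

  st3b <- add_stripes(img, 3, 0.3, "horizontal", seed = 5)
  expect_identical(st3$mask, st3b$mask)

  expect_error(add_stripes(img, 60, 0.3, seed = 1), "cannot place")
})

test_that("phantom composition is exact and datasets split 8:1:1", {
  truth <- make_phantom(small_phantom_config(seed = 3))
  recon <- truth$clean$pixels * truth$speckle_field +
    truth$background_field + truth$stripe_amplitude * truth$stripe_mask
  vr <- truth$config$value_range
  expect_equal(truth$noisy$pixels, pmin(pmax(recon, vr[1]), vr[2]),
               tolerance = 1e-12)

  expect_length(make_dataset(small_phantom_config(), 1L), 1L)
  sp <- split_indices(10)
  expect_equal(lengths(sp), c(train = 8L, val = 1L, test = 1L))
  expect_setequal(unlist(sp), 1:10)
})
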