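# Volumes of consecutive B-scans: tissue and speckle decorrelate from scan
# to scan while the stripe pattern and periodic background persist.

test_that("stripe removal is a no-op without stripes and recovers injected rows", {
  cfg0 <- phantom_config(size = c(128, 128), seed = 2, stripe_count = 0L)
  vol0 <- lapply(make_volume(cfg0, 8), function(tr) tr$noisy)
  out0 <- remove_stripes(vol0, stripe_removal_spec(threshold = 10))
  for (i in seq_along(out0)) {
    expect_equal(out0[[i]]$pixels, vol0[[i]]$pixels)
  }

  for (s in c(1, 7, 31)) {
    cfg <- phantom_config(size = c(128, 128), seed = s)
    vol <- make_volume(cfg, 8)
    scans <- lapply(vol, function(tr) tr$noisy)
    out <- remove_stripes(scans, stripe_removal_spec())
    injected <- which(rowSums(vol[[1]]$stripe_mask) > 0)
    flagged <- attr(out, "stripe_rows")
    jaccard <- length(intersect(flagged, injected)) /
      length(union(flagged, injected))
    expect_gte(jaccard, 0.9)
  }

  expect_error(remove_stripes(vol0[1:3], stripe_removal_spec(stack_depth = 8)),
               "stack_depth")
})

test_that("stripe contrast drops by at least 90 percent after removal", {
  cfg <- phantom_config(size = c(128, 128), seed = 1)
  vol <- make_volume(cfg, 8)
  scans <- lapply(vol, function(tr) tr$noisy)
  out <- remove_stripes(scans, stripe_removal_spec())
  rows <- which(rowSums(vol[[1]]$stripe_mask) > 0)
  contrast <- function(scans) {
    mean(vapply(scans, function(b) {
      px <- fenoct:::as_pixels(b)
      mean(vapply(rows, function(r) {
        nb <- intersect(c(r - 3, r + 3), setdiff(seq_len(nrow(px)), rows))
        abs(mean(px[r, ]) - mean(px[nb, , drop = FALSE]))
      }, numeric(1)))
    }, numeric(1)))
  }
  expect_lte(contrast(out), 0.1 * contrast(scans))
})

test_that("dominant-frequency detection finds injected sinusoids", {
  h <- 64; w <- 64
  base <- matrix(0.5, h, w)
  col_sin <- function(period, amp) {
    matrix(amp * sin(2 * pi * (seq_len(w) - 1) / period), h, w, byrow = TRUE)
  }
  # pure sinusoid of period 16 px along columns -> column bin W/16
  img <- base + col_sin(16, 0.2)
  pk <- detect_dominant_frequencies(img, n_peaks = 1)
  expect_equal(unname(pk[1, ]), c(0L, as.integer(w / 16)))

  # constant image: nothing above the floor
  expect_equal(nrow(detect_dominant_frequencies(base, n_peaks = 3)), 0)

  # two sinusoids, amplitude order preserved
  img2 <- base + col_sin(8, 0.3) + col_sin(4, 0.1)
  pk2 <- detect_dominant_frequencies(img2, n_peaks = 2)
  expect_equal(unname(pk2[, "col_bin"]), as.integer(c(w / 8, w / 4)))

  expect_error(detect_dominant_frequencies(img, 1, exclude_radius = 40),
               "whole spectrum")
})

test_that("notch filtering is identity at depth 0 and suppresses the target bin", {
  set.seed(8)
  img <- matrix(runif(64 * 64, 0.2, 0.8), 64, 64)
  id_spec <- notch_spec(data.frame(row_bin = 5, col_bin = 0, radius = 2,
                                   depth = 0), gaussian_sigma = 0)
  expect_lt(max(abs(notch_filter(img, id_spec) - img)), 1e-6)

  # flat clean + one sinusoid: the notch must remove (almost) exactly the
  # injected component
  clean <- make_clean_phantom(phantom_config(size = c(64, 64), n_layers = 1L,
                                             layer_intensity_range = c(0.4, 0.4)))
  bg <- add_periodic_background(clean, 0.15, list(c(8, Inf)), seed = 3)
  noisy <- bg$bscan
  spec <- notch_spec(data.frame(row_bin = 8, col_bin = 0, radius = 1.5,
                                depth = 1), gaussian_sigma = 0)
  filtered <- notch_filter(noisy, spec)

  # PSNR against the clean image strictly increases
  expect_gt(psnr(filtered, clean), psnr(noisy, clean))

  bin_mag <- function(px) {
    m <- Mod(fenoct:::fftshift2(fft(px)))
    m[which(fenoct:::centered_bins(64) == 8),
      which(fenoct:::centered_bins(64) == 0)]
  }
  # residual sinusoid amplitude < 5% of injected
  inj <- bin_mag(bg$field)
  expect_lt(bin_mag(filtered$pixels - clean$pixels), 0.05 * inj)

  # >= 20 dB power reduction at the notched bin
  drop_db <- 10 * log10(bin_mag(noisy$pixels)^2 / bin_mag(filtered$pixels)^2)
  expect_gte(drop_db, 20)

  expect_error(notch_filter(matrix(c(NA, runif(64 * 64 - 1)), 64, 64),
                            id_spec), "finite")
})

test_that("full preprocessing raises ROI SNR by at least 3 dB on phantom volumes", {
  cfg <- phantom_config(size = c(128, 128), seed = 31,
                        background_periods = list(c(16, Inf)))
  vol <- make_volume(cfg, 8)
  scans <- lapply(vol, function(tr) tr$noisy)
  pre <- preprocess_volume(scans, stripe_removal_spec(), n_peaks = 2,
                           gaussian_sigma = 1.0)
  masks <- default_roi_masks(vol[[1]])
  snr_of <- function(ss) {
    mean(vapply(ss, snr, numeric(1), signal_mask = masks$signal,
                background_mask = masks$background))
  }
  expect_gte(snr_of(pre) - snr_of(scans), 3)
})
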