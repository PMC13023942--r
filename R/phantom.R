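#' Phantom generator configuration
#'
#' The phantom module emulates what a MEMS-scanned OCT probe sees in layered
#' biological tissue: piecewise-smooth horizontal bands (tissue layers under
#' an air gap) corrupted by the three characteristic degradations of such
#' systems — multiplicative speckle from coherent backscatter, smooth
#' periodic background bias from source/scanner instability, and
#' full-length coherent stripe artifacts from parasitic reflections.
#'
#' Defaults: 256x256 phantoms on a unit intensity range, 4 layers, Gamma
#' speckle with shape `k = 4` (speckle variance `1/k = 0.25`), background
#' amplitude 10% of the dynamic range at long periods, and 3 horizontal
#' stripes.
#'
#' @param size `(H, W)`, both even and >= 16.
#' @param n_layers Number of horizontal tissue bands (the top band plays the
#'   role of the air gap above the sample and receives the lowest intensity).
#' @param layer_intensity_range Range the per-layer base intensities are
#'   drawn from.
#' @param speckle_shape Gamma shape parameter `k`; speckle variance is `1/k`.
#' @param background_amplitude Amplitude of each background sinusoid, in
#'   intensity units.
#' @param background_periods List of `(row_period, col_period)` pixel periods;
#'   `Inf` means constant along that axis. All finite periods must be >= 4.
#' @param stripe_count,stripe_amplitude,stripe_orientation Coherent stripe
#'   artifact parameters; orientation `"horizontal"` or `"vertical"`.
#' @param value_range Representable intensity range (clipping bounds).
#' @param seed Base seed; every generator below is bit-reproducible given it.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(size = c(256L, 256L),
                           n_layers = 4L,
                           layer_intensity_range = c(0.05, 0.9),
                           speckle_shape = 4,
                           background_amplitude = 0.1,
                           background_periods = list(c(32, Inf), c(Inf, 48)),
                           stripe_count = 3L,
                           stripe_amplitude = 0.35,
                           stripe_orientation = c("horizontal", "vertical"),
                           value_range = c(0, 1),
                           seed = 1L) {
  stripe_orientation <- match.arg(stripe_orientation)
  size <- as.integer(size)
  stopifnot_even(size[1], size[2], "phantom")
  if (any(size < 16L)) stop("phantom size must be >= 16 in both dimensions")
  if (speckle_shape <= 0) stop("speckle_shape must be > 0")
  if (background_amplitude < 0 || stripe_amplitude < 0) {
    stop("amplitudes must be >= 0")
  }
  for (p in background_periods) {
    if (any(p[is.finite(p)] < 4)) stop("background periods must be >= 4 px")
  }
  structure(list(
    size = size, n_layers = as.integer(n_layers),
    layer_intensity_range = layer_intensity_range,
    speckle_shape = speckle_shape,
    background_amplitude = background_amplitude,
    background_periods = background_periods,
    stripe_count = as.integer(stripe_count),
    stripe_amplitude = stripe_amplitude,
    stripe_orientation = stripe_orientation,
    value_range = as.numeric(value_range),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Generate a clean layered-tissue phantom
#'
#' Produces `n_layers` horizontal bands with smoothly curved boundaries
#' (a sum of two low-frequency lateral sinusoids perturbs each interface)
#' and a constant base intensity per band. The top band is assigned the
#' lowest drawn intensity so phantoms carry an air-like dark region above
#' the tissue, which the default SNR regions of interest rely on.
#'
#' @param config A [phantom_config].
#' @return A [bscan] (the latent clean image).
#' @export
make_clean_phantom <- function(config) {
  h <- config$size[1]; w <- config$size[2]
  n <- config$n_layers
  with_seed(config$seed, {
    lo <- config$layer_intensity_range[1]
    hi <- config$layer_intensity_range[2]
    vals <- runif(n, lo, hi)
    # air on top: darkest band first, others keep their random order
    ord <- order(vals)
    vals <- c(vals[ord[1]], vals[-ord[1]])
    # interface i sits near depth i*H/n, perturbed by a smooth lateral curve
    x <- seq_len(w)
    bounds <- matrix(0, nrow = max(n - 1L, 0L), ncol = w)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        amp <- 0.03 * h
        curve <- amp * sin(2 * pi * x / runif(1, 0.7 * w, 1.6 * w) +
                             runif(1, 0, 2 * pi)) +
          0.5 * amp * sin(2 * pi * x / runif(1, 0.25 * w, 0.5 * w) +
                            runif(1, 0, 2 * pi))
        bounds[i, ] <- i * h / n + curve
      }
    }
    px <- matrix(vals[1], h, w)
    if (n > 1L) {
      rows <- seq_len(h)
      for (j in seq_len(w)) {
        # layer index of each row = 1 + number of interfaces above it
        layer <- 1L + colSums(outer(bounds[, j], rows, `<`))
        px[, j] <- vals[layer]
      }
    }
    clip_bscan(px, config$value_range)
  })
}

#' Add multiplicative speckle
#'
#' Fully developed speckle is modelled as i.i.d. unit-mean Gamma
#' multiplicative noise: `field ~ Gamma(shape = k, scale = 1/k)`, so
#' `E[field] = 1` and `Var[field] = 1/k`.
#'
#' @param clean A [bscan].
#' @param shape Gamma shape parameter `k > 0`; larger = weaker speckle.
#' @param seed Seed for the field.
#' @return List with `bscan` (clipped product) and `field` (exact,
#'   pre-clip multiplicative factors).
#' @export
add_speckle <- function(clean, shape, seed = 1L) {
  stopifnot(is_bscan(clean))
  if (!is.numeric(shape) || shape <= 0) stop("speckle shape must be > 0")
  d <- dim(clean$pixels)
  field <- with_seed(seed, matrix(rgamma(prod(d), shape = shape,
                                         rate = shape), d[1], d[2]))
  list(bscan = clip_bscan(clean$pixels * field, clean$value_range),
       field = field)
}

#' Add periodic low-frequency background
#'
#' Adds a sum of 2D sinusoids, one per `(row_period, col_period)` entry,
#' each with amplitude `amplitude` and a random phase. `Inf` in one axis
#' makes the component constant along that axis.
#'
#' @param img A [bscan].
#' @param amplitude Per-component amplitude in intensity units.
#' @param periods List of `(row_period, col_period)`; finite periods >= 4 px.
#' @param seed Seed for the phases.
#' @return List with `bscan` (clipped sum) and `field` (exact additive field).
#' @export
add_periodic_background <- function(img, amplitude, periods, seed = 1L) {
  stopifnot(is_bscan(img))
  for (p in periods) {
    if (any(p[is.finite(p)] < 4)) {
      stop("background period below 4 px would not be low-frequency")
    }
  }
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  r <- matrix(seq_len(h) - 1L, h, w)
  cc <- matrix(seq_len(w) - 1L, h, w, byrow = TRUE)
  field <- with_seed(seed, {
    f <- matrix(0, h, w)
    for (p in periods) {
      fr <- if (is.finite(p[1])) 1 / p[1] else 0
      fc <- if (is.finite(p[2])) 1 / p[2] else 0
      f <- f + amplitude * cos(2 * pi * (fr * r + fc * cc) +
                                 runif(1, 0, 2 * pi))
    }
    f
  })
  list(bscan = clip_bscan(img$pixels + field, img$value_range), field = field)
}

#' Add coherent stripe artifacts
#'
#' Adds `count` full-length constant-intensity lines of width 1–2 px at
#' random, well-separated positions. Reusing the same seed reproduces the
#' same positions, emulating stripes that are spatially consistent across
#' consecutive B-scans of a volume.
#'
#' @param img A [bscan].
#' @param count Number of stripes (>= 0).
#' @param amplitude Added intensity on stripe pixels.
#' @param orientation `"horizontal"` (stripe = row band) or `"vertical"`.
#' @param seed Seed for positions and widths.
#' @return List with `bscan`, `mask` (binary stripe-pixel matrix) and
#'   `amplitude`.
#' @export
add_stripes <- function(img, count, amplitude,
                        orientation = c("horizontal", "vertical"),
                        seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(is_bscan(img))
  if (count < 0) stop("stripe count must be >= 0")
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  extent <- if (orientation == "horizontal") h else w
  if (count > extent %/% 6L) {
    stop(sprintf("cannot place %d separated stripes in an extent of %d px",
                 count, extent))
  }
  mask <- matrix(0, h, w)
  if (count > 0) {
    with_seed(seed, {
      # rejection-sample positions at least 4 px apart so stripes stay
      # distinct connected bands
      pos <- integer(0)
      while (length(pos) < count) {
        cand <- sample.int(extent - 2L, 1L) + 1L
        if (all(abs(cand - pos) >= 4L)) pos <- c(pos, cand)
      }
      widths <- sample(1:2, count, replace = TRUE)
      for (i in seq_len(count)) {
        lines <- pos[i]:min(pos[i] + widths[i] - 1L, extent)
        if (orientation == "horizontal") mask[lines, ] <- 1 else
          mask[, lines] <- 1
      }
    })
  }
  list(bscan = clip_bscan(img$pixels + amplitude * mask, img$value_range),
       mask = mask, amplitude = amplitude)
}

#' Generate one fully corrupted phantom with its ground truth
#'
#' Applies, in order: clean layers, multiplicative speckle, additive
#' periodic background, additive stripes; a single clip into `value_range`
#' happens at the end, so the stored component fields satisfy
#' `noisy = clip(clean * speckle_field + background_field +
#' stripe_amplitude * stripe_mask)` exactly.
#'
#' @param config A [phantom_config].
#' @param seeds Optional list overriding the per-component seeds
#'   (`clean`, `speckle`, `background`, `stripes`); defaults derive from
#'   `config$seed`. [make_volume] uses this to share the stripe and
#'   background patterns across consecutive B-scans.
#' @return A list of class `phantom_truth` with fields `clean`, `noisy`,
#'   `speckle_field`, `background_field`, `stripe_mask`, `stripe_amplitude`,
#'   `config`, `seed`.
#' @export
make_phantom <- function(config, seeds = list()) {
  s <- list(clean = config$seed, speckle = config$seed + 1L,
            background = config$seed + 2L, stripes = config$seed + 3L)
  s[names(seeds)] <- seeds
  cfg_clean <- config
  cfg_clean$seed <- s$clean
  clean <- make_clean_phantom(cfg_clean)
  sp <- add_speckle(clean, config$speckle_shape, seed = s$speckle)
  bg <- add_periodic_background(clean, config$background_amplitude,
                                config$background_periods,
                                seed = s$background)
  st <- add_stripes(clean, config$stripe_count, config$stripe_amplitude,
                    config$stripe_orientation, seed = s$stripes)
  raw <- clean$pixels * sp$field + bg$field + st$amplitude * st$mask
  structure(list(
    clean = clean,
    noisy = clip_bscan(raw, config$value_range),
    speckle_field = sp$field,
    background_field = bg$field,
    stripe_mask = st$mask,
    stripe_amplitude = st$amplitude,
    config = config,
    seed = config$seed
  ), class = "phantom_truth")
}

#' Generate a phantom dataset
#'
#' @param config Base [phantom_config]; image `i` uses `seed + i - 1`
#'   (and therefore a different layer geometry and noise draw per image).
#' @param n_images Number of phantoms (>= 1).
#' @param dir Optional directory: writes `phantom_###_{clean,noisy}.tif`
#'   16-bit pairs plus a JSON sidecar per phantom.
#' @return List of `phantom_truth`.
#' @export
make_dataset <- function(config, n_images, dir = NULL) {
  if (n_images < 1) stop("n_images must be >= 1")
  out <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    out[[i]] <- make_phantom(cfg)
    if (!is.null(dir)) write_phantom(out[[i]], dir, i)
  }
  out
}

#' Generate a volume of consecutive B-scans
#'
#' Emulates what stripe removal relies on: the tissue content and speckle
#' decorrelate from scan to scan (per-scan seeds), while the coherent
#' stripe pattern and the periodic background — both system-induced — are
#' identical across the whole volume (shared seeds).
#'
#' @param config A [phantom_config].
#' @param n_scans Number of consecutive B-scans (>= 2).
#' @return List of `phantom_truth`; all elements share one `stripe_mask`
#'   and one `background_field`.
#' @export
make_volume <- function(config, n_scans) {
  if (n_scans < 2L) stop("a volume needs at least 2 scans")
  lapply(seq_len(n_scans), function(i) {
    make_phantom(config, seeds = list(
      clean = config$seed + 10L * i,
      speckle = config$seed + 10L * i + 1L,
      background = config$seed + 2L,
      stripes = config$seed + 3L))
  })
}

write_phantom <- function(truth, dir, index) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- file.path(dir, sprintf("phantom_%03d", index))
  write_bscan(truth$clean, paste0(stem, "_clean.tif"))
  write_bscan(truth$noisy, paste0(stem, "_noisy.tif"))
  side <- list(
    seed = truth$seed,
    size = truth$config$size,
    speckle_shape = truth$config$speckle_shape,
    background_amplitude = truth$config$background_amplitude,
    stripe_count = truth$config$stripe_count,
    files = list(clean = basename(paste0(stem, "_clean.tif")),
                 noisy = basename(paste0(stem, "_noisy.tif")))
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Partition dataset indices into train/validation/test
#'
#' Deterministic contiguous split in the stated ratio (default 8:1:1);
#' remainders are assigned to the training set. Covers all indices with
#' no overlap.
#'
#' @param n Number of images.
#' @param ratio Length-3 positive weights.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, ratio = c(8, 1, 1)) {
  stopifnot(length(ratio) == 3L, all(ratio > 0), n >= 3)
  n_val <- max(1L, floor(n * ratio[2] / sum(ratio)))
  n_test <- max(1L, floor(n * ratio[3] / sum(ratio)))
  n_train <- n - n_val - n_test
  list(train = seq_len(n_train),
       val = n_train + seq_len(n_val),
       test = n_train + n_val + seq_len(n_test))
}

#' Default signal/background regions for phantom SNR
#'
#' Signal = a band inside the first tissue layer (between the deepest point
#' of interface 1 and the shallowest point of interface 2, shrunk by a
#' margin); background = the air rows above the shallowest point of
#' interface 1.
#'
#' @param truth A `phantom_truth`.
#' @param margin Rows excluded on each side of an interface.
#' @return List of logical matrices `signal` and `background`.
#' @export
default_roi_masks <- function(truth, margin = 4L) {
  cfg <- truth$config
  h <- cfg$size[1]; w <- cfg$size[2]
  n <- cfg$n_layers
  if (n < 2L) stop("ROI masks need at least 2 layers (air + tissue)")
  # interfaces were centred at i*h/n with lateral wobble of ~4.5% of h
  wob <- ceiling(0.05 * h)
  b1 <- round(h / n); b2 <- if (n >= 3L) round(2 * h / n) else h
  bg_rows <- seq_len(max(b1 - wob - margin, 1L))
  sig_rows <- (b1 + wob + margin):max(b1 + wob + margin + 1L,
                                      min(b2 - wob - margin, h))
  signal <- matrix(FALSE, h, w); background <- matrix(FALSE, h, w)
  signal[sig_rows, ] <- TRUE
  background[bg_rows, ] <- TRUE
  list(signal = signal, background = background)
}
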