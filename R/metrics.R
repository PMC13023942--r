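#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)`. Identical images return `Inf` (a
#' sentinel, not an error), so averaging code must handle it explicitly.
#'
#' @param a,b [bscan]s or matrices of identical shape.
#' @param data_range Dynamic range of the data; defaults to the declared
#'   `value_range` width when both inputs are [bscan]s.
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(a, b, data_range = NULL) {
  pa <- as_pixels(a); pb <- as_pixels(b)
  if (!all(dim(pa) == dim(pb))) stop("images must have the same shape")
  data_range <- data_range %||%
    (if (is_bscan(a)) diff(a$value_range) else stop("data_range required"))
  if (data_range <= 0) stop("data_range must be > 0")
  mse <- mean((pa - pb)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index
#'
#' Mean local SSIM with the canonical parameters: 11x11 Gaussian window
#' (sigma 1.5), stabilizers `K1 = 0.01`, `K2 = 0.03`, population (not
#' sample) local moments, reflect padding, and the half-window border
#' cropped before averaging — the convention shared by the reference
#' implementations in common image libraries.
#'
#' @param a,b [bscan]s or matrices, min dimension >= 11.
#' @param data_range As in [psnr].
#' @return SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = NULL) {
  pa <- as_pixels(a); pb <- as_pixels(b)
  if (!all(dim(pa) == dim(pb))) stop("images must have the same shape")
  if (min(dim(pa)) < 11L) stop("images smaller than the 11x11 SSIM window")
  data_range <- data_range %||%
    (if (is_bscan(a)) diff(a$value_range) else stop("data_range required"))
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)        # 5 -> 11x11 window
  filt <- function(x) gaussian_filter2(x, sigma, truncate)
  ux <- filt(pa); uy <- filt(pb)
  vx <- filt(pa * pa) - ux * ux
  vy <- filt(pb * pb) - uy * uy
  vxy <- filt(pa * pb) - ux * uy
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  s <- ((2 * ux * uy + c1) * (2 * vxy + c2)) /
    ((ux^2 + uy^2 + c1) * (vx + vy + c2))
  h <- nrow(s); w <- ncol(s)
  mean(s[(r + 1):(h - r), (r + 1):(w - r)])
}

#' Region-of-interest signal-to-noise ratio
#'
#' `20 * log10(mean(img[signal]) / sd(img[background]))`, the ROI-based
#' protocol common in medical image evaluation. A zero background standard
#' deviation returns the `Inf` sentinel.
#'
#' @param img A [bscan] or matrix.
#' @param signal_mask,background_mask Non-empty, disjoint logical matrices.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr <- function(img, signal_mask, background_mask) {
  px <- as_pixels(img)
  if (!any(signal_mask) || !any(background_mask)) {
    stop("both ROI masks must be non-empty")
  }
  if (any(signal_mask & background_mask)) stop("ROI masks must be disjoint")
  s <- mean(px[signal_mask])
  n <- stats::sd(px[background_mask])
  if (n == 0) return(Inf)
  20 * log10(s / n)
}

#' Aggregate metric report
#'
#' @param snr_db,psnr_db,ssim Mean metric values (`NA` allowed for SNR when
#'   no ROI masks are available).
#' @param reference_kind `"pseudo_clean"` or `"true_clean"`.
#' @param n_images Number of images averaged.
#' @return A list of class `metric_report`.
#' @export
metric_report <- function(snr_db, psnr_db, ssim, reference_kind, n_images) {
  stopifnot(reference_kind %in% c("pseudo_clean", "true_clean"))
  structure(list(snr_db = snr_db, psnr_db = psnr_db, ssim = ssim,
                 reference_kind = reference_kind,
                 n_images = as.integer(n_images)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report [%s], n = %d>\n  SNR %s dB | PSNR %s dB | SSIM %s\n",
              x$reference_kind, x$n_images,
              format(x$snr_db, digits = 4), format(x$psnr_db, digits = 4),
              format(x$ssim, digits = 4)))
  invisible(x)
}

#' Pseudo-clean evaluation protocol
#'
#' When no clean reference exists, each noisy scan is split with the fixed
#' subsampling pattern; one half (`g1`) is denoised and the complementary
#' half (`g2`) serves as the pseudo-clean reference. Metrics are averaged
#' over the set. Deterministic given model and data.
#'
#' @param model A function mapping a [bscan] to a denoised [bscan] (e.g.
#'   `function(y) denoise(fit, y)`), applied to the half-resolution `g1`.
#' @param test_set Non-empty list of [bscan]s with even dimensions.
#' @param pattern Subsampling pattern, as in [subsample_pair].
#' @param roi An optional function `bscan -> list(signal, background)`
#'   giving half-resolution SNR masks; `NA` SNR otherwise.
#' @return A [metric_report] (`reference_kind = "pseudo_clean"`) with the
#'   per-image table attached as attribute `per_image`.
#' @export
evaluate_pseudo_clean <- function(model, test_set, pattern = "A",
                                  roi = NULL) {
  if (length(test_set) == 0L) stop("test_set must be non-empty")
  rows <- lapply(test_set, function(y) {
    pair <- subsample_pair(y, pattern)
    pred <- model(pair$g1)
    data.frame(
      psnr_db = psnr(pred, pair$g2),
      ssim = ssim(pred, pair$g2),
      snr_db = if (is.null(roi)) NA_real_ else {
        m <- roi(pred)
        snr(pred, m$signal, m$background)
      }
    )
  })
  tab <- do.call(rbind, rows)
  rep <- metric_report(mean(tab$snr_db), mean(tab$psnr_db), mean(tab$ssim),
                       "pseudo_clean", nrow(tab))
  attr(rep, "per_image") <- tab
  rep
}

#' True-clean evaluation on phantoms
#'
#' Oracle protocol only possible on synthetic data: the full noisy image is
#' denoised and compared against the known clean phantom.
#'
#' @param model A function mapping a [bscan] to a denoised [bscan].
#' @param truths Non-empty list of `phantom_truth` objects.
#' @param use_roi Compute ROI SNR with [default_roi_masks].
#' @return A [metric_report] (`reference_kind = "true_clean"`) with
#'   attribute `per_image`.
#' @export
evaluate_true_clean <- function(model, truths, use_roi = TRUE) {
  if (length(truths) == 0L) stop("truths must be non-empty")
  rows <- lapply(truths, function(tr) {
    pred <- model(tr$noisy)
    data.frame(
      psnr_db = psnr(pred, tr$clean),
      ssim = ssim(pred, tr$clean),
      snr_db = if (!use_roi || tr$config$n_layers < 2L) NA_real_ else {
        m <- default_roi_masks(tr)
        snr(pred, m$signal, m$background)
      }
    )
  })
  tab <- do.call(rbind, rows)
  rep <- metric_report(mean(tab$snr_db), mean(tab$psnr_db), mean(tab$ssim),
                       "true_clean", nrow(tab))
  attr(rep, "per_image") <- tab
  rep
}
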