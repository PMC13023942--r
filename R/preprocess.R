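#' Stripe-removal specification
#'
#' Coherent stripes from parasitic reflections are spatially consistent
#' across consecutive B-scans while tissue speckle decorrelates, so the
#' per-pixel mean over a stack of scans is the natural statistic to detect
#' them on.
#'
#' @param stack_depth Number of consecutive B-scans averaged (>= 2).
#' @param threshold Deviation (intensity units) of a line's stack-mean
#'   profile from its robust baseline above which the line is flagged as a
#'   stripe; `NULL` selects the automatic rule (3 x the MAD-based scale of
#'   the deviations).
#' @param replacement `"interpolate"` (linear interpolation across the
#'   stripe from unflagged neighbors along the perpendicular axis) or
#'   `"median"` (median of the nearest unflagged neighbors).
#' @return A list of class `stripe_removal_spec`.
#' @export
stripe_removal_spec <- function(stack_depth = 8L, threshold = NULL,
                                replacement = c("interpolate", "median")) {
  replacement <- match.arg(replacement)
  if (stack_depth < 2L) stop("stack_depth must be >= 2")
  structure(list(stack_depth = as.integer(stack_depth),
                 threshold = threshold, replacement = replacement),
            class = "stripe_removal_spec")
}

#' Remove coherent stripe artifacts from a B-scan volume
#'
#' (1) average the stack; (2) flag rows/columns whose stack-mean line
#' profile deviates from a robust (running-median) baseline by more than
#' the threshold; (3) replace flagged lines in every scan by interpolation
#' from unflagged neighbors along the perpendicular axis.
#'
#' @param volume List of [bscan]s (>= `stack_depth`, identical shapes).
#' @param spec A [stripe_removal_spec].
#' @return List of corrected [bscan]s, with attributes `stripe_rows` and
#'   `stripe_cols` (the flagged line indices).
#' @export
remove_stripes <- function(volume, spec = stripe_removal_spec()) {
  if (length(volume) < spec$stack_depth) {
    stop(sprintf("need at least stack_depth = %d scans, got %d",
                 spec$stack_depth, length(volume)))
  }
  shapes <- vapply(volume, function(b) dim(as_pixels(b)), integer(2))
  if (any(shapes != shapes[, 1])) stop("all B-scans must share one shape")
  stack <- Reduce(`+`, lapply(volume[seq_len(spec$stack_depth)],
                              as_pixels)) / spec$stack_depth
  flag_lines <- function(profile) {
    k <- min(9L, 2L * (length(profile) %/% 2L) - 1L)
    base <- stats::runmed(profile, k, endrule = "median")
    dev <- profile - base
    # auto rule: 3x the MAD scale of the residuals, floored by 4x their
    # 90th percentile (a running median leaves most residuals exactly
    # zero, which degenerates the MAD; stripes occupy far less than 10%
    # of the lines, so the upper quantile tracks the smooth-structure
    # residual scale)
    thr <- spec$threshold %||% max(3 * mad(dev, constant = 1.4826),
                                   4 * stats::quantile(abs(dev), 0.9))
    which(abs(dev) > thr)
  }
  rows <- flag_lines(rowMeans(stack))
  cols <- flag_lines(colMeans(stack))
  out <- lapply(volume, function(b) {
    px <- as_pixels(b)
    px <- replace_lines(px, rows, along = "row", how = spec$replacement)
    px <- t(replace_lines(t(px), cols, along = "row", how = spec$replacement))
    if (is_bscan(b)) bscan(px, b$value_range, validate = FALSE) else px
  })
  attr(out, "stripe_rows") <- rows
  attr(out, "stripe_cols") <- cols
  out
}

# Replace the given rows of `px` using the nearest unflagged rows above and
# below (linear interpolation or median of the two).
replace_lines <- function(px, lines, along = "row", how = "interpolate") {
  if (length(lines) == 0L) return(px)
  n <- nrow(px)
  good <- setdiff(seq_len(n), lines)
  if (length(good) < 2L) stop("too many flagged lines to interpolate from")
  for (i in lines) {
    lo <- max(good[good < i], -Inf)
    hi <- min(good[good > i], Inf)
    if (!is.finite(lo)) {
      px[i, ] <- px[hi, ]
    } else if (!is.finite(hi)) {
      px[i, ] <- px[lo, ]
    } else if (how == "interpolate") {
      w <- (i - lo) / (hi - lo)
      px[i, ] <- (1 - w) * px[lo, ] + w * px[hi, ]
    } else {
      px[i, ] <- (px[lo, ] + px[hi, ]) / 2
    }
  }
  px
}

#' Locate dominant periodic-noise frequencies
#'
#' Finds the `n_peaks` largest local maxima of the centered log-magnitude
#' spectrum outside a disk of `exclude_radius` bins around DC. Conjugate
#' twins (a real image's spectrum is symmetric) are reported once, with the
#' canonical representative having positive column bin (or positive row bin
#' when the column bin is 0). Peaks are returned strongest first.
#'
#' @param img A [bscan] or matrix.
#' @param n_peaks Maximum number of peaks to report (>= 1).
#' @param exclude_radius Radius in bins of the DC exclusion disk.
#' @return Integer matrix with columns `row_bin`, `col_bin` in centered
#'   coordinates (possibly zero rows if no peak clears the noise floor).
#' @export
detect_dominant_frequencies <- function(img, n_peaks = 4L,
                                        exclude_radius = 4) {
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  px <- as_pixels(img)
  h <- nrow(px); w <- ncol(px)
  if (exclude_radius >= min(h, w) / 2) {
    stop("exclude_radius covers the whole spectrum")
  }
  mag <- Mod(fftshift2(stats::fft(px)))
  rb <- matrix(centered_bins(h), h, w)
  cb <- matrix(centered_bins(w), h, w, byrow = TRUE)
  dist2 <- rb^2 + cb^2
  cand <- mag
  cand[dist2 < exclude_radius^2] <- -Inf   # strict interior of the disk
  # 8-neighbor local maxima
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- cand
  ismax <- cand > -Inf
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    ismax <- ismax & (cand >= pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  }
  # noise floor: a genuine periodic component towers above the typical
  # off-peak magnitude and carries non-negligible energy
  floor_mag <- stats::median(mag[dist2 > exclude_radius^2])
  total_pow <- sum(mag^2)
  keep <- which(ismax & cand > 10 * floor_mag & cand^2 > 1e-12 * total_pow)
  if (length(keep) == 0L) {
    return(matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("row_bin", "col_bin"))))
  }
  ord <- keep[order(cand[keep], decreasing = TRUE)]
  seen <- matrix(numeric(0), 0, 2)
  for (k in ord) {
    if (nrow(seen) >= n_peaks) break
    r <- rb[k]; c <- cb[k]
    # canonical representative of the conjugate pair
    if (c < 0 || (c == 0 && r < 0)) { r <- -r; c <- -c }
    if (nrow(seen) == 0L ||
        !any(seen[, 1] == r & seen[, 2] == c)) {
      seen <- rbind(seen, c(r, c))
    }
  }
  colnames(seen) <- c("row_bin", "col_bin")
  storage.mode(seen) <- "integer"
  seen
}

#' Notch-filter specification
#'
#' @param notches Matrix or data frame with columns `row_bin`, `col_bin`
#'   (centered coordinates), `radius` (bins, > 0) and `depth` (`[0, 1]`;
#'   1 = full suppression). The conjugate twin of every notch is implied.
#' @param gaussian_sigma Spatial Gaussian de-ringing blur in pixels
#'   (0 disables).
#' @return A list of class `notch_spec`.
#' @export
notch_spec <- function(notches, gaussian_sigma = 0) {
  notches <- as.data.frame(notches)
  need <- c("row_bin", "col_bin", "radius", "depth")
  if (!all(need %in% names(notches))) {
    stop("notches needs columns: ", paste(need, collapse = ", "))
  }
  if (any(notches$radius <= 0)) stop("notch radius must be > 0")
  if (any(notches$depth < 0 | notches$depth > 1)) {
    stop("notch depth must lie in [0, 1]")
  }
  structure(list(notches = notches, gaussian_sigma = gaussian_sigma),
            class = "notch_spec")
}

#' Build a notch spec automatically from detected peaks
#'
#' @param img A [bscan] or matrix.
#' @param n_peaks,exclude_radius Passed to [detect_dominant_frequencies].
#' @param radius,depth,gaussian_sigma Notch profile parameters.
#' @return A [notch_spec] (possibly with zero notches).
#' @export
auto_notch_spec <- function(img, n_peaks = 4L, exclude_radius = 4,
                            radius = 2, depth = 1, gaussian_sigma = 0.8) {
  pk <- detect_dominant_frequencies(img, n_peaks, exclude_radius)
  notch_spec(data.frame(row_bin = pk[, "row_bin"], col_bin = pk[, "col_bin"],
                        radius = radius, depth = depth),
             gaussian_sigma = gaussian_sigma)
}

#' Apply a Gaussian-profile notch filter
#'
#' Multiplies the centered spectrum by `prod(1 - depth * G)` where `G` is a
#' radial Gaussian bump of the stated radius at each notch and its
#' conjugate twin (keeping the mask conjugate-symmetric, so the output is
#' real), inverse-transforms, optionally blurs with `gaussian_sigma` to
#' suppress residual ringing, and clips to the value range. Smooth notch
#' profiles are used instead of ideal (binary) notches because they ring
#' far less to begin with.
#'
#' @param img A [bscan] or matrix with finite values.
#' @param spec A [notch_spec].
#' @return Same type as the input.
#' @export
notch_filter <- function(img, spec) {
  px <- as_pixels(img)
  if (!all(is.finite(px))) stop("notch_filter input must be finite")
  h <- nrow(px); w <- ncol(px)
  if (nrow(spec$notches) > 0) {
    if (any(abs(spec$notches$row_bin) > h / 2) ||
        any(abs(spec$notches$col_bin) > w / 2)) {
      stop("notch bins outside spectrum bounds")
    }
  }
  rb <- matrix(centered_bins(h), h, w)
  cb <- matrix(centered_bins(w), h, w, byrow = TRUE)
  mask <- matrix(1, h, w)
  if (nrow(spec$notches) > 0) {
    for (i in seq_len(nrow(spec$notches))) {
      nt <- spec$notches[i, ]
      for (sgn in c(1, -1)) {
        d2 <- (rb - sgn * nt$row_bin)^2 + (cb - sgn * nt$col_bin)^2
        mask <- mask * (1 - nt$depth * exp(-d2 / (2 * nt$radius^2)))
        if (nt$row_bin == 0 && nt$col_bin == 0) break
      }
    }
  }
  spec_c <- fftshift2(stats::fft(px)) * mask
  out <- Re(stats::fft(ifftshift2(spec_c), inverse = TRUE)) / (h * w)
  if (spec$gaussian_sigma > 0) {
    out <- gaussian_filter2(out, spec$gaussian_sigma)
  }
  if (is_bscan(img)) clip_bscan(out, img$value_range) else out
}

#' Full classical preprocessing of a B-scan volume
#'
#' Stack-based stripe removal followed by automatic notch filtering of the
#' periodic background (notches detected on the stripe-free stack mean and
#' applied to every scan).
#'
#' @param volume List of [bscan]s.
#' @param stripe_spec A [stripe_removal_spec].
#' @param n_peaks,exclude_radius,radius,depth,gaussian_sigma Notch options,
#'   as in [auto_notch_spec].
#' @return List of preprocessed [bscan]s; the applied [notch_spec] is
#'   attached as attribute `notch_spec`.
#' @export
preprocess_volume <- function(volume, stripe_spec = stripe_removal_spec(),
                              n_peaks = 4L, exclude_radius = 4, radius = 2,
                              depth = 1, gaussian_sigma = 0.8) {
  destriped <- remove_stripes(volume, stripe_spec)
  stack <- Reduce(`+`, lapply(destriped, as_pixels)) / length(destriped)
  spec <- auto_notch_spec(stack, n_peaks, exclude_radius, radius, depth,
                          gaussian_sigma)
  out <- lapply(destriped, notch_filter, spec = spec)
  attr(out, "stripe_rows") <- attr(destriped, "stripe_rows")
  attr(out, "stripe_cols") <- attr(destriped, "stripe_cols")
  attr(out, "notch_spec") <- spec
  out
}
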