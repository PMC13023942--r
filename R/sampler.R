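#' Deterministic neighbor subsampling
#'
#' Splits a noisy B-scan into the two complementary half-resolution images
#' `(g1, g2)` used by the Neighbor2Neighbor training scheme. The image is
#' partitioned into non-overlapping 2x2 cells and each cell contributes one
#' fixed position to `g1` and an adjacent one to `g2`; the assignment is a
#' pure function of the image shape and `pattern`, identical across
#' training, validation and test. There is no randomness anywhere.
#'
#' Pattern `"A"` (default) takes the top-left pixel of every cell for `g1`
#' and the top-right for `g2`: the split direction is lateral, so axial
#' layer boundaries — where OCT anatomy lives — are never separated.
#' Pattern `"B"` is the axial counterpart (top-left / bottom-left),
#' available for ablation.
#'
#' @param y A [bscan] or numeric matrix with even dimensions.
#' @param pattern `"A"` or `"B"`.
#' @return A list of class `subsampled_pair` with `g1`, `g2` (same type as
#'   the input), `pattern` and `source_shape`.
#' @export
subsample_pair <- function(y, pattern = c("A", "B")) {
  pattern <- match.arg(pattern)
  px <- as_pixels(y)
  h <- nrow(px); w <- ncol(px)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop(sprintf(
      "subsampling needs even dimensions (got %dx%d); crop or pad first",
      h, w
    ))
  }
  idx <- subsample_indices(h, w, pattern)
  g1 <- px[idx$rows1, idx$cols1, drop = FALSE]
  g2 <- px[idx$rows2, idx$cols2, drop = FALSE]
  if (is_bscan(y)) {
    g1 <- bscan(g1, y$value_range, validate = FALSE)
    g2 <- bscan(g2, y$value_range, validate = FALSE)
  }
  structure(list(g1 = g1, g2 = g2, pattern = pattern,
                 source_shape = c(h, w)),
            class = "subsampled_pair")
}

# Row/column index sets of the two sub-images in source coordinates.
subsample_indices <- function(h, w, pattern = "A") {
  odd_r <- seq(1L, h, by = 2L); odd_c <- seq(1L, w, by = 2L)
  switch(pattern,
    A = list(rows1 = odd_r, cols1 = odd_c,        # top-left
             rows2 = odd_r, cols2 = odd_c + 1L),  # top-right
    B = list(rows1 = odd_r, cols1 = odd_c,        # top-left
             rows2 = odd_r + 1L, cols2 = odd_c),  # bottom-left
    stop("unknown pattern: ", pattern)
  )
}

#' Empirical noise-consistency gap
#'
#' The subsampling scheme is built so the conditional means of the two
#' sub-images agree; `|mean(g2) - mean(g1)|` estimates the residual gap.
#' Diagnostic only — it shrinks like `n^(-1/2)` for i.i.d. noise.
#'
#' @param g1,g2 Matching [bscan]s or matrices.
#' @return A single non-negative number.
#' @export
noise_consistency_gap <- function(g1, g2) {
  a <- as_pixels(g1); b <- as_pixels(g2)
  if (!all(dim(a) == dim(b))) stop("g1 and g2 must have the same shape")
  abs(mean(b) - mean(a))
}

#' Nearest-neighbor upsampling to full size
#'
#' Replicates every pixel into its 2x2 cell; used to build the pseudo-clean
#' full-size image for the frequency-consistency loss.
#'
#' @param sub Half-resolution [bscan] or matrix.
#' @param target_shape `(H, W)`, exactly twice the input dims.
#' @return Same type as the input, at `target_shape`.
#' @export
upsample_to_full <- function(sub, target_shape) {
  px <- as_pixels(sub)
  if (!all(target_shape == 2L * dim(px))) {
    stop("target_shape must be exactly twice the sub-image dimensions")
  }
  out <- px[rep(seq_len(nrow(px)), each = 2L),
            rep(seq_len(ncol(px)), each = 2L), drop = FALSE]
  if (is_bscan(sub)) out <- bscan(out, sub$value_range, validate = FALSE)
  out
}
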