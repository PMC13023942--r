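#' Orthonormal single-level 2D Haar transform
#'
#' For every non-overlapping 2x2 block `[a b; c d]` (a = top-left, b =
#' top-right, c = bottom-left, d = bottom-right):
#' `LL = (a+b+c+d)/2`, `LH = (c+d-a-b)/2`, `HL = (b+d-a-c)/2`,
#' `HH = (a+d-b-c)/2`. The transform is orthonormal, so total energy is
#' conserved and [haar_idwt2] is its exact inverse.
#'
#' Accepts a matrix (H x W) or a 3D/4D array whose first two dimensions are
#' spatial; the transform is applied per channel/sample.
#'
#' @param x Numeric matrix or array with even spatial dimensions.
#' @return A list of class `wavelet_subbands` with fields `LL`, `LH`, `HL`,
#'   `HH`, each of half the spatial extent.
#' @export
haar_dwt2 <- function(x) {
  d <- dim(x)
  stopifnot_even(d[1], d[2], "Haar input")
  or <- seq(1L, d[1], by = 2L); oc <- seq(1L, d[2], by = 2L)
  sub <- function(ri, ci) {
    if (length(d) == 2L) x[ri, ci, drop = FALSE]
    else if (length(d) == 3L) x[ri, ci, , drop = FALSE]
    else x[ri, ci, , , drop = FALSE]
  }
  a <- sub(or, oc); b <- sub(or, oc + 1L)
  cc <- sub(or + 1L, oc); dd <- sub(or + 1L, oc + 1L)
  structure(list(
    LL = (a + b + cc + dd) / 2,
    LH = (cc + dd - a - b) / 2,
    HL = (b + dd - a - cc) / 2,
    HH = (a + dd - b - cc) / 2
  ), class = "wavelet_subbands")
}

#' @rdname haar_dwt2
#' @param s A `wavelet_subbands` list (fields `LL`, `LH`, `HL`, `HH` of
#'   identical shape).
#' @export
haar_idwt2 <- function(s) {
  dims <- lapply(s[c("LL", "LH", "HL", "HH")], dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("subbands must all have the same shape")
  }
  LL <- s$LL; LH <- s$LH; HL <- s$HL; HH <- s$HH
  d <- dim(LL)
  out_d <- d; out_d[1:2] <- 2L * d[1:2]
  out <- array(0, out_d)
  or <- seq(1L, out_d[1], by = 2L); oc <- seq(1L, out_d[2], by = 2L)
  put <- function(ri, ci, v) {
    if (length(d) == 2L) out[ri, ci] <<- v
    else if (length(d) == 3L) out[ri, ci, ] <<- v
    else out[ri, ci, , ] <<- v
  }
  put(or, oc, (LL - LH - HL + HH) / 2)           # a
  put(or, oc + 1L, (LL - LH + HL - HH) / 2)      # b
  put(or + 1L, oc, (LL + LH - HL - HH) / 2)      # c
  put(or + 1L, oc + 1L, (LL + LH + HL + HH) / 2) # d
  if (length(d) == 2L) out <- matrix(out, out_d[1], out_d[2])
  out
}

#' Wavelet-guided spectral pooling (functional form)
#'
#' The spectral pooling step used inside the network, exposed on plain
#' matrices/arrays: decompose with [haar_dwt2], refine the LL band with a
#' channel-mixing map, attenuate the three detail bands by `(1 - lambda)`,
#' and reconstruct with [haar_idwt2]. With `lambda = 0` and an identity
#' refiner the operation is the identity; with `lambda = 1` it equals the
#' 2x2 block-average reconstruction.
#'
#' @param x Matrix (single channel) or 3D array (H, W, C).
#' @param lambda Spectral mixing strength in `[0, 1]`; default 0.65.
#' @param ll_weight Optional `C x C` mixing matrix applied across channels
#'   of the LL band (identity by default). For matrices this is a scalar.
#' @return Same shape as `x`.
#' @export
wspm_apply <- function(x, lambda = 0.65, ll_weight = NULL) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  s <- haar_dwt2(x)
  if (!is.null(ll_weight)) {
    if (is.matrix(x)) {
      s$LL <- s$LL * as.numeric(ll_weight)
    } else {
      d <- dim(s$LL)
      flat <- matrix(s$LL, prod(d[1:2]), d[3])
      s$LL <- array(flat %*% t(ll_weight), d)
    }
  }
  s$LH <- (1 - lambda) * s$LH
  s$HL <- (1 - lambda) * s$HL
  s$HH <- (1 - lambda) * s$HH
  haar_idwt2(s)
}
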