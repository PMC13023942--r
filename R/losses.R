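#' Loss weights for the self-supervised objective
#'
#' The total training objective is
#' `total = lambda1 * L_pred + lambda2 * L_cons + lambda3 * L_freq +
#' gamma * L_reg`, with defaults `(0.8, 0.1, 0.1)` chosen by grid search on
#' validation SSIM and the retained Neighbor2Neighbor regularizer weight
#' `gamma = 0.01`.
#'
#' @param lambda1,lambda2,lambda3,gamma Non-negative weights.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(lambda1 = 0.8, lambda2 = 0.1, lambda3 = 0.1,
                         gamma = 0.01) {
  w <- c(lambda1, lambda2, lambda3, gamma)
  if (any(!is.finite(w)) || any(w < 0)) stop("loss weights must be >= 0")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 gamma = gamma), class = "loss_weights")
}

#' Sub-image prediction loss
#'
#' Mean absolute difference between the denoised first sub-image and the
#' complementary sub-image acting as supervision: `mean(|f(g1) - g2|)`.
#'
#' @param pred_g1,g2 [bscan]s or matrices of identical shape.
#' @return A non-negative scalar.
#' @export
sub_image_prediction_loss <- function(pred_g1, g2) {
  a <- as_pixels(pred_g1); b <- as_pixels(g2)
  if (!all(dim(a) == dim(b))) stop("shapes differ")
  mean(abs(a - b))
}

#' Noise-distribution consistency loss
#'
#' Mean squared difference between the denoised versions of the two
#' sub-images: `mean((f(g1) - f(g2))^2)`. Penalizes the network for
#' treating the two noise realizations differently, which counteracts
#' over-smoothing.
#'
#' @param pred_g1,pred_g2 [bscan]s or matrices of identical shape.
#' @return A non-negative scalar.
#' @export
noise_consistency_loss <- function(pred_g1, pred_g2) {
  a <- as_pixels(pred_g1); b <- as_pixels(pred_g2)
  if (!all(dim(a) == dim(b))) stop("shapes differ")
  mean((a - b)^2)
}

#' Frequency-domain consistency loss
#'
#' Mean squared modulus of the difference between the centered 2D Fourier
#' transforms of the full-size denoised image and the pseudo-clean image,
#' under the orthonormal FFT convention (`F(x) = fft(x) / sqrt(H * W)`) and
#' normalized by pixel count — which makes the value resolution-independent
#' and, by Parseval's theorem, exactly equal to the spatial-domain MSE.
#'
#' @param denoised_full,x_pseudo [bscan]s or matrices of identical shape.
#'   `x_pseudo` is built by [build_pseudo_clean].
#' @return A non-negative real scalar.
#' @export
frequency_consistency_loss <- function(denoised_full, x_pseudo) {
  a <- as_pixels(denoised_full); b <- as_pixels(x_pseudo)
  if (!all(dim(a) == dim(b))) stop("shapes differ")
  n <- length(a)
  fa <- stats::fft(a) / sqrt(n)
  fb <- stats::fft(b) / sqrt(n)
  mean(Mod(fa - fb)^2)
}

#' Pseudo-clean full-size image
#'
#' Averages the complementary sub-images (halving the variance of
#' independent per-pixel noise) and replicates the result back to full
#' size; the frequency-consistency loss compares the full-size denoised
#' output against this image.
#'
#' @param y A [bscan] or matrix with even dimensions.
#' @param pattern Subsampling pattern.
#' @return Same type/shape as `y`.
#' @export
build_pseudo_clean <- function(y, pattern = "A") {
  pair <- subsample_pair(y, pattern)
  avg <- (as_pixels(pair$g1) + as_pixels(pair$g2)) / 2
  if (is_bscan(y)) avg <- bscan(avg, y$value_range, validate = FALSE)
  upsample_to_full(avg, dim(as_pixels(y)))
}

#' Neighbor2Neighbor regularizer
#'
#' `mean(((f(g1(y)) - g2(y)) - (g1(f(y)) - g2(f(y))))^2)`: the mismatch
#' between the subsample-then-denoise residual and the denoise-then-
#' subsample residual. It vanishes for the identity model and pushes the
#' denoiser to commute with subsampling, mitigating over-smoothing.
#'
#' @param model A function mapping a [bscan]/matrix to a denoised image of
#'   the same shape (it is applied both at half and at full resolution).
#' @param y A [bscan] or matrix with even dimensions.
#' @param pattern Subsampling pattern.
#' @return A non-negative scalar.
#' @export
n2n_regularizer <- function(model, y, pattern = "A") {
  pair <- subsample_pair(y, pattern)
  f_g1 <- as_pixels(model(pair$g1))
  fy <- model(y)
  fpair <- subsample_pair(fy, pattern)
  res1 <- f_g1 - as_pixels(pair$g2)
  res2 <- as_pixels(fpair$g1) - as_pixels(fpair$g2)
  mean((res1 - res2)^2)
}

#' Weighted total loss
#'
#' @param parts Numeric vector or list with elements `l1_pred`,
#'   `l2_consistency`, `l_freq`, `l_reg` (in that order if unnamed).
#' @param weights A [loss_weights].
#' @return A list of class `loss_breakdown` with the four parts, the
#'   weights, and `total` satisfying the exact arithmetic identity
#'   `total = lambda1*l1 + lambda2*l2 + lambda3*lf + gamma*lr`.
#' @export
total_loss <- function(parts, weights = loss_weights()) {
  p <- unlist(parts)
  names(p) <- NULL
  if (length(p) != 4L) stop("parts must hold exactly 4 loss components")
  bad <- which(!is.finite(p))
  if (length(bad)) {
    nm <- c("l1_pred", "l2_consistency", "l_freq", "l_reg")[bad[1]]
    stop("non-finite loss component: ", nm)
  }
  total <- weights$lambda1 * p[1] + weights$lambda2 * p[2] +
    weights$lambda3 * p[3] + weights$gamma * p[4]
  structure(list(l1_pred = p[1], l2_consistency = p[2], l_freq = p[3],
                 l_reg = p[4], total = total, weights = weights),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "<loss: total %.6g = %.3g*%.4g + %.3g*%.4g + %.3g*%.4g + %.3g*%.4g>\n",
    x$total, x$weights$lambda1, x$l1_pred, x$weights$lambda2,
    x$l2_consistency, x$weights$lambda3, x$l_freq, x$weights$gamma, x$l_reg))
  invisible(x)
}

#' Grid search over loss weights
#'
#' Evaluates a user-supplied scoring function (typically validation SSIM
#' after a short training run) over the grid `lambda in {0, 0.1, ..., 1}^3`
#' (step configurable) and returns the argmax together with the full score
#' table, so the selection can be audited by re-scanning the scores.
#'
#' @param score_fn `function(lambda1, lambda2, lambda3) -> numeric(1)`;
#'   larger is better.
#' @param step Grid step in `[0, 1]` (default 0.1).
#' @param gamma Fixed regularizer weight recorded alongside.
#' @return List with `best` (a [loss_weights]), `best_score`, and `scores`
#'   (a data frame of every evaluated combination).
#' @export
grid_search_loss_weights <- function(score_fn, step = 0.1, gamma = 0.01) {
  grid <- seq(0, 1, by = step)
  combos <- expand.grid(lambda1 = grid, lambda2 = grid, lambda3 = grid)
  combos$score <- mapply(score_fn, combos$lambda1, combos$lambda2,
                         combos$lambda3)
  best <- which.max(combos$score)
  list(
    best = loss_weights(combos$lambda1[best], combos$lambda2[best],
                        combos$lambda3[best], gamma),
    best_score = combos$score[best],
    scores = combos
  )
}
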