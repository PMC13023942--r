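#' Training configuration
#'
#' Defaults follow the reference training recipe: Adam with betas
#' `(0.9, 0.999)`, initial learning rate `1e-4` halved every 20 epochs,
#' batch size 4, 100 epochs, 64-pixel patches. [desk_preset] gives a
#' scaled-down configuration for CPU-scale experiments on small phantoms.
#'
#' @param epochs Training epochs (>= 0).
#' @param batch_size Images per step.
#' @param learning_rate Initial Adam learning rate (> 0).
#' @param lr_halving_period Epochs between learning-rate halvings.
#' @param adam_betas Adam `(beta1, beta2)`.
#' @param seed Run seed: fully determines initialization, patch order and
#'   every logged number.
#' @param patch_size Square training patch edge, divisible by 16.
#' @param ablation Variant to train: `"full"`, `"no_wspm"`, `"no_ferfb"`
#'   (structural switches) or `"n2n_baseline"` (plain network trained with
#'   the plain Neighbor2Neighbor objective: MSE prediction loss plus the
#'   gamma-weighted regularizer only).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 4L,
                         learning_rate = 1e-4, lr_halving_period = 20L,
                         adam_betas = c(0.9, 0.999), seed = 1L,
                         patch_size = 64L,
                         ablation = c("full", "no_wspm", "no_ferfb",
                                      "n2n_baseline")) {
  ablation <- match.arg(ablation)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (patch_size %% 16L != 0L) stop("patch_size must be divisible by 16")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_halving_period = as.integer(lr_halving_period),
                 adam_betas = adam_betas, seed = as.integer(seed),
                 patch_size = as.integer(patch_size), ablation = ablation),
            class = "train_config")
}

#' @rdname train_config
#' @export
desk_preset <- function(seed = 1L, ablation = "full") {
  train_config(epochs = 5L, batch_size = 1L, learning_rate = 1e-3,
               lr_halving_period = 2L, seed = seed, ablation = ablation)
}

#' @rdname train_config
#' @export
full_preset <- function(seed = 1L, ablation = "full") {
  train_config(seed = seed, ablation = ablation)
}

#' Learning rate at a (0-based) epoch
#'
#' Step schedule: the rate is halved every `lr_halving_period` epochs.
#'
#' @param cfg A [train_config].
#' @param epoch 0-based epoch index.
#' @return The learning rate in effect during that epoch.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$learning_rate * 0.5^(epoch %/% cfg$lr_halving_period)
}

# Apply the structural part of an ablation switch to the net config.
apply_ablation <- function(net_cfg, ablation) {
  if (ablation %in% c("no_wspm", "n2n_baseline")) net_cfg$use_wspm <- FALSE
  if (ablation %in% c("no_ferfb", "n2n_baseline")) net_cfg$use_ferfb <- FALSE
  net_cfg
}

# Random even-aligned square crop (keeps 2x2 subsampling cells intact).
crop_patch <- function(px, size) {
  h <- nrow(px); w <- ncol(px)
  if (h == size && w == size) return(px)
  if (h < size || w < size) stop("image smaller than patch_size")
  r0 <- 2L * sample.int((h - size) %/% 2L + 1L, 1L) - 1L
  c0 <- 2L * sample.int((w - size) %/% 2L + 1L, 1L) - 1L
  px[r0:(r0 + size - 1L), c0:(c0 + size - 1L), drop = FALSE]
}

#' Train a denoiser
#'
#' Self-supervised loop: per step, a batch of even-aligned patches is split
#' into the complementary sub-image pair; the network denoises `g1`, `g2`
#' and the full patch; the weighted objective (prediction + consistency +
#' frequency terms plus the regularizer — or the plain baseline objective
#' for `ablation = "n2n_baseline"`) is backpropagated through the
#' package's tape and the parameters take an Adam step. Validation SSIM
#' under the pseudo-clean protocol is computed each epoch and the
#' best-validation parameters are retained.
#'
#' @param train_set,val_set Non-empty lists of noisy [bscan]s.
#' @param net_cfg A [net_config] (ablation switches are derived from
#'   `train_cfg$ablation` automatically).
#' @param train_cfg A [train_config].
#' @param weights A [loss_weights].
#' @param pattern Subsampling pattern (fixed across the whole run).
#' @param log_csv Optional path; per-step loss breakdown rows are appended.
#' @param verbose Print per-epoch summaries.
#' @return A list of class `fenoct_fit` with `model` (best-validation
#'   parameters) and `manifest` (configs, seed, per-epoch history table,
#'   best epoch).
#' @export
train <- function(train_set, val_set, net_cfg = net_config(),
                  train_cfg = desk_preset(), weights = loss_weights(),
                  pattern = "A", log_csv = NULL, verbose = FALSE) {
  if (length(train_set) == 0L || length(val_set) == 0L) {
    stop("train_set and val_set must be non-empty")
  }
  net_cfg <- apply_ablation(net_cfg, train_cfg$ablation)
  model <- build_feunet(net_cfg, seed = train_cfg$seed)
  params <- model$params
  opt <- adam_init(params)
  ps <- train_cfg$patch_size
  sub <- subsample_indices(ps, ps, pattern)
  history <- list()
  best <- list(ssim = -Inf, values = NULL, epoch = NA_integer_)
  step_id <- 0L

  run_epochs <- function() {
    for (ep in seq_len(train_cfg$epochs)) {
      lr <- lr_at_epoch(train_cfg, ep - 1L)
      ord <- sample(length(train_set))
      batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
      ep_parts <- numeric(5)
      for (bi in batches) {
        y_arr <- array(0, c(ps, ps, 1L, length(bi)))
        for (k in seq_along(bi)) {
          y_arr[, , 1L, k] <- crop_patch(as_pixels(train_set[[bi[k]]]), ps)
        }
        g1 <- y_arr[sub$rows1, sub$cols1, , , drop = FALSE]
        g2 <- y_arr[sub$rows2, sub$cols2, , , drop = FALSE]
        bd <- train_step(model, params, y_arr, g1, g2, sub, weights,
                         train_cfg$ablation)
        if (!is.finite(bd$total)) {
          stop(sprintf(
            paste0("non-finite loss at step %d: l1=%g l2=%g lf=%g lr=%g; ",
                   "lower the learning rate"),
            step_id + 1L, bd$l1_pred, bd$l2_consistency, bd$l_freq, bd$l_reg))
        }
        opt <<- adam_step(opt, params, lr, train_cfg$adam_betas)
        ad_zero_grads(params)
        step_id <<- step_id + 1L
        ep_parts <- ep_parts + c(bd$l1_pred, bd$l2_consistency, bd$l_freq,
                                 bd$l_reg, bd$total)
        if (!is.null(log_csv)) {
          row <- data.frame(step = step_id, epoch = ep, l1_pred = bd$l1_pred,
                            l2_consistency = bd$l2_consistency,
                            l_freq = bd$l_freq, l_reg = bd$l_reg,
                            total = bd$total)
          utils::write.table(row, log_csv, append = file.exists(log_csv),
                             col.names = !file.exists(log_csv),
                             row.names = FALSE, sep = ",")
        }
      }
      ep_parts <- ep_parts / length(batches)
      val <- evaluate_pseudo_clean(function(b) denoise(model, b),
                                   val_set, pattern)
      if (val$ssim > best$ssim) {
        best <<- list(ssim = val$ssim,
                      values = lapply(params, function(p) p$value),
                      epoch = ep)
      }
      history[[ep]] <<- data.frame(
        epoch = ep, lr = lr, l1_pred = ep_parts[1],
        l2_consistency = ep_parts[2], l_freq = ep_parts[3],
        l_reg = ep_parts[4], total = ep_parts[5], val_ssim = val$ssim)
      if (verbose) {
        message(sprintf("epoch %d: loss %.5f, val SSIM %.4f (lr %.2g)",
                        ep, ep_parts[5], val$ssim, lr))
      }
    }
  }
  with_seed(train_cfg$seed, run_epochs())

  if (!is.null(best$values)) {
    for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("fenoct")),
    net_config = net_cfg, train_config = train_cfg, loss_weights = weights,
    pattern = pattern, seed = train_cfg$seed,
    n_train = length(train_set), n_val = length(val_set),
    steps = step_id, best_epoch = best$epoch,
    best_val_ssim = if (is.finite(best$ssim)) best$ssim else NA_real_,
    history = if (length(history)) do.call(rbind, history) else
      data.frame())
  structure(list(model = model, manifest = manifest), class = "fenoct_fit")
}

# One optimization step; returns the loss breakdown (gradients are left on
# the parameters for the optimizer).
train_step <- function(model, params, y_arr, g1, g2, sub, weights,
                       ablation) {
  n_g2 <- ad_const(g2)
  b <- dim(g1)[4]
  f_y <- feunet_node(model, ad_const(y_arr))
  s1 <- nn_subsample(f_y, sub$rows1, sub$cols1)
  s2 <- nn_subsample(f_y, sub$rows2, sub$cols2)
  if (ablation == "n2n_baseline") {
    f_g1 <- feunet_node(model, ad_const(g1))
    resid <- nn_sub(nn_sub(f_g1, n_g2), nn_sub(s1, s2))
    reg <- nn_mean_sq(resid)
    lpred <- nn_mean_sq(nn_sub(f_g1, n_g2))
    total <- nn_wsum(list(lpred, reg), c(1, weights$gamma))
    ad_backward(total)
    return(list(l1_pred = lpred$value, l2_consistency = 0, l_freq = 0,
                l_reg = reg$value, total = total$value))
  }
  # one batched pass over both sub-images (exactly equivalent to two
  # passes: every layer acts per sample)
  g12 <- array(0, c(dim(g1)[1:3], 2L * b))
  g12[, , , seq_len(b)] <- g1
  g12[, , , b + seq_len(b)] <- g2
  f_g12 <- feunet_node(model, ad_const(g12))
  f_g1 <- nn_slice_n(f_g12, seq_len(b))
  f_g2 <- nn_slice_n(f_g12, b + seq_len(b))
  resid <- nn_sub(nn_sub(f_g1, n_g2), nn_sub(s1, s2))
  reg <- nn_mean_sq(resid)
  avg <- (g1 + g2) / 2
  xps <- avg[rep(seq_len(dim(avg)[1]), each = 2L),
             rep(seq_len(dim(avg)[2]), each = 2L), , , drop = FALSE]
  l1 <- nn_mean_abs(nn_sub(f_g1, n_g2))
  l2 <- nn_mean_sq(nn_sub(f_g1, f_g2))
  # orthonormal-FFT frequency consistency: by Parseval this equals the
  # spatial MSE against the pseudo-clean image, which is what is computed
  # (and differentiated) here
  lf <- nn_mean_sq(nn_sub(f_y, ad_const(xps)))
  total <- nn_wsum(list(l1, l2, lf, reg),
                   c(weights$lambda1, weights$lambda2, weights$lambda3,
                     weights$gamma))
  ad_backward(total)
  list(l1_pred = l1$value, l2_consistency = l2$value, l_freq = lf$value,
       l_reg = reg$value, total = total$value)
}

#' Denoise an image
#'
#' Reflect-pads to the next multiple of 16 in each dimension, runs the
#' network, crops back, and clips into the declared value range.
#' Deterministic: the same model and image always give the same output.
#'
#' @param model A `fenoct_fit` or `feunet`.
#' @param img A [bscan] or matrix of any size >= 16x16.
#' @return Same type and shape as the input.
#' @export
denoise <- function(model, img) {
  if (inherits(model, "fenoct_fit")) model <- model$model
  px <- as_pixels(img)
  h <- nrow(px); w <- ncol(px)
  H <- 16L * ceiling(h / 16L); W <- 16L * ceiling(w / 16L)
  ri <- c(seq_len(h), h - seq_len(H - h))
  ci <- c(seq_len(w), w - seq_len(W - w))
  out <- feunet_forward(model, px[ri, ci, drop = FALSE])
  out <- out[seq_len(h), seq_len(w), drop = FALSE]
  if (is_bscan(img)) clip_bscan(out, img$value_range) else out
}

#' Train and evaluate all ablation variants
#'
#' Trains the full model and its ablated variants under identical seeds and
#' data and evaluates each on held-out phantoms with both reference kinds
#' (pseudo-clean and, since phantoms carry their clean image, true-clean).
#'
#' @param phantom_cfg A [phantom_config] (ignored when `data` is given).
#' @param net_cfg,train_cfg,weights,pattern As in [train].
#' @param n_images Dataset size, split 8:1:1.
#' @param variants Character vector of ablation names, in output order.
#' @param data Optional pre-generated list of `phantom_truth` (overrides
#'   `phantom_cfg`/`n_images`).
#' @param fits Optional named list of already-trained `fenoct_fit`s to
#'   reuse for matching variants (they must come from the same seed/data
#'   to keep the comparison fair).
#' @return Data frame with one row per variant x reference kind and
#'   columns `variant`, `reference_kind`, `snr_db`, `psnr_db`, `ssim`;
#'   the fitted models are attached as attribute `fits`.
#' @export
run_ablation_suite <- function(phantom_cfg = phantom_config(),
                               net_cfg = net_config(),
                               train_cfg = desk_preset(),
                               weights = loss_weights(),
                               n_images = 80L,
                               variants = c("full", "no_wspm", "no_ferfb",
                                            "n2n_baseline"),
                               pattern = "A", data = NULL, fits = list()) {
  truths <- data %||% make_dataset(phantom_cfg, n_images)
  sp <- split_indices(length(truths))
  noisy <- lapply(truths, function(tr) tr$noisy)
  rows <- list()
  for (v in variants) {
    tc <- train_cfg
    tc$ablation <- v
    fit <- fits[[v]] %||% train(noisy[sp$train], noisy[sp$val],
                                net_cfg, tc, weights, pattern)
    fits[[v]] <- fit
    model_fun <- function(b) denoise(fit, b)
    rt <- evaluate_true_clean(model_fun, truths[sp$test])
    rp <- evaluate_pseudo_clean(model_fun, noisy[sp$test], pattern)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, reference_kind = "true_clean",
      snr_db = rt$snr_db, psnr_db = rt$psnr_db, ssim = rt$ssim)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = v, reference_kind = "pseudo_clean",
      snr_db = rp$snr_db, psnr_db = rp$psnr_db, ssim = rp$ssim)
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Save / load a trained model
#'
#' The binary parameter file is accompanied by a JSON manifest holding the
#' configuration, seed and an MD5 content hash of the parameter file.
#'
#' @param fit A `fenoct_fit` (or bare `feunet`).
#' @param path Destination `.rds` path.
#' @return `save_model` returns `path`; `load_model` returns a
#'   `fenoct_fit`.
#' @export
save_model <- function(fit, path) {
  model <- if (inherits(fit, "fenoct_fit")) fit$model else fit
  manifest <- if (inherits(fit, "fenoct_fit")) fit$manifest else NULL
  saveRDS(list(cfg = model$cfg, seed = model$seed,
               values = lapply(model$params, function(p) p$value),
               manifest = manifest), path)
  side <- list(
    base_channels = model$cfg$base_channels,
    use_wspm = model$cfg$use_wspm, use_ferfb = model$cfg$use_ferfb,
    lambda_mix = model$cfg$wspm$lambda_mix,
    seed = model$seed, n_params = count_params(model),
    md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  blob <- readRDS(path)
  model <- build_feunet(blob$cfg, seed = blob$seed)
  for (nm in names(model$params)) model$params[[nm]]$value <- blob$values[[nm]]
  structure(list(model = model, manifest = blob$manifest),
            class = "fenoct_fit")
}
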