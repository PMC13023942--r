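# Shared fixtures, all generated in code.

# Small network for structural/unit tests (8 base channels, GN groups 4).
tiny_net_config <- function(...) {
  net_config(base_channels = 8L, gn_groups = 4L, ...)
}

# Small phantoms for fast tests.
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(size = c(64L, 64L), seed = seed, ...)
}

# Central-difference gradient of a scalar-valued forward at one coordinate.
numeric_grad <- function(param, i, forward, eps = 1e-6) {
  old <- param$value
  v <- old; v[i] <- v[i] + eps
  param$value <- v
  up <- forward()
  v <- old; v[i] <- v[i] - eps
  param$value <- v
  dn <- forward()
  param$value <- old
  (up - dn) / (2 * eps)
}

# The scaled-down study conditions used by the end-to-end and ablation
# acceptance checks: 88 phantoms at 64x64 (split 8:1:1 into 72/8/8, with
# the first 64 of the training block used for training and 16 held-out
# images for testing), default noise settings, desk-scale training
# (5 epochs x 64 steps = 320 Adam steps), one fixed seed.
acceptance_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truths <- make_dataset(phantom_config(size = c(64L, 64L), seed = 100L),
                             88L)
      cache <<- list(
        truths = truths,
        noisy = lapply(truths, function(tr) tr$noisy),
        train_idx = 1:64, val_idx = 65:72, test_idx = 73:88)
    }
    cache
  }
})

# Trained models are cached across acceptance blocks: the end-to-end gain
# check and the ablation-direction check share one set of runs under the
# identical desk-scale setup (320 steps, same seed and data per variant).
acceptance_fit <- local({
  cache <- list()
  function(variant = "full") {
    if (is.null(cache[[variant]])) {
      d <- acceptance_data()
      cache[[variant]] <<- train(d$noisy[d$train_idx], d$noisy[d$val_idx],
                                 net_config(),
                                 desk_preset(seed = 1L, ablation = variant))
    }
    cache[[variant]]
  }
})

true_clean_psnr <- function(fit, truths) {
  mean(vapply(truths,
              function(tr) psnr(denoise(fit, tr$noisy), tr$clean),
              numeric(1)))
}
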