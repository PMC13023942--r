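# Minimal reverse-mode tape for the training engine. Nodes are
# environments holding a value, an accumulated gradient, parent links and
# a backward closure returning one gradient per parent. Tensor values are
# dense arrays in (H, W, C, N) layout; losses are length-1 scalars.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0

ad_node <- function(value, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1
  e$id <- .ad_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$is_param <- FALSE
  class(e) <- "ad_node"
  e
}

ad_const <- function(value) ad_node(value)

ad_param <- function(value) {
  e <- ad_node(value)
  e$is_param <- TRUE
  e
}

# Reverse sweep from a scalar root. Topological order by DFS postorder;
# constants (no backfn, not params) stop propagation.
ad_backward <- function(root) {
  stopifnot(length(root$value) == 1L)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nd <- top$node
    key <- as.character(nd$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = nd, stage = 2L)
      for (p in nd$parents) {
        stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
      }
    } else {
      order[[length(order) + 1L]] <- nd
    }
  }
  root$grad <- 1
  for (nd in rev(order)) {
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    gs <- nd$backfn(nd$grad)
    for (i in seq_along(nd$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- nd$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- tensor ops -----------------------------------------------------------

# Same-size convolution, stride 1; pad follows the dilation so odd kernels
# preserve shape.
nn_conv <- function(x, w, b, dil = 1L) {
  xd <- dim(x$value); wd <- dim(w$value)
  pad <- as.integer(dil * (wd[1] - 1L) / 2L)
  val <- conv2d_fwd(x$value, xd, w$value, wd, b$value, pad, dil)
  ad_node(val, list(x, w, b), function(g) {
    bw <- conv2d_bwd(x$value, xd, w$value, wd, g, pad, dil)
    list(bw$gx, bw$gw, bw$gb)
  })
}

nn_lrelu <- function(x, slope = 0.1) {
  v <- x$value
  ad_node(lrelu_fwd(v, slope), list(x),
          function(g) list(lrelu_bwd(v, g, slope)))
}

nn_pool <- function(x) {
  xd <- dim(x$value)
  fw <- maxpool2_fwd(x$value, xd)
  ad_node(fw$out, list(x), function(g) list(maxpool2_bwd(g, fw$argmax, xd)))
}

nn_up2 <- function(x) {
  xd <- dim(x$value)
  ad_node(upsample2_fwd(x$value, xd), list(x),
          function(g) list(upsample2_bwd(g, xd)))
}

nn_cat <- function(a, b) {
  da <- dim(a$value); db <- dim(b$value)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a$value
  out[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

nn_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

nn_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

# Wavelet-guided spectral pooling: Haar split, learnable 1x1 mixing of the
# LL band, (1 - lambda) attenuation of the detail bands, inverse Haar.
# Both Haar maps are orthonormal, so their Jacobian transposes are their
# inverses.
nn_wspm <- function(x, wll, bll, lambda) {
  xd <- dim(x$value)
  s <- haar4_fwd(x$value, xd)
  lld <- dim(s$LL); wd <- dim(wll$value)
  llref <- conv2d_fwd(s$LL, lld, wll$value, wd, bll$value, 0L, 1L)
  att <- 1 - lambda
  val <- haar4_inv(llref, att * s$LH, att * s$HL, att * s$HH, lld)
  ad_node(val, list(x, wll, bll), function(g) {
    gs <- haar4_fwd(g, xd)
    bw <- conv2d_bwd(s$LL, lld, wll$value, wd, gs$LL, 0L, 1L)
    gx <- haar4_inv(bw$gx, att * gs$LH, att * gs$HL, att * gs$HH, lld)
    list(gx, bw$gw, bw$gb)
  })
}

# Group normalization: per (group, sample) moments, per-channel affine.
nn_gn <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$value)
  if (d[3] %% groups != 0L) stop("channel count not divisible by GN groups")
  fw <- gn_fwd(x$value, d, gamma$value, beta$value, groups, eps)
  ad_node(fw$out, list(x, gamma, beta), function(gr) {
    bw <- gn_bwd(fw$xhat, d, gamma$value, fw$inv_sd, gr, groups)
    list(bw$gx, bw$ggamma, bw$gbeta)
  })
}

# Select samples along the batch axis (the complementary sub-images are
# denoised in one batched forward pass and split afterwards; every layer
# operates per sample, so this is exactly equivalent to two passes).
nn_slice_n <- function(x, n_idx) {
  d <- dim(x$value)
  val <- x$value[, , , n_idx, drop = FALSE]
  ad_node(val, list(x), function(g) {
    dim(g) <- dim(val)
    gx <- array(0, d)
    gx[, , , n_idx] <- g
    list(gx)
  })
}

# Fixed-pattern subsampling of a full-resolution tensor (used on the
# denoised full image inside the regularizer).
nn_subsample <- function(x, rows, cols) {
  d <- dim(x$value)
  val <- x$value[rows, cols, , , drop = FALSE]
  ad_node(val, list(x), function(g) {
    dim(g) <- dim(val)
    gx <- array(0, d)
    gx[rows, cols, , ] <- g
    list(gx)
  })
}

# ---- scalar reductions ----------------------------------------------------

nn_mean_abs <- function(x) {
  n <- length(x$value)
  ad_node(mean(abs(x$value)), list(x), function(g) {
    gg <- g * sign(x$value) / n
    dim(gg) <- dim(x$value)
    list(gg)
  })
}

nn_mean_sq <- function(x) {
  n <- length(x$value)
  ad_node(mean(x$value^2), list(x), function(g) {
    gg <- g * 2 * x$value / n
    dim(gg) <- dim(x$value)
    list(gg)
  })
}

# total = sum(weights[i] * scalars[[i]])
nn_wsum <- function(scalars, weights) {
  val <- sum(weights * vapply(scalars, function(s) s$value, numeric(1)))
  ad_node(val, scalars, function(g) as.list(g * weights))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p$value) %||%
                                              length(p$value))),
       v = lapply(params, function(p) array(0, dim(p$value) %||%
                                              length(p$value))),
       t = 0L)
}

adam_step <- function(state, params, lr, betas = c(0.9, 0.999),
                      eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[i]] <- b1 * state$m[[i]] + (1 - b1) * g
    state$v[[i]] <- b2 * state$v[[i]] + (1 - b2) * g^2
    p$value <- p$value -
      lr * (state$m[[i]] / bc1) / (sqrt(state$v[[i]] / bc2) + eps)
  }
  state
}
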