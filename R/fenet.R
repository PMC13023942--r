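#' Spectral pooling configuration
#'
#' @param lambda_mix Detail-band suppression strength in `[0, 1]`;
#'   default 0.65.
#' @return A list of class `wspm_config`.
#' @export
wspm_config <- function(lambda_mix = 0.65) {
  if (lambda_mix < 0 || lambda_mix > 1) stop("lambda_mix must be in [0, 1]")
  structure(list(lambda_mix = lambda_mix), class = "wspm_config")
}

#' Receptive-field block configuration
#'
#' Parallel dilated-convolution branches; each branch reduces channels with
#' a 1x1 convolution, applies a 3x3 convolution at its dilation rate, and
#' refines the result in the wavelet domain. Branch outputs are
#' concatenated, fused by a 1x1 convolution and added back to the input.
#'
#' @param n_branches Number of branches.
#' @param dilation_rates Strictly increasing integer rates, one per branch.
#' @param branch_channel_fraction Fraction of the block's channels given to
#'   each branch (the channel count times this must be an integer).
#' @return A list of class `ferfb_config`.
#' @export
ferfb_config <- function(n_branches = 4L, dilation_rates = c(1L, 2L, 3L, 5L),
                         branch_channel_fraction = 0.25) {
  if (length(dilation_rates) != n_branches) {
    stop("need one dilation rate per branch")
  }
  if (any(diff(dilation_rates) <= 0)) {
    stop("dilation rates must be strictly increasing")
  }
  structure(list(n_branches = as.integer(n_branches),
                 dilation_rates = as.integer(dilation_rates),
                 branch_channel_fraction = branch_channel_fraction),
            class = "ferfb_config")
}

#' Frequency-enhanced UNet configuration
#'
#' A 4-level encoder/decoder with skip connections. Each encoder level is
#' an entry convolution, a receptive-field block and 2x2 max pooling; the
#' decoder mirrors it with bilinear upsampling + 3x3 convolution, skip
#' concatenation, 1x1 fusion and a receptive-field block. Channels start at
#' `base_channels` and double per level. `use_wspm`/`use_ferfb` are the
#' structural ablation switches (disabling the receptive-field block
#' replaces it with a plain two-layer 3x3 convolution block).
#'
#' @param base_channels First-level channel count (doubled per level).
#' @param depth Number of resolution levels; fixed at 4.
#' @param wspm A [wspm_config].
#' @param ferfb A [ferfb_config].
#' @param use_wspm,use_ferfb Ablation switches.
#' @param gn_groups Group-normalization groups (normalization is applied
#'   only outside the spectral paths, keeping the spectral pooling linear).
#' @param in_channels,out_channels Image channels (grayscale: 1).
#' @return A list of class `net_config`.
#' @export
net_config <- function(base_channels = 32L, depth = 4L,
                       wspm = wspm_config(), ferfb = ferfb_config(),
                       use_wspm = TRUE, use_ferfb = TRUE, gn_groups = 8L,
                       in_channels = 1L, out_channels = 1L) {
  if (depth != 4L) stop("the architecture is fixed at 4 levels")
  ch <- base_channels * 2^(seq_len(depth) - 1L)
  if (use_ferfb) {
    cb <- ch * ferfb$branch_channel_fraction
    if (any(cb != as.integer(cb)) || any(cb < 1)) {
      stop("channel count not divisible per branch_channel_fraction")
    }
  }
  if (any(ch %% gn_groups != 0L)) {
    stop("base_channels must be divisible by gn_groups")
  }
  structure(list(base_channels = as.integer(base_channels),
                 depth = 4L, wspm = wspm, ferfb = ferfb,
                 use_wspm = use_wspm, use_ferfb = use_ferfb,
                 gn_groups = as.integer(gn_groups),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "net_config")
}

# Fan-in-scaled (He) initial weights for a (kh, kw, cin, cout) kernel.
he_weights <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

add_conv_params <- function(params, name, kh, cin, cout,
                            init = c("he", "identity")) {
  init <- match.arg(init)
  w <- if (init == "identity") {
    # exact identity map: only possible for 1x1 with cin == cout
    array(diag(cout), c(1L, 1L, cin, cout))
  } else {
    he_weights(kh, kh, cin, cout)
  }
  params[[paste0(name, ".w")]] <- ad_param(w)
  params[[paste0(name, ".b")]] <- ad_param(numeric(cout))
  params
}

add_gn_params <- function(params, name, C) {
  params[[paste0(name, ".g")]] <- ad_param(rep(1, C))
  params[[paste0(name, ".be")]] <- ad_param(numeric(C))
  params
}

# Parameters of one receptive-field block (or its plain replacement).
add_block_params <- function(params, name, C, cfg) {
  if (!cfg$use_ferfb) {
    params <- add_conv_params(params, paste0(name, ".c1"), 3L, C, C)
    params <- add_conv_params(params, paste0(name, ".c2"), 3L, C, C)
    return(params)
  }
  cb <- as.integer(C * cfg$ferfb$branch_channel_fraction)
  for (i in seq_len(cfg$ferfb$n_branches)) {
    params <- add_conv_params(params, sprintf("%s.br%d.red", name, i),
                              1L, C, cb)
    params <- add_conv_params(params, sprintf("%s.br%d.dil", name, i),
                              3L, cb, cb)
    if (cfg$use_wspm) {
      params <- add_conv_params(params, sprintf("%s.br%d.ll", name, i),
                                1L, cb, cb, init = "identity")
    }
  }
  add_conv_params(params, paste0(name, ".fuse"), 1L,
                  cb * cfg$ferfb$n_branches, C)
}

#' Build a frequency-enhanced UNet
#'
#' Constructs all parameters (fan-in-scaled random initialization, spectral
#' LL refiners initialized to the identity) under the given seed. Two
#' constructions with the same configuration have identical parameter
#' counts; with the same seed they are bit-identical.
#'
#' @param cfg A [net_config].
#' @param seed Initialization seed (recorded in the model).
#' @return An object of class `feunet` with fields `cfg`, `params`
#'   (named list of trainable tensors) and `seed`.
#' @export
build_feunet <- function(cfg = net_config(), seed = 1L) {
  ch <- cfg$base_channels * 2^(0:3)
  params <- with_seed(seed, {
    p <- list()
    cin <- cfg$in_channels
    for (l in 1:4) {
      p <- add_conv_params(p, sprintf("enc%d.in", l), 3L, cin, ch[l])
      p <- add_gn_params(p, sprintf("enc%d.gn", l), ch[l])
      p <- add_block_params(p, sprintf("enc%d.rfb", l), ch[l], cfg)
      cin <- ch[l]
    }
    p <- add_conv_params(p, "bott.c", 3L, ch[4], ch[4])
    p <- add_gn_params(p, "bott.gn", ch[4])
    above <- ch[4]
    for (l in 4:1) {
      p <- add_conv_params(p, sprintf("dec%d.pre", l), 1L, above, ch[l])
      p <- add_conv_params(p, sprintf("dec%d.up", l), 3L, ch[l], ch[l])
      p <- add_gn_params(p, sprintf("dec%d.upgn", l), ch[l])
      p <- add_conv_params(p, sprintf("dec%d.fuse", l), 1L, 2L * ch[l], ch[l])
      p <- add_gn_params(p, sprintf("dec%d.fusegn", l), ch[l])
      p <- add_block_params(p, sprintf("dec%d.rfb", l), ch[l], cfg)
      above <- ch[l]
    }
    add_conv_params(p, "out", 1L, ch[1], cfg$out_channels)
  })
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "feunet")
}

#' @export
print.feunet <- function(x, ...) {
  cat(sprintf(
    "<feunet base %d, wspm %s (lambda %.2f), ferfb %s, %d parameters>\n",
    x$cfg$base_channels, x$cfg$use_wspm, x$cfg$wspm$lambda_mix,
    x$cfg$use_ferfb, count_params(x)))
  invisible(x)
}

#' Number of trainable scalars in a model
#' @param model A `feunet`.
#' @return Integer count.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, function(p) length(p$value), numeric(1)))
}

# Node-level forward passes -------------------------------------------------

conv_gn_act <- function(p, x, conv, gn, groups, dil = 1L) {
  h <- nn_conv(x, p[[paste0(conv, ".w")]], p[[paste0(conv, ".b")]], dil)
  h <- nn_gn(h, p[[paste0(gn, ".g")]], p[[paste0(gn, ".be")]], groups)
  nn_lrelu(h)
}

block_node <- function(p, name, x, cfg) {
  if (!cfg$use_ferfb) {
    h <- nn_lrelu(nn_conv(x, p[[paste0(name, ".c1.w")]],
                          p[[paste0(name, ".c1.b")]], 1L))
    h <- nn_lrelu(nn_conv(h, p[[paste0(name, ".c2.w")]],
                          p[[paste0(name, ".c2.b")]], 1L))
    return(h)
  }
  branches <- vector("list", cfg$ferfb$n_branches)
  for (i in seq_len(cfg$ferfb$n_branches)) {
    nb <- sprintf("%s.br%d", name, i)
    h <- nn_lrelu(nn_conv(x, p[[paste0(nb, ".red.w")]],
                          p[[paste0(nb, ".red.b")]], 1L))
    h <- nn_lrelu(nn_conv(h, p[[paste0(nb, ".dil.w")]],
                          p[[paste0(nb, ".dil.b")]],
                          cfg$ferfb$dilation_rates[i]))
    if (cfg$use_wspm) {
      h <- nn_wspm(h, p[[paste0(nb, ".ll.w")]], p[[paste0(nb, ".ll.b")]],
                   cfg$wspm$lambda_mix)
    }
    branches[[i]] <- h
  }
  cat <- Reduce(nn_cat, branches)
  fused <- nn_conv(cat, p[[paste0(name, ".fuse.w")]],
                   p[[paste0(name, ".fuse.b")]], 1L)
  nn_add(x, fused)
}

# Full forward pass on an input node holding an (H, W, 1, N) tensor.
feunet_node <- function(model, x) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(x$value)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop(sprintf(
      "input %dx%d not divisible by 16; pad or crop (denoise() pads for you)",
      d[1], d[2]))
  }
  g <- cfg$gn_groups
  skips <- vector("list", 4L)
  h <- x
  for (l in 1:4) {
    h <- conv_gn_act(p, h, sprintf("enc%d.in", l), sprintf("enc%d.gn", l), g)
    h <- block_node(p, sprintf("enc%d.rfb", l), h, cfg)
    skips[[l]] <- h
    h <- nn_pool(h)
  }
  h <- conv_gn_act(p, h, "bott.c", "bott.gn", g)
  for (l in 4:1) {
    h <- nn_conv(h, p[[sprintf("dec%d.pre.w", l)]],
                 p[[sprintf("dec%d.pre.b", l)]], 1L)
    h <- nn_up2(h)
    h <- conv_gn_act(p, h, sprintf("dec%d.up", l), sprintf("dec%d.upgn", l), g)
    h <- nn_cat(h, skips[[l]])
    h <- conv_gn_act(p, h, sprintf("dec%d.fuse", l),
                     sprintf("dec%d.fusegn", l), g)
    h <- block_node(p, sprintf("dec%d.rfb", l), h, cfg)
  }
  nn_conv(h, p[["out.w"]], p[["out.b"]], 1L)
}

# Coerce a matrix / bscan / (H,W) array into the (H, W, 1, N) tensor layout.
as_tensor <- function(x) {
  px <- as_pixels(x)
  if (is.matrix(px)) {
    array(px, c(nrow(px), ncol(px), 1L, 1L))
  } else {
    px
  }
}

#' Run the network on an image
#'
#' Thin numeric wrapper: no padding, no clipping — dimensions must be
#' divisible by 16. Use [denoise] for arbitrary sizes and range-clipped
#' output.
#'
#' @param model A `feunet`.
#' @param img A [bscan], matrix, or (H, W, 1, N) array.
#' @return A matrix (single image in) or array of the same shape.
#' @export
feunet_forward <- function(model, img) {
  xt <- as_tensor(img)
  out <- feunet_node(model, ad_const(xt))$value
  if (dim(xt)[4] == 1L && (is.matrix(as_pixels(img)) || is_bscan(img))) {
    out <- matrix(out, dim(xt)[1], dim(xt)[2])
    if (is_bscan(img)) out <- bscan(out, img$value_range, validate = FALSE)
  }
  out
}

#' Standalone receptive-field block (for inspection and ablation probes)
#'
#' @param channels Channel count the block operates on.
#' @param cfg A [net_config] carrying the block and spectral settings.
#' @param seed Initialization seed.
#' @return List with `params` (named trainable tensors) and
#'   `forward(x)` taking and returning an (H, W, C, N) array.
#' @export
fe_rfb_module <- function(channels, cfg = net_config(), seed = 1L) {
  params <- with_seed(seed, add_block_params(list(), "blk", channels, cfg))
  list(params = params,
       forward = function(x) {
         block_node(params, "blk", ad_const(x), cfg)$value
       })
}
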