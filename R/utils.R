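#' @useDynLib fenoct, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rgamma runif rnorm median mad fft sd runmed quantile
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic generators in the package go
# through this so that a seed fully determines their output.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Centered-spectrum index shift: moves DC from [1,1] to the array centre
# (row H/2+1, col W/2+1 for even dims), matching the package's convention
# that notch/peak coordinates are reported in centered frequency bins.
fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((floor(h / 2) + 1):h, seq_len(floor(h / 2))),
    c((floor(w / 2) + 1):w, seq_len(floor(w / 2))), drop = FALSE]
}

ifftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  x[c((ceiling(h / 2) + 1):h, seq_len(ceiling(h / 2))),
    c((ceiling(w / 2) + 1):w, seq_len(ceiling(w / 2))), drop = FALSE]
}

# Centered frequency bins for an even extent n: -n/2 .. n/2-1, DC at 0.
centered_bins <- function(n) seq_len(n) - (floor(n / 2) + 1L)

stopifnot_even <- function(h, w, what = "image") {
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop(sprintf(
      "%s dimensions must be even (got %dx%d); crop or pad by one pixel first",
      what, h, w
    ))
  }
}

# Separable Gaussian filter with reflect padding; sigma in pixels,
# truncated at `truncate` sigmas (scipy.ndimage convention).
gaussian_filter2 <- function(x, sigma, truncate = 4) {
  if (sigma <= 0) return(x)
  r <- as.integer(sigma * truncate + 0.5)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  sep_filter2(x, k)
}

# Apply a 1D kernel along rows then columns with reflect ('mirror without
# repeating the edge sample' is NOT used; scipy 'reflect' duplicates the
# edge) padding.
sep_filter2 <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  pad_reflect <- function(m, r) {
    n <- nrow(m)
    idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
    m[idx, , drop = FALSE]
  }
  conv_rows <- function(m) {
    p <- pad_reflect(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[j:(j + nrow(m) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
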