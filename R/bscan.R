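#' B-scan container
#'
#' A `bscan` is the package's universal currency: one grayscale OCT
#' cross-section stored as a real-valued matrix (rows = axial depth,
#' columns = lateral position) together with its declared intensity range.
#' The declared range, not the observed pixel min/max, is used as the
#' `data_range` of every metric so values are comparable across images.
#'
#' @param pixels Numeric matrix of intensities.
#' @param value_range Length-2 numeric `(min, max)` of representable values.
#' @param validate Check invariants (even dimensions >= 16 are required by
#'   the 2x2 subsampling cells and the Haar decomposition; pixel values must
#'   lie inside `value_range`).
#' @return An object of class `bscan` with fields `pixels` and `value_range`.
#' @export
bscan <- function(pixels, value_range = c(0, 1), validate = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix")
  }
  value_range <- as.numeric(value_range)
  if (length(value_range) != 2L || diff(value_range) <= 0) {
    stop("`value_range` must be (min, max) with max > min")
  }
  x <- structure(list(pixels = pixels, value_range = value_range),
                 class = "bscan")
  if (validate) validate_bscan(x)
  x
}

validate_bscan <- function(x) {
  h <- nrow(x$pixels); w <- ncol(x$pixels)
  if (h < 16L || w < 16L) stop("bscan must be at least 16x16")
  stopifnot_even(h, w, "bscan")
  if (!all(is.finite(x$pixels))) stop("bscan pixels must be finite")
  rng <- range(x$pixels)
  tol <- 1e-9 * diff(x$value_range)
  if (rng[1] < x$value_range[1] - tol || rng[2] > x$value_range[2] + tol) {
    stop("bscan pixels fall outside the declared value_range")
  }
  invisible(x)
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %dx%d, range [%g, %g], mean %.4g>\n",
              nrow(x$pixels), ncol(x$pixels),
              x$value_range[1], x$value_range[2], mean(x$pixels)))
  invisible(x)
}

#' @export
dim.bscan <- function(x) dim(x$pixels)

is_bscan <- function(x) inherits(x, "bscan")

as_pixels <- function(x) if (is_bscan(x)) x$pixels else x

# Replace pixels, keeping the declared range and clipping into it.
clip_bscan <- function(pixels, value_range) {
  bscan(pmin(pmax(pixels, value_range[1]), value_range[2]),
        value_range, validate = FALSE)
}

#' Read / write B-scans
#'
#' Single-channel images only. 16-bit TIFF and 8-bit PNG are supported;
#' pixel values are mapped linearly between the file's integer range and
#' `value_range`.
#'
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param value_range Intensity range the integer samples represent.
#' @return `read_bscan` returns a [bscan]; `write_bscan` returns `path`.
#' @export
read_bscan <- function(path, value_range = c(0, 1)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  # readers return [0,1]; rescale into the declared range
  px <- value_range[1] + img * diff(value_range)
  bscan(px, value_range)
}

#' @rdname read_bscan
#' @param x A [bscan] to write.
#' @export
write_bscan <- function(x, path) {
  stopifnot(is_bscan(x))
  u <- (x$pixels - x$value_range[1]) / diff(x$value_range)
  u <- pmin(pmax(u, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(u, path, bits.per.sample = 16L),
    png = png::writePNG(u, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}
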