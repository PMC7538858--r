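#' Single-channel immunofluorescence intensity image
#'
#' Minimal container pairing a 2-D non-negative intensity matrix with its
#' physical pixel size. All downstream area rules (the 200 um^2 component
#' and hole thresholds, the 10 um/px working grid) are stated in microns,
#' so the pixel size travels with the pixels.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Physical size of one pixel edge in micrometres
#'   (e.g. 0.5 for the higher-resolution cohort, 0.975 for the other).
#' @return An object of class `if_image`.
#' @export
#' @examples
#' img <- if_image(matrix(runif(64), 8, 8), pixel_size_um = 0.5)
#' dim(img$pixels)
if_image <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix")
  }
  if (any(!is.finite(pixels)) || any(pixels < 0)) {
    abort("`pixels` must be finite and non-negative")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um),
            class = "if_image")
}

#' @export
print.if_image <- function(x, ...) {
  cat(sprintf("<if_image> %d x %d px at %g um/px (%.0f x %.0f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um))
  invisible(x)
}

#' Read / write a single-channel grayscale TIFF
#'
#' Intensities are stored as 32-bit float TIFF scaled to `[0, 1]` (divided
#' by the image maximum). The percentile binarization used downstream is
#' invariant to that positive rescaling, so no information relevant to the
#' pipeline is lost.
#'
#' @param path File path.
#' @param pixel_size_um Pixel size in micrometres (TIFF files carry no
#'   reliable physical calibration; it is supplied by the cohort manifest).
#' @return `read_if_image()` returns an [if_image()]; `write_if_image()`
#'   returns `path` invisibly.
#' @export
read_if_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) abort(sprintf("no such image file: %s", path))
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1L]  # tolerate grayscale-as-RGB
  if_image(px, pixel_size_um)
}

#' @rdname read_if_image
#' @param img An [if_image()].
#' @export
write_if_image <- function(img, path) {
  stopifnot(inherits(img, "if_image"))
  px <- img$pixels
  mx <- max(px)
  if (mx > 0) px <- px / mx
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}
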