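#' Binarize one IF channel at a per-image intensity percentile
#'
#' The threshold is the nearest-rank `percentile_q`-th percentile of all
#' pixel intensities of this image (so with the default `q = 90` the
#' brightest ~10% of pixels are positive); pixels strictly above the
#' threshold become 1. The threshold adapts per image -- there is no global
#' intensity scale across patients, which also makes the operation
#' invariant to positive rescaling of the intensities.
#'
#' @param img An [if_image()].
#' @param percentile_q Percentile in (0, 100); default 90.
#' @return A binary integer matrix of the same shape.
#' @export
#' @examples
#' img <- if_image(matrix(1:100, 10, 10), 0.5)
#' sum(binarize_channel(img, 90))  # 10 positive pixels
binarize_channel <- function(img, percentile_q = 90) {
  stopifnot(inherits(img, "if_image"))
  assert_scalar_number(percentile_q, "percentile_q", lower = 1e-9,
                       upper = 100 - 1e-9)
  px <- img$pixels
  if (length(px) == 0L) abort("empty image")
  # nearest-rank percentile (quantile type 1) via partial sort
  k <- max(1L, ceiling(percentile_q / 100 * length(px)))
  thr <- sort(as.vector(px), partial = k)[k]
  if (min(px) == max(px)) {
    warn("constant image: binarization yields an all-zero mask")
  }
  as_binary_int(matrix(as.integer(px > thr), nrow(px), ncol(px)))
}

component_areas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

#' Remove small connected components from a binary mask
#'
#' Deletes every 8-connected foreground component whose physical area
#' (pixel count times `pixel_size_um^2`) is strictly smaller than
#' `min_area_um2`; such specks are attributed to noise in the IF signal.
#' Idempotent.
#'
#' @param mask Binary matrix.
#' @param min_area_um2 Area threshold in square micrometres (default 200).
#' @param pixel_size_um Physical pixel size of `mask`.
#' @return The cleaned binary matrix.
#' @export
remove_small_components <- function(mask, min_area_um2 = 200, pixel_size_um) {
  assert_binary_matrix(mask)
  assert_scalar_number(min_area_um2, "min_area_um2", lower = 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  labels <- label_components_cpp(as_binary_int(mask), 8L)
  areas <- component_areas(labels) * pixel_size_um^2
  if (any(areas < min_area_um2)) {
    drop <- c(FALSE, areas < min_area_um2)  # index 1 = background label 0
    mask[drop[labels + 1L]] <- 0L
  }
  as_binary_int(mask)
}

#' Fill small holes in a binary mask
#'
#' Sets to foreground every 4-connected background component that does not
#' touch the image border and whose physical area is strictly smaller than
#' `max_area_um2`. Used on the cancer-cell (PanCK) mask only: PanCK is a
#' surface marker, so cell interiors image dark and would otherwise punch
#' holes in the cancer islands. Idempotent.
#'
#' @param mask Binary matrix.
#' @param max_area_um2 Hole area threshold in square micrometres.
#' @param pixel_size_um Physical pixel size of `mask`.
#' @return The filled binary matrix.
#' @export
fill_small_holes <- function(mask, max_area_um2 = 200, pixel_size_um) {
  assert_binary_matrix(mask)
  assert_scalar_number(max_area_um2, "max_area_um2", lower = 0)
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  bg <- as_binary_int(1L - mask)
  labels <- label_components_cpp(bg, 4L)
  if (max(labels) == 0L) return(as_binary_int(mask))
  border <- unique(c(labels[1L, ], labels[nrow(labels), ],
                     labels[, 1L], labels[, ncol(labels)]))
  areas <- component_areas(labels) * pixel_size_um^2
  fill_lab <- setdiff(which(areas < max_area_um2), border)
  if (length(fill_lab)) {
    fill <- logical(max(labels) + 1L)
    fill[fill_lab + 1L] <- TRUE
    mask[fill[labels + 1L]] <- 1L
  }
  as_binary_int(mask)
}

#' Co-registered pair of cleaned binary masks
#'
#' @param panck,cd8 Binary matrices of identical shape.
#' @param pixel_size_um Physical pixel size shared by both masks.
#' @return An object of class `mask_pair`.
#' @export
mask_pair <- function(panck, cd8, pixel_size_um) {
  assert_binary_matrix(panck, "panck")
  assert_binary_matrix(cd8, "cd8")
  if (!identical(dim(panck), dim(cd8))) {
    abort("panck and cd8 masks must have identical shape")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  structure(list(panck = as_binary_int(panck), cd8 = as_binary_int(cd8),
                 pixel_size_um = pixel_size_um), class = "mask_pair")
}

#' @export
print.mask_pair <- function(x, ...) {
  cat(sprintf(
    "<mask_pair> %d x %d px at %g um/px; PanCK+ %d px, CD8+ %d px\n",
    nrow(x$panck), ncol(x$panck), x$pixel_size_um, sum(x$panck), sum(x$cd8)))
  invisible(x)
}

#' Build the cleaned mask pair from the two raw channels
#'
#' Runs the standard per-channel pipeline: percentile binarization, then
#' removal of connected areas under `min_area_um2` on both channels, then
#' filling of holes under `fill_area_um2` on the PanCK channel only.
#'
#' @param panck_img,cd8_img [if_image()] objects with equal shape and
#'   pixel size.
#' @param percentile_q Binarization percentile (default 90).
#' @param min_area_um2 Component-removal threshold (default 200).
#' @param fill_area_um2 Hole-filling threshold for PanCK (default 200).
#' @return A [mask_pair()].
#' @export
make_mask_pair <- function(panck_img, cd8_img, percentile_q = 90,
                           min_area_um2 = 200, fill_area_um2 = 200) {
  stopifnot(inherits(panck_img, "if_image"), inherits(cd8_img, "if_image"))
  if (!identical(dim(panck_img$pixels), dim(cd8_img$pixels))) {
    abort("channel images must have identical shape")
  }
  if (panck_img$pixel_size_um != cd8_img$pixel_size_um) {
    abort("channel images must share one pixel size")
  }
  psz <- panck_img$pixel_size_um
  panck <- binarize_channel(panck_img, percentile_q)
  panck <- remove_small_components(panck, min_area_um2, psz)
  panck <- fill_small_holes(panck, fill_area_um2, psz)
  cd8 <- binarize_channel(cd8_img, percentile_q)
  cd8 <- remove_small_components(cd8, min_area_um2, psz)
  mask_pair(panck, cd8, psz)
}
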