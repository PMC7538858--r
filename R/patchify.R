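block_means <- function(m, k) {
  nr2 <- nrow(m) %/% k
  nc2 <- ncol(m) %/% k
  m <- m[seq_len(nr2 * k), seq_len(nc2 * k), drop = FALSE]
  a <- array(as.numeric(m), c(k, nr2, k, nc2))
  b <- colMeans(a, dims = 1)          # (nr2, k, nc2)
  colMeans(aperm(b, c(2, 1, 3)), dims = 1)
}

#' Rescale a mask pair to the common working grid
#'
#' Downsamples both masks by integer block reduction to `target_um`
#' micrometres per pixel (default 10, the patch-classification grid).
#' The PanCK channel uses a majority rule (output pixel positive iff the
#' block mean is at least 0.5); the CD8 channel uses a presence rule
#' (positive iff the block contains any positive pixel), because a single
#' T-cell blob is sub-pixel at 10 um/px and would be erased by a majority
#' vote. Input is cropped to whole blocks.
#'
#' @param mp A [mask_pair()].
#' @param target_um Target pixel size; must be at least the native pixel
#'   size, and the ratio must be integral within `ratio_tol`.
#' @param ratio_tol Relative tolerance on the reduction factor. The
#'   default 3% admits a 0.975 um native pixel with a factor of 10
#'   (9.75 um treated as the 10 um grid); a genuinely non-integer ratio
#'   must be resampled upstream.
#' @return A `mask_pair` at `target_um` um/px.
#' @export
rescale_mask_pair <- function(mp, target_um = 10, ratio_tol = 0.03) {
  stopifnot(inherits(mp, "mask_pair"))
  assert_scalar_number(target_um, "target_um", lower = 1e-6)
  ratio <- target_um / mp$pixel_size_um
  if (ratio < 1 - 1e-9) {
    abort("upscaling requested: target_um is finer than the native pixel size")
  }
  k <- round(ratio)
  if (abs(ratio - k) / ratio > ratio_tol) {
    abort(paste("pixel-size ratio", signif(ratio, 4),
                "is not integer within the tolerance; resample the input first"))
  }
  if (k == 1) {
    return(mask_pair(mp$panck, mp$cd8, target_um))
  }
  if (nrow(mp$panck) < k || ncol(mp$panck) < k) {
    abort("mask smaller than one block at the target resolution")
  }
  pk <- block_means(mp$panck, k)
  cd <- block_means(mp$cd8, k)
  mask_pair(as_binary_int(matrix(as.integer(pk >= 0.5), nrow(pk))),
            as_binary_int(matrix(as.integer(cd > 0), nrow(cd))),
            target_um)
}

#' Tile a rescaled mask pair into adjacent square patches
#'
#' Non-overlapping `size_px` x `size_px` tiles taken on a regular grid
#' from the top-left corner; partial tiles at the right/bottom edges are
#' discarded. Tile indices are 0-based.
#'
#' @param smp A [mask_pair()] (normally at 10 um/px).
#' @param size_px Patch edge length in pixels (default 64).
#' @param patient_id Identifier recorded on every patch.
#' @return A tibble with one row per tile: `patient_id`, `row`, `col`,
#'   `n_panck`, `n_cd8` and list-columns `panck`, `cd8` holding the binary
#'   patch matrices.
#' @export
tile_patches <- function(smp, size_px = 64L, patient_id = "patient") {
  stopifnot(inherits(smp, "mask_pair"))
  size_px <- as.integer(size_px)
  nr <- nrow(smp$panck) %/% size_px
  nc <- ncol(smp$panck) %/% size_px
  if (nr == 0L || nc == 0L) return(empty_patch_tbl())
  grid <- expand.grid(row = 0:(nr - 1L), col = 0:(nc - 1L))
  grid <- grid[order(grid$row, grid$col), ]
  out <- purrr::pmap(grid, function(row, col) {
    ri <- row * size_px + seq_len(size_px)
    ci <- col * size_px + seq_len(size_px)
    pk <- smp$panck[ri, ci, drop = FALSE]
    cd <- smp$cd8[ri, ci, drop = FALSE]
    tibble::tibble(row = row, col = col, n_panck = sum(pk), n_cd8 = sum(cd),
                   panck = list(pk), cd8 = list(cd))
  })
  dplyr::bind_rows(out) |>
    dplyr::mutate(patient_id = patient_id, .before = 1L)
}

empty_patch_tbl <- function() {
  tibble::tibble(patient_id = character(), row = integer(), col = integer(),
                 n_panck = integer(), n_cd8 = integer(), panck = list(),
                 cd8 = list())
}

#' Filter patches by cancer-cell content and T-cell presence
#'
#' Keeps a patch iff its PanCK-positive pixel count is at least
#' `min_panck_frac` of the patch (at the default quarter rule on 64 x 64
#' patches: at least 1024 of 4096 pixels) and it contains at least
#' `min_cd8` CD8-positive pixels. Patches failing the first rule carry too
#' little tumor to judge infiltration; patches with no T cells carry no
#' immune signal. Order is preserved and surviving patches are untouched.
#'
#' @param patches Patch tibble from [tile_patches()].
#' @param min_panck_frac Minimum PanCK-positive fraction (default 0.25).
#' @param min_cd8 Minimum CD8-positive pixel count (default 1).
#' @return The filtered patch tibble.
#' @export
filter_patches <- function(patches, min_panck_frac = 0.25, min_cd8 = 1L) {
  assert_scalar_number(min_panck_frac, "min_panck_frac", lower = 0, upper = 1)
  assert_scalar_number(min_cd8, "min_cd8", lower = 0)
  if (nrow(patches) == 0L) return(patches)
  size2 <- length(patches$panck[[1L]])
  need_panck <- ceiling(min_panck_frac * size2)
  dplyr::filter(patches, .data$n_panck >= need_panck, .data$n_cd8 >= min_cd8)
}
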