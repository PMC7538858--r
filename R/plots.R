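#' Tidiers for tilstrat result objects
#'
#' [tidy()] returns the element-wise table of a result (per-epoch training
#' trace, threshold-scan candidates, per-realization intervals); [glance()]
#' returns a one-row summary.
#'
#' @param x A `patch_cnn`, `threshold_scan`, `rc_selection` or `til_run`.
#' @param ... Unused.
#' @name tilstrat-tidiers
NULL

#' @export
autoplot.patch_cnn <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = "Patch-classifier training trace",
                  x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutoff, y = .data$accuracy)) +
    ggplot2::annotate("rect", xmin = object$lo, xmax = object$hi,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = "Patient-stratification accuracy vs cut-off",
                  x = expression(R[c]), y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rc_selection <- function(object, ...) {
  df <- object$realizations
  ggplot2::ggplot(df, ggplot2::aes(y = factor(.data$realization))) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = factor(.data$realization),
                                       linewidth = .data$used)) +
    ggplot2::scale_linewidth_manual(values = c(`TRUE` = 2, `FALSE` = 0.5)) +
    ggplot2::geom_vline(xintercept = object$rc_final, linetype = 2,
                        colour = "red") +
    ggplot2::labs(title = "Optimal cut-off intervals per realization",
                  x = expression(R[c]), y = "realization") +
    ggplot2::theme_minimal()
}

mask_overlay_df <- function(panck, cd8) {
  lev <- matrix("stroma", nrow(panck), ncol(panck))
  lev[panck == 1L] <- "PanCK"
  lev[cd8 == 1L] <- "CD8"   # CD8 drawn on top, as in the red/white rendering
  tibble::tibble(row = rep(seq_len(nrow(panck)), times = ncol(panck)),
                 col = rep(seq_len(ncol(panck)), each = nrow(panck)),
                 what = factor(as.vector(lev),
                               levels = c("stroma", "PanCK", "CD8")))
}

#' Plot a mask pair in the standard rendering
#'
#' Cancer-cell (PanCK) pixels in white, CD8 pixels in red, stroma in
#' black.
#'
#' @param mp A [mask_pair()].
#' @return A ggplot object.
#' @export
plot_mask_pair <- function(mp) {
  stopifnot(inherits(mp, "mask_pair"))
  df <- mask_overlay_df(mp$panck, mp$cd8)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$what)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(stroma = "black", PanCK = "white",
                                          CD8 = "red"), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = NULL, x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Write surviving patches as two-channel PNG images
#'
#' Renders each patch in the standard coloring (PanCK white, CD8 red on
#' black) to `<patient>_r<row>_c<col>.png` files, alongside an index TSV
#' (`patient_id`, `row`, `col`, `n_panck`, `n_cd8`, `file`).
#'
#' @param patches Patch tibble.
#' @param dir Output directory (created if needed).
#' @return The index path, invisibly.
#' @export
write_patches_png <- function(patches, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(nrow(patches))
  for (i in seq_len(nrow(patches))) {
    pk <- patches$panck[[i]]
    cd <- patches$cd8[[i]]
    rgb <- array(0, c(nrow(pk), ncol(pk), 3L))
    rgb[, , 1] <- pmax(pk, cd)              # red channel: PanCK or CD8
    rgb[, , 2] <- rgb[, , 3] <- pk * (1 - cd)  # white where PanCK only
    files[i] <- file.path(dir, sprintf("%s_r%d_c%d.png",
                                       patches$patient_id[i],
                                       patches$row[i], patches$col[i]))
    png::writePNG(rgb, files[i])
  }
  idx <- dplyr::mutate(dplyr::select(patches, -"panck", -"cd8"), file = files)
  index_path <- file.path(dir, "patch_index.tsv")
  utils::write.table(idx, index_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(index_path)
}

#' Plot a gallery of patches
#'
#' @param patches Patch tibble.
#' @param n Maximum number of patches to draw.
#' @return A ggplot object faceted by patch.
#' @export
plot_patches <- function(patches, n = 16L) {
  patches <- head(patches, n)
  if (nrow(patches) == 0L) abort("no patches to plot")
  dfs <- purrr::pmap(list(patches$panck, patches$cd8, seq_len(nrow(patches)),
                          patches$patient_id),
                     function(pk, cd, i, pid) {
    df <- mask_overlay_df(pk, cd)
    df$panel <- sprintf("%s (%d)", pid, i)
    df
  })
  df <- dplyr::bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$what)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(stroma = "black", PanCK = "white",
                                          CD8 = "red"), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::labs(fill = NULL) +
    ggplot2::theme_void()
}
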