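#' CD8 density inside cancer-cell islands
#'
#' The number of CD8-positive pixels lying inside the (hole-filled) PanCK
#' mask divided by the number of PanCK-positive pixels — the classical
#' infiltration-density statistic used as a manual baseline against the
#' patch classifier. Computed at the mask pair's native resolution.
#'
#' @param mp A [mask_pair()] (the standard pipeline fills PanCK holes
#'   before this point, so sub-200 um^2 intra-islet gaps count as island
#'   interior).
#' @return A single non-negative number.
#' @export
cd8_density_in_islands <- function(mp) {
  stopifnot(inherits(mp, "mask_pair"))
  n_panck <- sum(mp$panck)
  if (n_panck == 0L) {
    abort("PanCK mask is empty: island CD8 density is undefined")
  }
  sum(mp$cd8 == 1L & mp$panck == 1L) / n_panck
}

#' Absolute positive areas of the two channels
#'
#' @param mp A [mask_pair()].
#' @return A one-row tibble with `cd8_area_um2` and `panck_area_um2`
#'   (pixel counts times the squared pixel size).
#' @export
absolute_areas <- function(mp) {
  stopifnot(inherits(mp, "mask_pair"))
  a <- mp$pixel_size_um^2
  tibble::tibble(cd8_area_um2 = sum(mp$cd8) * a,
                 panck_area_um2 = sum(mp$panck) * a)
}

#' Per-patient baseline metric row
#'
#' @param mp A [mask_pair()].
#' @param patient_id Identifier for the row.
#' @return One-row tibble: `patient_id`, `cd8_density_in_islands`,
#'   `cd8_area_um2`, `panck_area_um2`.
#' @export
baseline_metrics <- function(mp, patient_id = "patient") {
  dplyr::bind_cols(tibble::tibble(patient_id = patient_id,
                                  cd8_density_in_islands =
                                    cd8_density_in_islands(mp)),
                   absolute_areas(mp))
}

#' Best manual cut-off for a per-patient scalar metric
#'
#' Exhaustively scans all cut points (midpoints of consecutive distinct
#' values plus the extreme segments) of the rule "predict poor iff the
#' value is below the cut-off" (`direction = "low_is_poor"`; `"high_is_poor"`
#' flips the inequality) and returns the accuracy-maximizing cut-off,
#' mirroring the manually placed dashed separation line of the density
#' baselines.
#'
#' @param values Numeric metric per patient.
#' @param truths Character outcome per patient ("good"/"poor"), aligned
#'   with `values`.
#' @param direction Which side of the cut-off is called poor.
#' @return A list: `cutoff` (midpoint of the optimal interval),
#'   `max_accuracy`, `lo`, `hi` and the candidate table.
#' @export
best_cutoff_accuracy <- function(values, truths,
                                 direction = c("low_is_poor", "high_is_poor")) {
  direction <- match.arg(direction)
  res <- scan_threshold_(values, truths == "poor", direction)
  list(cutoff = (res$lo + res$hi) / 2, max_accuracy = res$max_accuracy,
       lo = res$lo, hi = res$hi, candidates = res$candidates)
}
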