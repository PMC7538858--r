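#' Generate a synthetic cohort and reduce it straight to patches
#'
#' Runs each planned patient through generation, mask cleaning, rescaling
#' and patch filtering immediately, keeping only the patch tibble and
#' per-patient summaries (truth, patch counts, baseline metrics). Patients
#' are identical to what [generate_cohort()] with the same arguments would
#' produce, but full-resolution images are never all in memory at once,
#' which is what makes cohort-scale experiments cheap.
#'
#' @inheritParams generate_cohort
#' @param config A [pipeline_config()] controlling preprocessing and
#'   patch filtering.
#' @return A list: `patches` (filtered patch tibble with `outcome`),
#'   `patients` (tibble with `patient_id`, `outcome`, `truth_p_in`,
#'   `n_tiles`, `n_patches`, `cd8_density_in_islands`, `cd8_area_um2`,
#'   `panck_area_um2`).
#' @export
synthetic_cohort_patches <- function(n_good = 15L, n_poor = 9L,
                                     good_p_in_range = c(0.6, 0.9),
                                     poor_p_in_range = c(0.0, 0.2),
                                     base = synthetic_study_params(),
                                     seed = 1L, id_prefix = "S",
                                     config = pipeline_config()) {
  plan <- cohort_plan_(n_good, n_poor, good_p_in_range, poor_p_in_range,
                       seed, id_prefix)
  patches <- vector("list", nrow(plan))
  rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    pars <- base
    pars$p_in <- plan$truth_p_in[i]
    pars$seed <- plan$seed[i]
    pat <- generate_patient(pars, patient_id = plan$patient_id[i],
                            outcome = plan$outcome[i])
    red <- reduce_patient_(pat, config)
    red$patches$outcome <- plan$outcome[i]
    patches[[i]] <- red$patches
    rows[[i]] <- dplyr::bind_cols(plan[i, ], red$summary)
  }
  list(patches = dplyr::bind_rows(patches),
       patients = dplyr::bind_rows(rows))
}

# One patient through the mask/patch pipeline; images are dropped on exit.
reduce_patient_ <- function(pat, config = pipeline_config()) {
  mp <- make_mask_pair(pat$panck, pat$cd8, config$percentile_q,
                       config$min_area_um2, config$fill_area_um2)
  tiles <- tile_patches(rescale_mask_pair(mp, config$target_um),
                        config$patch_size_px, pat$patient_id)
  kept <- filter_patches(tiles, config$min_panck_frac, config$min_cd8)
  dens <- if (sum(mp$panck) > 0) cd8_density_in_islands(mp) else NA_real_
  list(patches = kept,
       summary = dplyr::bind_cols(
         tibble::tibble(n_tiles = nrow(tiles), n_patches = nrow(kept),
                        cd8_density_in_islands = dens),
         absolute_areas(mp)))
}
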