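# Shared fixtures, all built in code at test time.

# Small, fast synthetic-patient parameters for unit tests: a 1920 um field
# with the same physical rules (2.5 um/px, ~8-9% island coverage) as the
# full study conditions.
tiny_params <- function(...) {
  do.call(synthetic_study_params,
          utils::modifyList(list(canvas_size_px = c(768L, 768L),
                                 n_islands = 5L,
                                 island_radius_um = c(100, 180),
                                 n_tcells = 120L),
                            list(...)))
}

# Mid-sized parameters for end-to-end pipeline tests: islands large
# relative to the 640 um patch, so each patient yields a handful of
# surviving patches (tiny_params islands are sub-patch-sized and rarely
# pass the quarter rule).
patchy_params <- function(...) {
  do.call(synthetic_study_params,
          utils::modifyList(list(canvas_size_px = c(1280L, 1280L),
                                 n_islands = 3L,
                                 island_radius_um = c(250, 400),
                                 n_tcells = 250L),
                            list(...)))
}

# Fully separable toy patches: a fixed PanCK half-plane; CD8 pixels inside
# it for "good" patches, outside it for "poor" ones.
toy_patch_tbl <- function(n_per_class, seed = 1) {
  withr::with_seed(seed, {
    one <- function(outcome, i) {
      pk <- matrix(0L, 64, 64)
      pk[, 1:32] <- 1L
      cd <- matrix(0L, 64, 64)
      k <- sample(3:10, 1)
      cols <- if (outcome == "good") 1:32 else 33:64
      cd[cbind(sample(64, k, TRUE), sample(cols, k, TRUE))] <- 1L
      tibble::tibble(patient_id = sprintf("%s%02d", outcome, i), row = 0L,
                     col = 0L, n_panck = sum(pk), n_cd8 = sum(cd),
                     panck = list(pk), cd8 = list(cd), outcome = outcome)
    }
    dplyr::bind_rows(purrr::map(seq_len(n_per_class), function(i) {
      dplyr::bind_rows(one("good", i), one("poor", i))
    }))
  })
}

# A patch tibble row from explicit matrices.
patch_row <- function(pk, cd, patient_id = "P", row = 0L, col = 0L) {
  tibble::tibble(patient_id = patient_id, row = row, col = col,
                 n_panck = sum(pk), n_cd8 = sum(cd),
                 panck = list(pk), cd8 = list(cd))
}

# A model whose output probability is exactly 0.5 for any input (all-zero
# weights), to pin down boundary behavior of the labeling rule.
constant_half_model <- function() {
  m <- train_patch_classifier(toy_patch_tbl(2, seed = 99),
                              train_config(epochs = 1, seed = 1))
  m$weights[] <- 0
  m
}
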