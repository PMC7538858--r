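#' Training configuration for desk-scale synthetic studies
#'
#' The reference schedule (see [train_config()]) is tuned for cohorts with
#' thousands of patches and ~50k RMSProp updates. The synthetic desk-scale
#' cohorts produce a few hundred patches and a few hundred updates, so the
#' study configuration uses a proportionally larger learning rate (0.02),
#' a lighter weight decay, 15 epochs with no decay step inside the run,
#' and a larger RMSProp stabilizer (0.01) that damps the first updates
#' while the squared-gradient accumulator is still near zero — without it
#' a short run can be thrown into a region it has no time to leave.
#' Everything else (mini-batch 20, 80/20 split, 3 extra minority copies,
#' 0.5 patch cutoff, small_cnn) is unchanged.
#'
#' @param seed Training seed.
#' @param ... Further overrides forwarded to [train_config()].
#' @return A [train_config()].
#' @export
study_train_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(learning_rate = 0.02, weight_decay = 1e-3, epochs = 15L,
         factor_epoch = 15L, rmsprop_eps = 0.01, seed = seed),
    list(...))
  do.call(train_config, args)
}

#' Run the full synthetic stratification study
#'
#' The package's end-to-end validation experiment: generate a labeled
#' training cohort (default 15 good / 9 poor patients) whose outcome is
#' driven by T-cell infiltration, run the holdout-split + training
#' realizations, scan and select the patient-level cut-off Rc, then
#' classify an independently generated test cohort and evaluate the
#' confusion summary. All randomness derives from `seed`.
#'
#' @param seed Master seed for the study.
#' @param n_good,n_poor Training cohort composition.
#' @param n_test_good,n_test_poor Test cohort composition.
#' @param good_p_in_range,poor_p_in_range Infiltration ranges per group.
#' @param base Generator parameters ([synthetic_study_params()]).
#' @param realizations Number of split+training realizations.
#' @param train_cfg Training configuration template; its seed is replaced
#'   per realization.
#' @return A list of class `til_study`: `rc_selection`, `scans`, `model`
#'   (the classifier of the first realization whose holdout validation
#'   attained the best separation; `model_realization` records which),
#'   `confusion` (test cohort), `test_scores`,
#'   `train_patients`, `test_patients`, `seed`. `glance()` gives the
#'   headline numbers.
#' @export
run_synthetic_study <- function(seed = 1L, n_good = 15L, n_poor = 9L,
                                n_test_good = 5L, n_test_poor = 5L,
                                good_p_in_range = c(0.6, 0.9),
                                poor_p_in_range = c(0.0, 0.2),
                                base = synthetic_study_params(),
                                realizations = 5L,
                                train_cfg = study_train_config()) {
  seeds <- derive_child_seeds(seed, 3L)
  real_seeds <- derive_child_seeds(seeds[3L], realizations)
  tr <- synthetic_cohort_patches(n_good, n_poor, good_p_in_range,
                                 poor_p_in_range, base, seed = seeds[1L])
  truths <- tr$patients[, c("patient_id", "outcome")]

  scans <- vector("list", realizations)
  models <- vector("list", realizations)
  for (r in seq_len(realizations)) {
    sp <- split_train_holdout(tr$patches, train_cfg$train_frac, real_seeds[r])
    bal <- balance_by_replication(sp$train, train_cfg$extra_copies_minority,
                                  real_seeds[r])
    cfg_r <- train_cfg
    cfg_r$seed <- real_seeds[r]
    models[[r]] <- train_patch_classifier(bal, cfg_r)
    scans[[r]] <- scan_rc(
      score_patients(predict_patches(models[[r]], sp$holdout)), truths)
  }
  sel <- select_rc(scans)
  # deploy the classifier from the first realization whose holdout
  # validation attained the best separation: the holdout scan is the
  # model-vetting step, and a realization that failed it (e.g. a run that
  # memorized its training patches) must not be the deployed model
  deployed <- which(sel$realizations$used)[1L]
  model <- models[[deployed]]

  te <- synthetic_cohort_patches(n_test_good, n_test_poor, good_p_in_range,
                                 poor_p_in_range, base, seed = seeds[2L],
                                 id_prefix = "T")
  scores <- predict_outcome(score_patients(predict_patches(model, te$patches)),
                            sel$rc_final)
  confusion <- evaluate_outcomes(scores,
                                 te$patients[, c("patient_id", "outcome")])
  structure(list(rc_selection = sel, scans = scans, model = model,
                 model_realization = deployed, confusion = confusion,
                 test_scores = scores, train_patients = tr$patients,
                 train_patches = tr$patches, test_patients = te$patients,
                 seed = seed),
            class = "til_study")
}

#' @export
print.til_study <- function(x, ...) {
  cat(sprintf("<til_study> seed %d\n", x$seed))
  print(x$rc_selection)
  cat(sprintf("  test cohort: accuracy %.3f, recall %.3f, precision %.3f\n",
              x$confusion$accuracy, x$confusion$recall, x$confusion$precision))
  invisible(x)
}

#' @rdname tilstrat-tidiers
#' @export
glance.til_study <- function(x, ...) {
  tibble::tibble(seed = x$seed,
                 training_separation_accuracy = x$rc_selection$best_accuracy,
                 rc_final = x$rc_selection$rc_final,
                 test_accuracy = x$confusion$accuracy,
                 test_recall = x$confusion$recall,
                 test_precision = x$confusion$precision)
}

#' Good-patch fraction and density baseline across infiltration levels
#'
#' Generates patients on a grid of infiltration levels, scores each with a
#' trained classifier (fraction of its surviving patches labeled "good")
#' and computes the CD8-in-island density baseline, then measures the
#' Spearman rank correlation of both statistics with the true infiltration
#' parameter.
#'
#' @param model A trained [patch_cnn].
#' @param p_in_levels Infiltration grid (default 0.1 to 0.9 by 0.1).
#' @param n_per_level Patients per level.
#' @param base Generator parameters.
#' @param seed Seed for patient generation.
#' @param config Pipeline configuration for preprocessing.
#' @return A list: `patients` tibble (`patient_id`, `truth_p_in`, `r_good`,
#'   `cd8_density_in_islands`, `n_patches`), `spearman_r_good`,
#'   `spearman_density`.
#' @export
infiltration_monotonicity <- function(model, p_in_levels = seq(0.1, 0.9, 0.1),
                                      n_per_level = 3L,
                                      base = synthetic_study_params(),
                                      seed = 1L,
                                      config = pipeline_config()) {
  grid <- expand.grid(level = p_in_levels, rep = seq_len(n_per_level))
  seeds <- derive_child_seeds(seed, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pars <- base
    pars$p_in <- grid$level[i]
    pars$seed <- seeds[i]
    pid <- sprintf("M%02d", i)
    pat <- generate_patient(pars, patient_id = pid)
    red <- reduce_patient_(pat, config)
    r_good <- if (nrow(red$patches) > 0) {
      score_patients(predict_patches(model, red$patches))$r_good
    } else NA_real_
    rows[[i]] <- dplyr::bind_cols(
      tibble::tibble(patient_id = pid, truth_p_in = grid$level[i],
                     r_good = r_good),
      red$summary)
  }
  patients <- dplyr::bind_rows(rows)
  ok <- !is.na(patients$r_good)
  if (any(!ok)) {
    warn(sprintf("%d patient(s) had no surviving patches", sum(!ok)))
  }
  list(patients = patients,
       spearman_r_good = cor(patients$truth_p_in[ok], patients$r_good[ok],
                             method = "spearman"),
       spearman_density = cor(patients$truth_p_in[ok],
                              patients$cd8_density_in_islands[ok],
                              method = "spearman"))
}

#' Subsampling robustness on homogeneous vs heterogeneous tumors
#'
#' Builds one spatially homogeneous patient (uniform high infiltration)
#' and one deliberately heterogeneous patient (left half highly
#' infiltrated, right half immune-excluded), and measures prediction
#' stability under half-section subsampling: random halves of the
#' homogeneous tumor should agree with the full-section call, while the
#' contiguous halves of the heterogeneous tumor should disagree with each
#' other.
#'
#' @param model A trained [patch_cnn].
#' @param rc Patient-level cut-off.
#' @param base Generator parameters.
#' @param seed Seed.
#' @param n_repeats Random-half repeats for the homogeneous patient.
#' @param p_in_high,p_in_low Infiltration of the two heterogeneous halves
#'   (and `p_in_high` for the homogeneous patient).
#' @param config Pipeline configuration.
#' @return A list: `homogeneous` and `heterogeneous` report tibbles from
#'   [subsample_robustness()], `homogeneous_agreement` (rate) and
#'   `heterogeneous_discordant` (logical: the two contiguous halves
#'   disagree).
#' @export
robustness_study <- function(model, rc, base = synthetic_study_params(),
                             seed = 1L, n_repeats = 10L, p_in_high = 0.85,
                             p_in_low = 0.1, config = pipeline_config()) {
  seeds <- derive_child_seeds(seed, 2L)
  pars <- base
  pars$p_in <- p_in_high
  pars$seed <- seeds[1L]
  hom <- reduce_patient_(generate_patient(pars, "HOM"), config)$patches
  hom_rep <- subsample_robustness(hom, model, rc, fraction = 0.5,
                                  mode = "random", n_repeats = n_repeats,
                                  seed = seeds[1L])
  pars$seed <- seeds[2L]
  het_pat <- generate_heterogeneous_patient(pars, p_in_left = p_in_high,
                                            p_in_right = p_in_low,
                                            patient_id = "HET")
  het <- reduce_patient_(het_pat, config)$patches
  het_rep <- subsample_robustness(het, model, rc, fraction = 0.5,
                                  mode = "contiguous")
  list(homogeneous = hom_rep, heterogeneous = het_rep,
       homogeneous_agreement = mean(hom_rep$agree),
       heterogeneous_discordant =
         length(unique(het_rep$predicted)) > 1L)
}
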