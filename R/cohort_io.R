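manifest_columns <- c("patient_id", "panck_path", "cd8_path",
                      "pixel_size_um", "outcome", "grade", "nodal_status")

#' Read and validate a cohort manifest
#'
#' The manifest is a tab-separated table with columns `patient_id`,
#' `panck_path`, `cd8_path`, `pixel_size_um`, `outcome`, `grade`,
#' `nodal_status`. Outcome labels follow the relapse rule the pipeline is
#' built around: relapse within 3 years of surgery is "poor", relapse-free
#' for at least 5 years is "good", patients in between are "unknown" —
#' excluded from training and cut-off selection but still scorable.
#'
#' @param path Path to the manifest TSV.
#' @return A validated tibble of patient records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = NULL, colClasses = "character")
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    abort(paste("manifest lacks required column(s):",
                paste(missing, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$pixel_size_um <- as.numeric(df$pixel_size_um)
  dup <- unique(df$patient_id[duplicated(df$patient_id)])
  if (length(dup)) {
    abort(paste("duplicate patient_id(s):", paste(dup, collapse = ", ")))
  }
  bad <- setdiff(unique(df$outcome), c("good", "poor", "unknown"))
  if (length(bad)) {
    abort(paste("invalid outcome value(s):", paste(bad, collapse = ", "),
                "(allowed: good, poor, unknown)"))
  }
  bad <- setdiff(unique(df$grade), c("I", "II", "III", "NA"))
  if (length(bad)) {
    abort(paste("invalid grade value(s):", paste(bad, collapse = ", ")))
  }
  bad <- setdiff(unique(df$nodal_status), c("yes", "no", "NA"))
  if (length(bad)) {
    abort(paste("invalid nodal_status value(s):", paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(df$pixel_size_um) | df$pixel_size_um <= 0)) {
    abort("pixel_size_um must be positive")
  }
  df
}

#' Pipeline configuration
#'
#' One bag for every tunable of the pipeline, round-trippable through a
#' YAML file with [read_pipeline_config()] / [write_pipeline_config()].
#'
#' @param percentile_q Binarization percentile (default 90).
#' @param min_area_um2 Component-removal area threshold in um^2.
#' @param fill_area_um2 PanCK hole-filling area threshold in um^2.
#' @param target_um Working grid pixel size in um (default 10).
#' @param patch_size_px Patch edge length (default 64).
#' @param min_panck_frac Patch PanCK-fraction filter (default 0.25).
#' @param min_cd8 Patch CD8-presence filter (default 1 pixel).
#' @param train A [train_config()].
#' @param realizations Number of split+training realizations used for
#'   cut-off selection (default 5).
#' @param seed Master seed for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(percentile_q = 90, min_area_um2 = 200,
                            fill_area_um2 = 200, target_um = 10,
                            patch_size_px = 64L, min_panck_frac = 0.25,
                            min_cd8 = 1L, train = train_config(),
                            realizations = 5L, seed = 1L) {
  stopifnot(inherits(train, "train_config"))
  assert_scalar_number(realizations, "realizations", lower = 1)
  structure(list(percentile_q = percentile_q, min_area_um2 = min_area_um2,
                 fill_area_um2 = fill_area_um2, target_um = target_um,
                 patch_size_px = as.integer(patch_size_px),
                 min_panck_frac = min_panck_frac,
                 min_cd8 = as.integer(min_cd8), train = train,
                 realizations = as.integer(realizations),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$train <- unclass(x$train)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  train <- do.call(train_config, x$train)
  x$train <- NULL
  do.call(pipeline_config, c(x, list(train = train)))
}

#' Preprocess and patchify every patient in a manifest
#'
#' Reads each patient's channel TIFFs, builds the cleaned mask pair,
#' rescales to the working grid and tiles into filtered patches.
#'
#' @param manifest Manifest tibble from [read_manifest()].
#' @param config A [pipeline_config()].
#' @param outdir Optional directory; when given, cleaned masks (as 0/1
#'   TIFF) and the patch index TSV are written there.
#' @return A list: `patches` (patch tibble with an `outcome` column) and
#'   `patient_counts` (per-patient patch bookkeeping, including patients
#'   with zero surviving patches).
#' @export
prepare_cohort_patches <- function(manifest, config = pipeline_config(),
                                   outdir = NULL) {
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  all_patches <- list()
  counts <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    mp <- withCallingHandlers({
      panck <- read_if_image(rec$panck_path, rec$pixel_size_um)
      cd8 <- read_if_image(rec$cd8_path, rec$pixel_size_um)
      make_mask_pair(panck, cd8, config$percentile_q, config$min_area_um2,
                     config$fill_area_um2)
    }, error = function(e) {
      abort(sprintf("preprocess failed for patient %s: %s", rec$patient_id,
                    conditionMessage(e)))
    })
    smp <- rescale_mask_pair(mp, config$target_um)
    tiles <- tile_patches(smp, config$patch_size_px, rec$patient_id)
    kept <- filter_patches(tiles, config$min_panck_frac, config$min_cd8)
    if (!is.null(outdir)) {
      tiff::writeTIFF(matrix(as.numeric(mp$panck), nrow(mp$panck)),
                      file.path(outdir, paste0(rec$patient_id, "_panck_mask.tif")))
      tiff::writeTIFF(matrix(as.numeric(mp$cd8), nrow(mp$cd8)),
                      file.path(outdir, paste0(rec$patient_id, "_cd8_mask.tif")))
      jsonlite::write_json(
        list(patient_id = rec$patient_id,
             percentile_q = config$percentile_q,
             min_area_um2 = config$min_area_um2,
             fill_area_um2 = config$fill_area_um2,
             pixel_size_um = mp$pixel_size_um,
             panck_positive_px = sum(mp$panck), cd8_positive_px = sum(mp$cd8)),
        file.path(outdir, paste0(rec$patient_id, "_masks.json")),
        auto_unbox = TRUE, digits = NA)
    }
    kept$outcome <- rec$outcome
    all_patches[[rec$patient_id]] <- kept
    counts[[i]] <- tibble::tibble(patient_id = rec$patient_id,
                                  outcome = rec$outcome,
                                  n_tiles = nrow(tiles),
                                  n_patches = nrow(kept))
  }
  patches <- dplyr::bind_rows(all_patches)
  patient_counts <- dplyr::bind_rows(counts)
  none <- patient_counts$patient_id[patient_counts$n_patches == 0L]
  if (length(none)) {
    warn(paste("patient(s) with zero surviving patches (unpredictable):",
               paste(none, collapse = ", ")))
  }
  if (!is.null(outdir) && nrow(patches)) {
    utils::write.table(dplyr::select(patches, -"panck", -"cd8"),
                       file.path(outdir, "patch_index.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(patches = patches, patient_counts = patient_counts)
}

#' Run the full stratification pipeline
#'
#' `mode = "train"`: preprocess the training manifest, run
#' `config$realizations` holdout-split + training realizations, scan the
#' cut-off per realization and select the final Rc. The deployed
#' classifier is the one from the first realization whose holdout
#' validation attained the best separation.
#' `mode = "predict"`: apply a trained model and cut-off to a manifest and
#' (where truth labels exist) evaluate the confusion summary.
#' `mode = "full"`: train, then predict — on `test_manifest` when given,
#' otherwise back on the training cohort's full patch sets.
#'
#' @param manifest Training (or prediction) manifest tibble.
#' @param config A [pipeline_config()].
#' @param mode One of "full", "train", "predict".
#' @param model Trained [patch_cnn] (required for `mode = "predict"`).
#' @param rc Patient-level cut-off (required for `mode = "predict"`).
#' @param test_manifest Optional test-cohort manifest for `mode = "full"`.
#' @param outdir Optional directory for intermediates and the run report.
#' @return A list of class `til_run` containing, depending on mode:
#'   `model`, `rc_selection`, `scans`, `scores`, `predictions`,
#'   `confusion`, `patient_counts`, `config` and `seeds`.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         mode = c("full", "train", "predict"), model = NULL,
                         rc = NULL, test_manifest = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "predict") {
    if (is.null(model)) abort("predict mode requires a trained `model`")
    if (is.null(rc)) abort("predict mode requires a cut-off `rc`")
    return(predict_cohort_(manifest, config, model, rc, outdir))
  }

  known <- manifest[manifest$outcome %in% c("good", "poor"), ]
  n_excluded <- nrow(manifest) - nrow(known)
  if (n_excluded > 0) {
    warn(sprintf("%d patient(s) with unknown outcome excluded from training",
                 n_excluded))
  }
  if (!all(c("good", "poor") %in% known$outcome)) {
    abort("training needs patients of both outcome groups")
  }
  prep <- prepare_cohort_patches(known, config, outdir)
  patches <- prep$patches
  truths <- dplyr::distinct(known[, c("patient_id", "outcome")])

  seeds <- derive_child_seeds(config$seed, config$realizations)
  scans <- vector("list", config$realizations)
  models <- vector("list", config$realizations)
  holdout_scores <- vector("list", config$realizations)
  for (r in seq_len(config$realizations)) {
    sp <- split_train_holdout(patches, config$train$train_frac, seeds[r])
    train_set <- balance_by_replication(sp$train,
                                        config$train$extra_copies_minority,
                                        seeds[r])
    cfg_r <- config$train
    cfg_r$seed <- seeds[r]
    models[[r]] <- train_patch_classifier(train_set, cfg_r)
    holdout_scores[[r]] <- score_patients(
      predict_patches(models[[r]], sp$holdout))
    scans[[r]] <- scan_rc(holdout_scores[[r]], truths)
  }
  sel <- select_rc(scans)
  # deploy the model of the first realization whose holdout validation
  # attained the best separation (the scan is the vetting step)
  deployed <- which(sel$realizations$used)[1L]
  out <- structure(list(mode = "train", model = models[[deployed]],
                        model_realization = deployed,
                        rc_selection = sel, scans = scans,
                        holdout_scores = holdout_scores[[deployed]],
                        patient_counts = prep$patient_counts,
                        truths = truths, config = config, seeds = seeds),
                   class = "til_run")

  if (mode == "full") {
    target <- if (is.null(test_manifest)) manifest else test_manifest
    pred <- predict_cohort_(target, config, out$model, sel$rc_final,
                            outdir, patches = if (is.null(test_manifest))
                              patches else NULL)
    out$predictions <- pred$predictions
    out$scores <- pred$scores
    out$confusion <- pred$confusion
    out$mode <- "full"
  }
  if (!is.null(outdir)) write_run_report_(out, outdir)
  out
}

predict_cohort_ <- function(manifest, config, model, rc, outdir = NULL,
                            patches = NULL) {
  if (is.null(patches)) {
    prep <- prepare_cohort_patches(manifest, config, outdir)
    patches <- prep$patches
    counts <- prep$patient_counts
  } else {
    counts <- dplyr::count(patches, .data$patient_id, name = "n_patches")
  }
  preds <- predict_patches(model, patches)
  scores <- predict_outcome(score_patients(preds), rc)
  truths <- manifest[manifest$outcome %in% c("good", "poor"),
                     c("patient_id", "outcome")]
  confusion <- if (nrow(truths) > 0 &&
                   any(scores$patient_id %in% truths$patient_id)) {
    evaluate_outcomes(scores[scores$patient_id %in% truths$patient_id, ],
                      truths[truths$patient_id %in% scores$patient_id, ])
  } else NULL
  structure(list(mode = "predict", predictions = preds, scores = scores,
                 confusion = confusion, patient_counts = counts,
                 rc = rc, config = config), class = "til_run")
}

write_run_report_ <- function(run, outdir) {
  cfg_plain <- unclass(run$config)
  cfg_plain$train <- unclass(cfg_plain$train)
  report <- list(mode = run$mode, seeds = run$seeds,
                 rc_final = if (!is.null(run$rc_selection))
                   run$rc_selection$rc_final else run$rc,
                 realizations = if (!is.null(run$rc_selection))
                   run$rc_selection$realizations else NULL,
                 patient_counts = run$patient_counts,
                 confusion = run$confusion,
                 config = cfg_plain)
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(run$scores)) {
    utils::write.table(run$scores, file.path(outdir, "patient_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' @export
print.til_run <- function(x, ...) {
  cat(sprintf("<til_run> mode = %s\n", x$mode))
  if (!is.null(x$rc_selection)) print(x$rc_selection)
  if (!is.null(x$confusion)) {
    cat(sprintf("  cohort accuracy %.3f (recall %.3f, precision %.3f)\n",
                x$confusion$accuracy, x$confusion$recall,
                x$confusion$precision))
  }
  invisible(x)
}

#' @rdname tilstrat-tidiers
#' @export
glance.til_run <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    rc_final = if (!is.null(x$rc_selection)) x$rc_selection$rc_final
               else x$rc,
    best_training_accuracy = if (!is.null(x$rc_selection))
      x$rc_selection$best_accuracy else NA_real_,
    accuracy = if (!is.null(x$confusion)) x$confusion$accuracy else NA_real_,
    recall = if (!is.null(x$confusion)) x$confusion$recall else NA_real_,
    precision = if (!is.null(x$confusion)) x$confusion$precision else NA_real_)
}
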