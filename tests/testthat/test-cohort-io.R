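write_manifest_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_manifest <- function() {
  tibble::tibble(patient_id = c("p1", "p2", "p3"),
                 panck_path = "x.tif", cd8_path = "y.tif",
                 pixel_size_um = "0.5",
                 outcome = c("good", "poor", "unknown"),
                 grade = c("III", "II", "NA"),
                 nodal_status = c("yes", "no", "NA"))
}

test_that("manifest validation names each failure", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  man <- read_manifest(write_manifest_(base_manifest(), tmp))
  expect_equal(nrow(man), 3L)
  expect_equal(sum(man$outcome == "unknown"), 1L)

  bad <- base_manifest()
  bad$patient_id[2] <- "p1"
  expect_error(read_manifest(write_manifest_(bad, tmp)), "duplicate.*p1")

  bad2 <- base_manifest()[, -5]
  expect_error(read_manifest(write_manifest_(bad2, tmp)), "outcome")

  bad3 <- base_manifest()
  bad3$outcome[1] <- "excellent"
  expect_error(read_manifest(write_manifest_(bad3, tmp)), "excellent")

  bad4 <- base_manifest()
  bad4$grade[1] <- "IV"
  expect_error(read_manifest(write_manifest_(bad4, tmp)), "grade")

  expect_error(read_manifest(file.path(tempdir(), "nope.tsv")), "not found")
})

test_that("pipeline configuration round-trips through YAML", {
  cfg <- pipeline_config(percentile_q = 85, min_area_um2 = 150,
                         train = train_config(epochs = 7, seed = 3,
                                              learning_rate = 0.01),
                         realizations = 2, seed = 42)
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, tmp)
  cfg2 <- read_pipeline_config(tmp)
  expect_equal(cfg2, cfg)
})

test_that("the orchestrated pipeline runs end to end on a written cohort", {
  dir <- withr::local_tempdir()
  base <- patchy_params()
  coh <- generate_cohort(3, 3, good_p_in_range = c(0.75, 0.9),
                         poor_p_in_range = c(0.0, 0.1), base = base,
                         seed = 77L)
  man <- read_manifest(write_cohort(coh, dir))
  cfg <- pipeline_config(train = train_config(learning_rate = 0.02,
                                              weight_decay = 1e-3,
                                              epochs = 6, seed = 1),
                         realizations = 2, seed = 5)
  run <- suppressWarnings(
    run_pipeline(man, cfg, mode = "full", outdir = file.path(dir, "out")))
  expect_s3_class(run, "til_run")
  expect_true(is.finite(run$rc_selection$rc_final))
  expect_equal(length(run$scans), 2L)
  expect_s3_class(run$confusion, "confusion_summary")
  expect_true(file.exists(file.path(dir, "out", "run_report.json")))
  expect_true(file.exists(file.path(dir, "out", "patch_index.tsv")))
  side <- jsonlite::read_json(file.path(dir, "out", "SG01_masks.json"))
  expect_equal(side$percentile_q, 90)
  expect_equal(side$pixel_size_um, 2.5)
  g <- glance(run)
  expect_equal(g$mode, "full")

  # rerun with identical config + seeds reproduces the metrics
  run2 <- suppressWarnings(run_pipeline(man, cfg, mode = "full"))
  expect_equal(glance(run2), g)

  # predict mode demands its artifacts
  expect_error(run_pipeline(man, cfg, mode = "predict"), "model")
  expect_error(run_pipeline(man, cfg, mode = "predict",
                            model = run$model), "rc")
  pred <- suppressWarnings(run_pipeline(man, cfg, mode = "predict",
                                        model = run$model,
                                        rc = run$rc_selection$rc_final))
  expect_equal(nrow(pred$scores), 6L)
})

test_that("unknown outcomes are excluded from training but scoreable", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(2, 2, base = patchy_params(),
                         good_p_in_range = c(0.75, 0.9),
                         poor_p_in_range = c(0.0, 0.1), seed = 88L)
  man <- read_manifest(write_cohort(coh, dir))
  man$outcome[4] <- "unknown"
  cfg <- pipeline_config(train = train_config(learning_rate = 0.02,
                                              epochs = 4, seed = 2),
                         realizations = 1, seed = 9)
  w <- testthat::capture_warnings(run <- run_pipeline(man, cfg, mode = "train"))
  expect_true(any(grepl("unknown outcome", w)))
  expect_false("unknown" %in% run$truths$outcome)
  expect_equal(nrow(run$patient_counts), 3L)
})

test_that("streamed cohort patches match the in-memory route", {
  base <- patchy_params()
  cfg <- pipeline_config()
  streamed <- synthetic_cohort_patches(2, 1, base = base, seed = 31L,
                                       config = cfg)
  coh <- generate_cohort(2, 1, base = base, seed = 31L)
  direct <- purrr::map2_dfr(coh$patient, coh$outcome, function(p, oc) {
    mp <- make_mask_pair(p$panck, p$cd8)
    k <- filter_patches(tile_patches(rescale_mask_pair(mp), 64, p$patient_id))
    k$outcome <- oc
    k
  })
  expect_equal(streamed$patches$n_panck, direct$n_panck)
  expect_identical(streamed$patches$panck, direct$panck)
  expect_equal(streamed$patients$truth_p_in, coh$truth_p_in)
})
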