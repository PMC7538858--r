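test_that("generation is deterministic given the seed", {
  p1 <- generate_patient(tiny_params(seed = 5L, p_in = 0.5))
  p2 <- generate_patient(tiny_params(seed = 5L, p_in = 0.5))
  expect_identical(p1$panck$pixels, p2$panck$pixels)
  expect_identical(p1$cd8$pixels, p2$cd8$pixels)
  expect_identical(p1$tcells, p2$tcells)
  p3 <- generate_patient(tiny_params(seed = 6L, p_in = 0.5))
  expect_false(identical(p1$panck$pixels, p3$panck$pixels))
})

test_that("all T-cell centers fall inside islands when p_in = 1", {
  p <- generate_patient(tiny_params(p_in = 1, noise_sd = 0, seed = 2L))
  expect_true(all(p$island_mask[cbind(p$tcells$row, p$tcells$col)] == 1L))
  expect_true(all(p$tcells$inside))
})

test_that("empirical inside fraction converges to p_in", {
  p <- generate_patient(tiny_params(p_in = 0.7, n_tcells = 1000L, seed = 3L))
  # binomial: sd = sqrt(0.7 * 0.3 / 1000) ~ 0.0145; allow 4 sd
  expect_lt(abs(mean(p$tcells$inside) - 0.7), 0.06)
  expect_true(all(p$island_mask[cbind(p$tcells$row[p$tcells$inside],
                                      p$tcells$col[p$tcells$inside])] == 1L))
})

test_that("degenerate generator inputs are rejected", {
  expect_error(generate_patient(tiny_params(n_islands = 0L, p_in = 0.5)),
               "island")
  expect_error(
    generate_patient(synthetic_params(canvas_size_px = c(64L, 64L),
                                      pixel_size_um = 0.5,
                                      island_radius_um = c(60, 150))),
    "too small")
  expect_error(synthetic_params(p_in = 1.5), "p_in")
  expect_error(synthetic_params(tcell_radius_um = 0), "tcell_radius_um")
})

test_that("intensities are non-negative and noise-free channels are clean", {
  p <- generate_patient(tiny_params(seed = 4L))
  expect_true(all(p$panck$pixels >= 0))
  expect_true(all(p$cd8$pixels >= 0))
  p0 <- generate_patient(tiny_params(noise_sd = 0, seed = 4L))
  expect_setequal(unique(as.vector(p0$panck$pixels)), c(0, 1))
})

test_that("cohort composition, labels and separation behave as requested", {
  coh <- generate_cohort(n_good = 4, n_poor = 3,
                         base = tiny_params(n_tcells = 30L), seed = 7L)
  expect_equal(nrow(coh), 7L)
  expect_equal(sum(coh$outcome == "good"), 4L)
  expect_equal(sum(coh$outcome == "poor"), 3L)
  expect_true(all(coh$truth_p_in[coh$outcome == "good"] >
                    max(coh$truth_p_in[coh$outcome == "poor"])))
  expect_true(all(purrr::map_chr(coh$patient, "truth_outcome") == coh$outcome))

  empty <- generate_cohort(0, 0, base = tiny_params(), seed = 1L)
  expect_equal(nrow(empty), 0L)

  expect_warning(generate_cohort(1, 1, good_p_in_range = c(0.1, 0.5),
                                 poor_p_in_range = c(0.3, 0.6),
                                 base = tiny_params(n_tcells = 10L),
                                 seed = 1L),
                 "overlap")
  expect_error(generate_cohort(-1, 2, base = tiny_params()), "n_good")
})

test_that("cohorts are reproducible and patients match standalone generation", {
  base <- tiny_params(n_tcells = 40L)
  c1 <- generate_cohort(2, 2, base = base, seed = 11L)
  c2 <- generate_cohort(2, 2, base = base, seed = 11L)
  expect_identical(c1$patient[[3]]$cd8$pixels, c2$patient[[3]]$cd8$pixels)
  pars <- base
  pars$p_in <- c1$truth_p_in[1]
  pars$seed <- c1$seed[1]
  solo <- generate_patient(pars, patient_id = c1$patient_id[1],
                           outcome = "good")
  expect_identical(solo$panck$pixels, c1$patient[[1]]$panck$pixels)
})

test_that("heterogeneous patients splice the two infiltration levels", {
  pars <- tiny_params(seed = 21L, n_tcells = 400L)
  het <- generate_heterogeneous_patient(pars, p_in_left = 0.9,
                                        p_in_right = 0.1)
  nc <- ncol(het$panck$pixels)
  left_cells <- het$tcells[het$tcells$col <= nc %/% 2, ]
  right_cells <- het$tcells[het$tcells$col > nc %/% 2, ]
  expect_gt(mean(left_cells$inside), mean(right_cells$inside))
  expect_equal(dim(het$cd8$pixels), dim(het$panck$pixels))
})

test_that("written cohorts round-trip through TIFF and the manifest", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(1, 1, base = tiny_params(n_tcells = 25L), seed = 9L)
  manifest_path <- write_cohort(coh, dir)
  man <- read_manifest(manifest_path)
  expect_equal(nrow(man), 2L)
  expect_setequal(man$outcome, c("good", "poor"))
  img <- read_if_image(man$panck_path[1], man$pixel_size_um[1])
  orig <- coh$patient[[1]]$panck
  expect_equal(dim(img$pixels), dim(orig$pixels))
  # stored intensities are rescaled to [0,1]; binarization is invariant
  expect_equal(binarize_channel(img, 90), binarize_channel(orig, 90))
})
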