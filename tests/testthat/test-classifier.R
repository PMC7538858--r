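test_that("per-patient split follows the rounding rule and is deterministic", {
  # one patient with 10 patches
  big <- dplyr::bind_rows(purrr::map(1:10, function(i) {
    patch_row(matrix(1L, 64, 64), matrix(0L, 64, 64), "multi", row = i)
  }))
  sp <- suppressWarnings(split_train_holdout(big, 0.8, seed = 4))
  expect_equal(nrow(sp$train), 8L)
  expect_equal(nrow(sp$holdout), 2L)
  expect_equal(dplyr::bind_rows(sp$train, sp$holdout) |>
                 dplyr::arrange(row) |> nrow(), 10L)

  # single-patch patient: round(0.8) = 1 -> all in train, warning
  single <- patch_row(matrix(1L, 64, 64), matrix(0L, 64, 64), "solo")
  expect_warning(sp1 <- split_train_holdout(single, 0.8, seed = 1), "solo")
  expect_equal(nrow(sp1$train), 1L)
  expect_equal(nrow(sp1$holdout), 0L)

  sp2 <- suppressWarnings(split_train_holdout(big, 0.8, seed = 4))
  expect_identical(sp$train$row, sp2$train$row)
})

test_that("replication balancing changes multiplicities only", {
  patches <- toy_patch_tbl(6, seed = 2)  # 6 good + 6 poor
  patches$outcome[1:9] <- "good"         # 9 good vs 3 poor
  patches$outcome[10:12] <- "poor"
  bal <- balance_by_replication(patches, extra_copies = 3, seed = 5)
  expect_equal(sum(bal$outcome == "poor"), 12L)  # 3 * (3 + 1)
  expect_equal(sum(bal$outcome == "good"), 9L)
  # distinct patch set unchanged
  key <- function(df) sort(unique(paste(df$patient_id, df$row, df$col)))
  expect_identical(key(bal), key(patches))

  bal0 <- balance_by_replication(patches, extra_copies = 0, seed = 5)
  expect_equal(nrow(bal0), nrow(patches))

  mono <- patches[patches$outcome == "good", ]
  expect_warning(out <- balance_by_replication(mono, 3, 1), "one outcome")
  expect_identical(out, mono)
})

test_that("training is deterministic and learns a separable toy task", {
  tr <- toy_patch_tbl(60, seed = 3)
  probe <- toy_patch_tbl(30, seed = 4)
  cfg <- train_config(learning_rate = 0.02, weight_decay = 1e-3,
                      epochs = 8, seed = 7)
  m1 <- train_patch_classifier(tr, cfg)
  m2 <- train_patch_classifier(tr, cfg)
  expect_identical(predict(m1, probe), predict(m2, probe))

  pr <- predict_patches(m1, probe)
  acc <- mean(pr$label == probe$outcome)
  expect_gte(acc, 0.9)
  expect_true(all(pr$prob_poor >= 0 & pr$prob_poor <= 1))
  expect_gte(m1$trace$accuracy[8], 0.9)

  expect_error(train_patch_classifier(tr[tr$outcome == "good", ], cfg),
               "both outcome classes")
})

test_that("randomly permuted labels give chance-level holdout accuracy", {
  tr <- toy_patch_tbl(60, seed = 8)
  te <- toy_patch_tbl(50, seed = 9)
  tr$outcome <- withr::with_seed(10, sample(tr$outcome))
  m <- train_patch_classifier(tr, train_config(learning_rate = 0.02,
                                               epochs = 8, seed = 11))
  acc <- mean(predict_patches(m, te)$label == te$outcome)
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("model outputs stay in [0,1] for arbitrary binary input", {
  m <- constant_half_model()
  m2 <- train_patch_classifier(toy_patch_tbl(10, seed = 12),
                               train_config(learning_rate = 0.05,
                                            epochs = 3, seed = 13))
  withr::with_seed(14, {
    arb <- dplyr::bind_rows(purrr::map(1:20, function(i) {
      patch_row(matrix(rbinom(4096, 1, runif(1)), 64, 64),
                matrix(rbinom(4096, 1, runif(1)), 64, 64), "arb", row = i)
    }))
  })
  for (mm in list(m, m2)) {
    p <- predict(mm, arb)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("patch labeling uses a strict > cutoff (ties are good)", {
  m <- constant_half_model()  # prob exactly 0.5 for every patch
  patches <- toy_patch_tbl(3, seed = 15)
  pr <- predict_patches(m, patches, patch_cutoff = 0.5)
  expect_equal(pr$prob_poor, rep(0.5, nrow(patches)))
  expect_true(all(pr$label == "good"))
  pr2 <- predict_patches(m, patches, patch_cutoff = 0.49)
  expect_true(all(pr2$label == "poor"))
  expect_equal(nrow(predict_patches(m, patches[0, ])), 0L)
})

test_that("checkpoints round-trip through JSON at full precision", {
  m <- train_patch_classifier(toy_patch_tbl(6, seed = 17),
                              train_config(learning_rate = 0.02, epochs = 2,
                                           seed = 5))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_patch_cnn(m, tmp)
  m2 <- load_patch_cnn(tmp)
  expect_equal(m2$weights, m$weights, tolerance = 1e-14)
  probe <- toy_patch_tbl(5, seed = 18)
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-14)
  expect_equal(m2$cfg, m$cfg)
  expect_error(load_patch_cnn(file.path(tempdir(), "absent.json")),
               "checkpoint")
})

test_that("tidiers and config validation behave", {
  m <- train_patch_classifier(toy_patch_tbl(5, seed = 16),
                              train_config(epochs = 2, seed = 1))
  expect_equal(nrow(tidy(m)), 2L)
  g <- glance(m)
  expect_equal(g$epochs, 2L)
  expect_equal(g$architecture, "small_cnn")
  expect_error(train_config(train_frac = 1), "train_frac")
  expect_error(train_config(patch_cutoff = 0), "patch_cutoff")
  expect_error(train_config(architecture = "resnet"), "arg")
})
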