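score_tbl <- function(ids, r) {
  tibble::tibble(patient_id = ids, n_patches_evaluated = 10L, r_good = r)
}
truth_tbl <- function(ids, outcome) {
  tibble::tibble(patient_id = ids, outcome = outcome)
}

test_that("patient scores are the good-patch fractions", {
  preds <- tibble::tibble(
    patient_id = c(rep("A", 4), rep("B", 3), rep("C", 2)),
    label = c("good", "good", "good", "poor", rep("good", 3), "poor", "poor"))
  sc <- score_patients(preds)
  expect_equal(sc$r_good[sc$patient_id == "A"], 0.75)
  expect_equal(sc$r_good[sc$patient_id == "B"], 1.0)
  expect_equal(sc$r_good[sc$patient_id == "C"], 0.0)
  expect_equal(sc$n_patches_evaluated, c(4L, 3L, 2L))

  # invariant to order and duplication
  sc2 <- score_patients(preds[sample.int(nrow(preds)), ])
  expect_equal(dplyr::arrange(sc, patient_id), dplyr::arrange(sc2, patient_id))
  sc3 <- score_patients(dplyr::bind_rows(preds, preds))
  expect_equal(sc3$r_good, sc$r_good)
})

test_that("the cut-off scan finds the exact optimal interval", {
  s <- scan_rc(score_tbl(c("g1", "g2", "p1", "p2"), c(0.8, 0.9, 0.1, 0.2)),
               truth_tbl(c("g1", "g2", "p1", "p2"),
                         c("good", "good", "poor", "poor")))
  expect_equal(s$max_accuracy, 1.0)
  expect_equal(s$lo, 0.2)
  expect_equal(s$hi, 0.8)

  s2 <- scan_rc(score_tbl(c("g1", "g2", "p1", "p2"), c(0.1, 0.3, 0.2, 0.4)),
                truth_tbl(c("g1", "g2", "p1", "p2"),
                          c("good", "good", "poor", "poor")))
  expect_equal(s2$max_accuracy, 0.5)

  s3 <- scan_rc(score_tbl(c("g", "p"), c(1, 0)),
                truth_tbl(c("g", "p"), c("good", "poor")))
  expect_equal(s3$max_accuracy, 1.0)
  expect_equal(c(s3$lo, s3$hi), c(0, 1))

  expect_error(scan_rc(score_tbl("a", 0.5), truth_tbl("a", "good")),
               "outcome group")
})

test_that("the scan agrees with brute-force enumeration on random inputs", {
  withr::with_seed(51, {
    for (i in seq_len(50)) {
      n <- sample(4:20, 1)
      r <- round(runif(n), 2)
      truth <- sample(c("good", "poor"), n, replace = TRUE)
      if (length(unique(truth)) < 2) truth[1:2] <- c("good", "poor")
      ids <- sprintf("p%02d", seq_len(n))
      s <- scan_rc(score_tbl(ids, r), truth_tbl(ids, truth))
      expect_equal(s$max_accuracy,
                   oracle_best_accuracy(r, truth == "poor", bounds = c(0, 1)))
      # interval really attains the max accuracy at its midpoint
      mid <- (s$lo + s$hi) / 2
      expect_equal(mean((r < mid) == (truth == "poor")), s$max_accuracy)
    }
  })
})

test_that("rc selection averages midpoints of the best realizations", {
  mk_scan <- function(lo, hi, acc) {
    structure(list(candidates = tibble::tibble(), max_accuracy = acc,
                   lo = lo, hi = hi, n_patients = 10L),
              class = "threshold_scan")
  }
  sel <- select_rc(list(mk_scan(0.2, 0.4, 1), mk_scan(0.3, 0.5, 1)))
  expect_equal(sel$rc_final, 0.35)

  sel2 <- select_rc(list(mk_scan(0.14, 0.40, 1)))
  expect_equal(sel2$rc_final, 0.27)

  sel3 <- select_rc(rep(list(mk_scan(0.2, 0.6, 0.9)), 3))
  expect_equal(sel3$rc_final, 0.4)

  # imperfect realizations are excluded when others reach the maximum
  sel4 <- select_rc(list(mk_scan(0.2, 0.4, 1), mk_scan(0.0, 0.9, 0.8)))
  expect_equal(sel4$rc_final, 0.3)
  expect_equal(sum(tidy(sel4)$used), 1L)

  expect_error(select_rc(list()), "realization")
})

test_that("outcome prediction treats the boundary as good", {
  sc <- score_tbl(c("a", "b", "c"), c(0.0, 1.0, 0.30))
  out <- predict_outcome(sc, 0.30)
  expect_equal(out$predicted, c("poor", "good", "good"))
})

test_that("confusion summaries reproduce the printed statistics", {
  cm <- confusion_summary(tp = 6, fp = 6, fn = 0, tn = 17)
  expect_equal(cm$recall, 1.0)
  expect_equal(cm$precision, 0.5)
  expect_equal(cm$accuracy, 23 / 29)

  preds <- tibble::tibble(patient_id = c("a", "b", "c"),
                          predicted = c("poor", "good", "good"))
  truths <- truth_tbl(c("a", "b", "c"), c("poor", "good", "poor"))
  cm2 <- evaluate_outcomes(preds, truths)
  expect_equal(unlist(cm2[, c("tp", "fp", "fn", "tn")], use.names = FALSE),
               c(1L, 0L, 1L, 1L))
  expect_error(evaluate_outcomes(preds, truths[1:2, ]), "align")
})

test_that("subsampling a homogeneous patient is stable, fraction 1 is exact", {
  m <- constant_half_model()
  m$weights[length(m$weights)] <- -2  # constant prob ~0.12 -> every patch good
  patches <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    patch_row(matrix(1L, 64, 64), matrix(1L, 64, 64), "hom",
              row = i %/% 4L, col = i %% 4L)
  }))
  full <- subsample_robustness(patches, m, rc = 0.3, fraction = 1)
  expect_equal(nrow(full), 1L)
  expect_true(full$agree)

  rnd <- subsample_robustness(patches, m, rc = 0.3, fraction = 0.5,
                              mode = "random", n_repeats = 10, seed = 2)
  expect_equal(nrow(rnd), 10L)
  expect_true(all(rnd$n_patches == 4L))
  expect_equal(mean(rnd$agree), 1.0)

  cont <- subsample_robustness(patches, m, rc = 0.3, fraction = 0.5,
                               mode = "contiguous")
  expect_equal(nrow(cont), 2L)
  expect_equal(sum(cont$n_patches), nrow(patches))

  expect_error(subsample_robustness(patches[1:3, ], m, 0.3), "4 patches")
  two <- dplyr::bind_rows(patches, patch_row(matrix(1L, 64, 64),
                                             matrix(1L, 64, 64), "other"))
  expect_error(subsample_robustness(two, m, 0.3), "single patient")
})
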