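test_that("percentile binarization follows the nearest-rank rule", {
  # 100 distinct values, q = 90: threshold 90, positives are 91..100
  img <- if_image(matrix(sample(1:100), 10, 10), 0.5)
  m <- binarize_channel(img, 90)
  expect_equal(sum(m), 10L)
  expect_true(all(img$pixels[m == 1L] > 90))

  expect_warning(b0 <- binarize_channel(if_image(matrix(0, 5, 5), 1), 90),
                 "constant")
  expect_equal(sum(b0), 0L)
  expect_error(binarize_channel(if_image(matrix(1, 2, 2), 1), 100),
               "percentile_q")
})

test_that("binarized positive fraction tracks (100 - q)/100", {
  withr::with_seed(31, {
    for (q in c(50, 75, 90, 95)) {
      n <- 200 * 200
      img <- if_image(matrix(runif(n), 200, 200), 1)
      frac <- mean(binarize_channel(img, q))
      expect_lt(abs(frac - (100 - q) / 100), 1 / sqrt(n) + 1e-6)
    }
  })
})

test_that("component removal applies the strict physical-area rule", {
  # 799 px at 0.5 um/px = 199.75 um^2 -> removed; 800 px = 200 um^2 -> kept
  for (npx in c(799L, 800L)) {
    mask <- matrix(0L, 40, 40)
    mask[seq_len(npx)] <- 1L  # one 8-connected column-major block
    expect_true(all(diff(range(which(mask == 1L))) == npx - 1))
    out <- remove_small_components(mask, 200, 0.5)
    if (npx == 799L) expect_equal(sum(out), 0L) else expect_equal(sum(out), 800L)
  }

  # two components, 900 px and 700 px: only the larger survives
  mask <- matrix(0L, 40, 80)
  mask[1:30, 1:30] <- 1L    # 900 px
  mask[1:20, 45:79] <- 1L   # 700 px
  out <- remove_small_components(mask, 200, 0.5)
  expect_equal(sum(out), 900L)
  expect_true(all(out[1:30, 1:30] == 1L))

  expect_equal(remove_small_components(matrix(0L, 5, 5), 200, 0.5),
               matrix(0L, 5, 5))
  expect_error(remove_small_components(matrix(2L, 3, 3), 200, 0.5), "binary")
})

test_that("hole filling fills only small enclosed background", {
  ring <- function(hole_px) {
    # hole of exactly hole_px pixels as a column-major run inside a frame
    side <- ceiling(sqrt(hole_px)) + 2L
    m <- matrix(1L, side + 2L, side + 2L)
    hole <- matrix(1L, side, side)
    hole[seq_len(hole_px)] <- 0L
    m[2:(side + 1L), 2:(side + 1L)] <- hole
    m
  }
  solid <- matrix(1L, 10, 10)
  expect_identical(fill_small_holes(solid, 200, 0.5), solid)

  small <- ring(100L)  # 25 um^2 at 0.5 um/px -> filled
  expect_true(all(fill_small_holes(small, 200, 0.5) == 1L))

  big <- ring(1000L)   # 250 um^2 -> untouched
  expect_identical(fill_small_holes(big, 200, 0.5), big)

  # background touching the border is never a hole
  open_mask <- matrix(0L, 10, 10)
  open_mask[3:8, 3:8] <- 1L
  expect_identical(fill_small_holes(open_mask, 1e6, 0.5), open_mask)
})

test_that("cleaning operators are idempotent and match the flood-fill oracle", {
  withr::with_seed(42, {
    for (i in seq_len(60)) {
      m <- random_mask(30, 30, p = runif(1, 0.2, 0.6))
      thr <- sample(c(5, 20, 50), 1)
      r1 <- remove_small_components(m, thr, 1)
      expect_identical(r1, oracle_remove_small(m, thr, 1))
      expect_identical(remove_small_components(r1, thr, 1), r1)
      f1 <- fill_small_holes(m, thr, 1)
      expect_identical(f1, oracle_fill_holes(m, thr, 1))
      expect_identical(fill_small_holes(f1, thr, 1), f1)
    }
  })
})

test_that("make_mask_pair composes the stages and validates inputs", {
  blank <- if_image(matrix(0, 64, 64), 0.5)
  mp <- suppressWarnings(make_mask_pair(blank, blank))  # warns per channel
  expect_equal(sum(mp$panck) + sum(mp$cd8), 0L)
  expect_equal(mp$pixel_size_um, 0.5)

  a <- if_image(matrix(runif(64), 8, 8), 0.5)
  b <- if_image(matrix(runif(100), 10, 10), 0.5)
  expect_error(make_mask_pair(a, b), "shape")
  b2 <- if_image(matrix(runif(64), 8, 8), 1.0)
  expect_error(make_mask_pair(a, b2), "pixel size")

  # composed cleaning is idempotent: re-cleaning the masks changes nothing
  p <- generate_patient(tiny_params(seed = 8L))
  mp <- make_mask_pair(p$panck, p$cd8)
  pk2 <- fill_small_holes(remove_small_components(mp$panck, 200, 2.5), 200, 2.5)
  cd2 <- remove_small_components(mp$cd8, 200, 2.5)
  expect_identical(pk2, mp$panck)
  expect_identical(cd2, mp$cd8)
})

test_that("noise-free fully-infiltrated patients put T-cell centers in the PanCK mask", {
  p <- generate_patient(tiny_params(noise_sd = 0, p_in = 1, seed = 12L))
  mp <- make_mask_pair(p$panck, p$cd8)
  centers <- cbind(p$tcells$row, p$tcells$col)
  expect_true(all(mp$panck[centers] == 1L))
})
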