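#' Parameters for the synthetic two-channel IF generator
#'
#' The generator emulates the structure the pipeline exploits: bright,
#' irregular cancer-cell islands on dark stroma in the PanCK channel, and
#' small punctate CD8 blobs whose placement is controlled by a per-patient
#' infiltration probability `p_in` (each T-cell event lands uniformly
#' inside the island union with probability `p_in`, otherwise uniformly in
#' stroma). Outcome labels in [generate_cohort()] are tied to `p_in`, which
#' is the signal the patch classifier is meant to recover.
#'
#' @param canvas_size_px Integer pair, canvas height and width in pixels.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param n_islands Number of cancer islands.
#' @param island_radius_um Length-2 range of island semi-axis radii (um).
#' @param n_tcells Number of CD8 blobs to place.
#' @param tcell_radius_um Radius of one CD8 blob (um). Note the cleaning
#'   stage removes connected areas under 200 um^2, so blobs below ~8 um
#'   radius are treated as noise by the standard pipeline.
#' @param p_in Probability that a T-cell is placed inside the island union.
#' @param signal_level Mean intensity of signal pixels (background is 0).
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (clipped at zero so intensities stay non-negative).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A list of class `synthetic_params`.
#' @export
synthetic_params <- function(canvas_size_px = c(1024L, 1024L),
                             pixel_size_um = 0.5,
                             n_islands = 8L,
                             island_radius_um = c(60, 150),
                             n_tcells = 300L,
                             tcell_radius_um = 4.0,
                             p_in = 0.5,
                             signal_level = 1.0,
                             noise_sd = 0.15,
                             seed = 1L) {
  if (length(canvas_size_px) != 2L || any(canvas_size_px < 1)) {
    abort("`canvas_size_px` must be two positive integers")
  }
  assert_scalar_number(pixel_size_um, "pixel_size_um", lower = 1e-6)
  assert_scalar_number(n_islands, "n_islands", lower = 0)
  if (length(island_radius_um) != 2L || any(island_radius_um <= 0) ||
      diff(island_radius_um) < 0) {
    abort("`island_radius_um` must be an increasing pair of positive radii")
  }
  assert_scalar_number(n_tcells, "n_tcells", lower = 0)
  assert_scalar_number(tcell_radius_um, "tcell_radius_um", lower = 1e-6)
  assert_scalar_number(p_in, "p_in", lower = 0, upper = 1)
  assert_scalar_number(signal_level, "signal_level", lower = 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  assert_scalar_number(seed, "seed")
  structure(list(canvas_size_px = as.integer(canvas_size_px),
                 pixel_size_um = pixel_size_um,
                 n_islands = as.integer(n_islands),
                 island_radius_um = as.numeric(island_radius_um),
                 n_tcells = as.integer(n_tcells),
                 tcell_radius_um = tcell_radius_um,
                 p_in = p_in,
                 signal_level = signal_level,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

#' Desk-scale study parameters for cohort experiments
#'
#' The parameter set used by the package's own cohort experiments, tests
#' and the acceptance script: a 5120 um field at 2.5 um/px, 8 islands of
#' 250-400 um radius (about 8-9% tissue coverage, so the top-10% percentile
#' binarization lands near the island/background boundary and the cleaning
#' operators do real work), and 300 CD8 blobs of 9 um radius (small
#' clusters of labeled cells; a blob this size survives the 200 um^2
#' noise-removal rule, which a single 4 um cell would not). The 2.5 um
#' native pixel keeps the 200 um^2 noise floor at 32 pixels, large enough
#' that binarization speckle never masquerades as CD8 signal.
#'
#' @param ... Overrides forwarded to [synthetic_params()].
#' @return A `synthetic_params` object.
#' @export
synthetic_study_params <- function(...) {
  defaults <- list(canvas_size_px = c(2048L, 2048L),
                   pixel_size_um = 2.5,
                   n_islands = 8L,
                   island_radius_um = c(250, 400),
                   n_tcells = 500L,
                   tcell_radius_um = 9.0,
                   signal_level = 1.0,
                   noise_sd = 0.15)
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_params, args)
}

# Rasterize one irregular island: an ellipse with a low-order sinusoidal
# boundary perturbation, guaranteed star-shaped (hence hole-free).
rasterize_island <- function(nr, nc, cx, cy, a_px, b_px, theta, ph1, ph2) {
  rmax <- max(a_px, b_px) * 1.3
  i0 <- max(1L, floor(cx - rmax)); i1 <- min(nr, ceiling(cx + rmax))
  j0 <- max(1L, floor(cy - rmax)); j1 <- min(nc, ceiling(cy + rmax))
  if (i0 > i1 || j0 > j1) return(NULL)
  di <- (i0:i1) - cx
  dj <- (j0:j1) - cy
  u <- outer(di, dj, function(x, y) x * cos(theta) + y * sin(theta))
  v <- outer(di, dj, function(x, y) -x * sin(theta) + y * cos(theta))
  r <- sqrt((u / a_px)^2 + (v / b_px)^2)
  phi <- atan2(v, u)
  lim <- 1 + 0.15 * sin(3 * phi + ph1) + 0.10 * sin(5 * phi + ph2)
  list(i = i0:i1, j = j0:j1, inside = r <= lim)
}

stamp_discs <- function(mask, centers, radius_px) {
  nr <- nrow(mask); nc <- ncol(mask)
  rad <- ceiling(radius_px)
  for (k in seq_len(nrow(centers))) {
    ci <- centers[k, 1L]; cj <- centers[k, 2L]
    i0 <- max(1L, ci - rad); i1 <- min(nr, ci + rad)
    j0 <- max(1L, cj - rad); j1 <- min(nc, cj + rad)
    dd <- outer((i0:i1) - ci, (j0:j1) - cj, function(x, y) x^2 + y^2)
    blk <- mask[i0:i1, j0:j1, drop = FALSE]
    blk[dd <= radius_px^2] <- 1L
    mask[i0:i1, j0:j1] <- blk
  }
  mask
}

#' Generate one synthetic patient
#'
#' Draws the island union, places T-cell blobs inside or outside it
#' according to `p_in`, and renders both channels with additive Gaussian
#' noise clipped at zero. The exact rasterized island mask and the T-cell
#' centers used for placement are stored on the result so tests can verify
#' placement against the generator's own ground truth.
#'
#' @param params A [synthetic_params()] object.
#' @param patient_id Identifier stored with the patient.
#' @param outcome Optional ground-truth outcome label ("good"/"poor"); set
#'   by [generate_cohort()], `NA` for a standalone patient.
#' @return A list of class `synthetic_patient` with elements `panck`, `cd8`
#'   (both [if_image()]), `island_mask` (binary matrix), `tcells` (tibble of
#'   centers with an `inside` flag), `truth_p_in`, `truth_outcome` and
#'   `patient_id`.
#' @export
#' @examples
#' p <- generate_patient(synthetic_params(canvas_size_px = c(256, 256),
#'                                        n_islands = 3, n_tcells = 50,
#'                                        island_radius_um = c(20, 40)))
#' mean(p$tcells$inside)
generate_patient <- function(params, patient_id = "S1", outcome = NA_character_) {
  stopifnot(inherits(params, "synthetic_params"))
  nr <- params$canvas_size_px[1L]; nc <- params$canvas_size_px[2L]
  psz <- params$pixel_size_um
  if (params$n_islands > 0 &&
      min(nr, nc) * psz < 2 * max(params$island_radius_um)) {
    abort("canvas too small to hold one island at the largest radius")
  }
  if (params$p_in > 0 && params$n_islands == 0L && params$n_tcells > 0L) {
    abort("p_in > 0 requires at least one island to place T cells into")
  }
  with_seed_(params$seed, {
    island_mask <- matrix(0L, nr, nc)
    for (k in seq_len(params$n_islands)) {
      cx <- runif(1, 1, nr); cy <- runif(1, 1, nc)
      ab <- runif(2, params$island_radius_um[1L],
                  params$island_radius_um[2L]) / psz
      isl <- rasterize_island(nr, nc, cx, cy, ab[1L], ab[2L],
                              runif(1, 0, pi), runif(1, 0, 2 * pi),
                              runif(1, 0, 2 * pi))
      if (!is.null(isl)) {
        blk <- island_mask[isl$i, isl$j, drop = FALSE]
        blk[isl$inside] <- 1L
        island_mask[isl$i, isl$j] <- blk
      }
    }

    n_t <- params$n_tcells
    inside_px <- which(island_mask == 1L)
    stroma_px <- which(island_mask == 0L)
    inside <- logical(0)
    centers <- matrix(integer(0), 0, 2)
    if (n_t > 0) {
      inside <- runif(n_t) < params$p_in
      if (any(inside) && length(inside_px) == 0L) {
        abort("no island pixels available to place T cells inside")
      }
      pick <- integer(n_t)
      pick[inside] <- sample(inside_px, sum(inside), replace = TRUE)
      pick[!inside] <- sample(stroma_px, sum(!inside), replace = TRUE)
      centers <- cbind(((pick - 1L) %% nr) + 1L, ((pick - 1L) %/% nr) + 1L)
    }
    cd8_mask <- stamp_discs(matrix(0L, nr, nc), centers,
                            params$tcell_radius_um / psz)

    render <- function(mask) {
      px <- params$signal_level * mask
      if (params$noise_sd > 0) {
        px <- px + rnorm(length(px), sd = params$noise_sd)
      }
      matrix(pmax(px, 0), nr, nc)
    }
    panck_px <- render(island_mask)
    cd8_px <- render(cd8_mask)

    structure(list(
      panck = if_image(panck_px, psz),
      cd8 = if_image(cd8_px, psz),
      island_mask = island_mask,
      tcells = tibble::tibble(row = centers[, 1L], col = centers[, 2L],
                              inside = inside),
      truth_p_in = params$p_in,
      truth_outcome = outcome,
      patient_id = patient_id,
      params = params), class = "synthetic_patient")
  })
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf("<synthetic_patient> %s: %d x %d px, p_in = %.2f, outcome = %s\n",
              x$patient_id, nrow(x$panck$pixels), ncol(x$panck$pixels),
              x$truth_p_in, x$truth_outcome))
  invisible(x)
}

#' Generate a labeled synthetic cohort
#'
#' Good-outcome patients draw their infiltration `p_in` uniformly from
#' `good_p_in_range`, poor-outcome patients from `poor_p_in_range`; the
#' default group sizes (15 good, 9 poor) mirror the composition of a
#' typical small TNBC training cohort. Per-patient seeds are derived
#' deterministically from `seed`, so the cohort is reproducible and
#' patients could be generated independently.
#'
#' @param n_good,n_poor Non-negative patient counts per outcome group.
#' @param good_p_in_range,poor_p_in_range `p_in` sampling ranges in `[0,1]`.
#'   A warning is issued when the ranges overlap, since the cohorts are then
#'   not separable by construction.
#' @param base A [synthetic_params()] template supplying everything but
#'   `p_in` and `seed`.
#' @param seed Master seed for the cohort.
#' @param id_prefix Prefix for generated patient ids.
#' @return A tibble with one row per patient: `patient_id`, `outcome`,
#'   `truth_p_in`, `seed` and a `patient` list-column of
#'   `synthetic_patient` objects.
#' @export
generate_cohort <- function(n_good = 15L, n_poor = 9L,
                            good_p_in_range = c(0.6, 0.9),
                            poor_p_in_range = c(0.0, 0.2),
                            base = synthetic_study_params(),
                            seed = 1L, id_prefix = "S") {
  assert_scalar_number(n_good, "n_good", lower = 0)
  assert_scalar_number(n_poor, "n_poor", lower = 0)
  for (rg in list(good_p_in_range, poor_p_in_range)) {
    if (length(rg) != 2L || any(rg < 0) || any(rg > 1) || diff(rg) < 0) {
      abort("p_in ranges must be increasing pairs within [0, 1]")
    }
  }
  if (n_good > 0 && n_poor > 0 && good_p_in_range[1L] <= poor_p_in_range[2L]) {
    warn("good and poor p_in ranges overlap; the cohorts will not be separable")
  }
  plan <- cohort_plan_(n_good, n_poor, good_p_in_range, poor_p_in_range,
                       seed, id_prefix)
  if (nrow(plan) == 0L) {
    return(dplyr::mutate(plan, patient = list()))
  }
  patients <- purrr::pmap(plan[c("patient_id", "outcome", "truth_p_in", "seed")],
                          function(patient_id, outcome, truth_p_in, seed) {
    pars <- base
    pars$p_in <- truth_p_in
    pars$seed <- as.integer(seed)
    generate_patient(pars, patient_id = patient_id, outcome = outcome)
  })
  dplyr::mutate(plan, patient = patients)
}

# Deterministic cohort layout: ids, outcomes, p_in draws and child seeds.
cohort_plan_ <- function(n_good, n_poor, good_p_in_range, poor_p_in_range,
                         seed, id_prefix = "S") {
  n <- as.integer(n_good + n_poor)
  if (n == 0L) {
    return(tibble::tibble(patient_id = character(), outcome = character(),
                          truth_p_in = numeric(), seed = integer()))
  }
  outcome <- rep(c("good", "poor"), c(n_good, n_poor))
  p_in <- with_seed_(seed, c(
    runif(n_good, good_p_in_range[1L], good_p_in_range[2L]),
    runif(n_poor, poor_p_in_range[1L], poor_p_in_range[2L])))
  child <- derive_child_seeds(seed, n)
  ids <- sprintf("%s%s%02d", id_prefix, ifelse(outcome == "good", "G", "P"),
                 c(seq_len(n_good), seq_len(n_poor)))
  tibble::tibble(patient_id = ids, outcome = outcome, truth_p_in = p_in,
                 seed = as.integer(child))
}

#' Generate a deliberately heterogeneous patient
#'
#' Splices the left and right halves (by image columns) of two patients
#' generated with different infiltration levels. Used for the subsampling
#' robustness analysis: contiguous half-sections of such a tumor carry
#' contradictory signal, as happens in spatially heterogeneous tumors.
#'
#' @param params Template [synthetic_params()].
#' @param p_in_left,p_in_right Infiltration for the two halves.
#' @inheritParams generate_patient
#' @return A `synthetic_patient`; `truth_p_in` is the mean of the halves.
#' @export
generate_heterogeneous_patient <- function(params, p_in_left, p_in_right,
                                           patient_id = "HET1",
                                           outcome = NA_character_) {
  seeds <- derive_child_seeds(params$seed, 2L)
  halves <- purrr::map2(c(p_in_left, p_in_right), seeds, function(p, s) {
    pars <- params
    pars$p_in <- p
    pars$seed <- as.integer(s)
    generate_patient(pars, patient_id = patient_id, outcome = outcome)
  })
  nc <- ncol(halves[[1L]]$panck$pixels)
  left <- seq_len(nc %/% 2L)
  right <- setdiff(seq_len(nc), left)
  splice <- function(f) {
    m <- f(halves[[1L]])
    m[, right] <- f(halves[[2L]])[, right]
    m
  }
  out <- halves[[1L]]
  out$panck <- if_image(splice(function(p) p$panck$pixels), params$pixel_size_um)
  out$cd8 <- if_image(splice(function(p) p$cd8$pixels), params$pixel_size_um)
  out$island_mask <- splice(function(p) p$island_mask)
  keep1 <- halves[[1L]]$tcells$col <= max(left)
  keep2 <- halves[[2L]]$tcells$col > max(left)
  out$tcells <- dplyr::bind_rows(halves[[1L]]$tcells[keep1, ],
                                 halves[[2L]]$tcells[keep2, ])
  out$truth_p_in <- mean(c(p_in_left, p_in_right))
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes one grayscale TIFF pair per patient plus a tab-separated cohort
#' manifest (`manifest.tsv`) with columns `patient_id`, `panck_path`,
#' `cd8_path`, `pixel_size_um`, `outcome`, `grade`, `nodal_status` (the
#' clinical columns are `NA` for synthetic patients).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::pmap(list(cohort$patient_id, cohort$outcome, cohort$patient),
                      function(id, oc, pat) {
    pp <- file.path(dir, paste0(id, "_panck.tif"))
    cp <- file.path(dir, paste0(id, "_cd8.tif"))
    write_if_image(pat$panck, pp)
    write_if_image(pat$cd8, cp)
    tibble::tibble(patient_id = id, panck_path = pp, cd8_path = cp,
                   pixel_size_um = pat$panck$pixel_size_um, outcome = oc,
                   grade = "NA", nodal_status = "NA")
  })
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
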