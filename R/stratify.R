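#' Aggregate patch predictions into per-patient good-patch fractions
#'
#' For each patient, computes the fraction of evaluated patches labeled
#' "good" (the holdout fraction during threshold selection; the same
#' statistic on a test patient's full patch set at prediction time).
#'
#' @param predictions Prediction tibble from [predict_patches()].
#' @return A tibble: `patient_id`, `n_patches_evaluated`, `r_good`.
#' @export
score_patients <- function(predictions) {
  if (!all(c("patient_id", "label") %in% names(predictions))) {
    abort("`predictions` must have `patient_id` and `label` columns")
  }
  predictions |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_patches_evaluated = dplyr::n(),
                     r_good = mean(.data$label == "good"),
                     .groups = "drop")
}

# Exhaustive threshold scan shared by scan_rc() and
# best_cutoff_accuracy(). The accuracy of the rule "predict poor iff
# value < cutoff" (or > for direction "high_is_poor") is piecewise
# constant between consecutive distinct values, so evaluating one
# candidate per segment — midpoints, plus the domain endpoints, which can
# realize classifications no interior midpoint reaches (e.g. "everyone
# good" at cutoff 0 when some score is exactly 0) — is an exact scan over
# the whole domain. `bounds` restricts cut-offs (e.g. [0, 1] for the
# good-patch fraction); when NULL the domain is unbounded and one
# candidate beyond each extreme value is added. Returns the candidate
# table and the widest maximal-accuracy run as an interval.
scan_threshold_ <- function(values, is_poor, direction = "low_is_poor",
                            bounds = NULL) {
  stopifnot(length(values) == length(is_poor))
  if (length(unique(is_poor)) < 2L) {
    abort("threshold scan needs at least one patient per outcome group")
  }
  v <- sort(unique(values))
  if (is.null(bounds)) {
    breaks <- c(v[1L] - 1, v, v[length(v)] + 1)
    endpoints <- numeric(0)
  } else {
    breaks <- unique(c(bounds[1L], v[v > bounds[1L] & v < bounds[2L]],
                       bounds[2L]))
    endpoints <- bounds
  }
  # candidates with the interval of cut-offs each one represents
  cand <- tibble::tibble(
    cutoff = c(endpoints[endpoints == breaks[1L]],
               (head(breaks, -1L) + breaks[-1L]) / 2,
               endpoints[endpoints == breaks[length(breaks)]]),
    lo = c(endpoints[endpoints == breaks[1L]], head(breaks, -1L),
           endpoints[endpoints == breaks[length(breaks)]]),
    hi = c(endpoints[endpoints == breaks[1L]], breaks[-1L],
           endpoints[endpoints == breaks[length(breaks)]]))
  cand <- cand[order(cand$cutoff), ]
  cand$accuracy <- vapply(cand$cutoff, function(rc) {
    pred_poor <- if (direction == "low_is_poor") values < rc else values > rc
    mean(pred_poor == is_poor)
  }, numeric(1))
  best <- max(cand$accuracy)
  is_best <- abs(cand$accuracy - best) < 1e-12
  runs <- rle(is_best)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  widths <- cand$hi[ends] - cand$lo[starts]
  widths[!runs$values] <- -Inf
  top <- which.max(widths)
  list(candidates = cand[, c("cutoff", "accuracy")],
       max_accuracy = best,
       lo = cand$lo[starts[top]], hi = cand$hi[ends[top]])
}

#' Scan the patient-level cut-off Rc
#'
#' Evaluates the stratification rule "predict poor outcome iff the
#' good-patch fraction is below Rc" at every cut point where its accuracy
#' can change — the midpoints between consecutive distinct scores plus
#' the domain endpoints 0 and 1 — and returns the widest maximal interval
#' of cut-offs attaining the maximum accuracy.
#'
#' @param scores Patient score tibble from [score_patients()].
#' @param truths Tibble with `patient_id` and true `outcome`
#'   ("good"/"poor").
#' @return An object of class `threshold_scan`: candidate table,
#'   `max_accuracy` and the optimal open interval `(lo, hi)`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
scan_rc <- function(scores, truths) {
  df <- dplyr::inner_join(scores, truths, by = "patient_id")
  if (nrow(df) < nrow(scores)) {
    warn("some scored patients have no truth label and were dropped")
  }
  res <- scan_threshold_(df$r_good, df$outcome == "poor", "low_is_poor",
                         bounds = c(0, 1))
  structure(c(res, list(n_patients = nrow(df))), class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold_scan> %d patients; max accuracy %.3f on Rc in (%.3g, %.3g)\n",
    x$n_patients, x$max_accuracy, x$lo, x$hi))
  invisible(x)
}

#' @rdname tilstrat-tidiers
#' @export
tidy.threshold_scan <- function(x, ...) x$candidates

#' @rdname tilstrat-tidiers
#' @export
glance.threshold_scan <- function(x, ...) {
  tibble::tibble(max_accuracy = x$max_accuracy, lo = x$lo, hi = x$hi,
                 n_patients = x$n_patients)
}

#' Select the final cut-off from repeated realizations
#'
#' Each realization (a fresh holdout split plus fresh classifier training)
#' contributes its optimal cut-off interval. The final Rc is the mean of
#' the interval midpoints over the realizations that attain the best
#' accuracy observed across realizations; realizations that fail to reach
#' it (e.g. no perfect separation when others achieve one) are excluded
#' from the average.
#'
#' @param scans List of [scan_rc()] results, one per realization.
#' @return An object of class `rc_selection` with per-realization
#'   intervals, the `used` flags and `rc_final`.
#' @export
select_rc <- function(scans) {
  if (length(scans) == 0L) abort("need at least one realization")
  stopifnot(all(vapply(scans, inherits, logical(1), "threshold_scan")))
  per <- dplyr::bind_rows(lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    tibble::tibble(realization = i, lo = s$lo, hi = s$hi,
                   max_accuracy = s$max_accuracy)
  }))
  best <- max(per$max_accuracy)
  per$used <- abs(per$max_accuracy - best) < 1e-12
  rc_final <- mean((per$lo[per$used] + per$hi[per$used]) / 2)
  structure(list(realizations = per, rc_final = rc_final,
                 best_accuracy = best), class = "rc_selection")
}

#' @export
print.rc_selection <- function(x, ...) {
  cat(sprintf(
    "<rc_selection> Rc = %.4f from %d/%d realizations at accuracy %.3f\n",
    x$rc_final, sum(x$realizations$used), nrow(x$realizations),
    x$best_accuracy))
  invisible(x)
}

#' @rdname tilstrat-tidiers
#' @export
tidy.rc_selection <- function(x, ...) x$realizations

#' @rdname tilstrat-tidiers
#' @export
glance.rc_selection <- function(x, ...) {
  tibble::tibble(rc_final = x$rc_final, best_accuracy = x$best_accuracy,
                 n_realizations = nrow(x$realizations),
                 n_used = sum(x$realizations$used))
}

#' Predict patient outcomes from good-patch fractions
#'
#' A patient is predicted "poor" iff `r_good < rc`; equality is resolved
#' to "good" (the stratification rule's two strict inequalities leave the
#' boundary undefined, so the tie rule is documented here).
#'
#' @param scores Patient score tibble.
#' @param rc Cut-off in (0, 1).
#' @return `scores` with a `predicted` column appended.
#' @export
predict_outcome <- function(scores, rc) {
  assert_scalar_number(rc, "rc", lower = 0, upper = 1)
  dplyr::mutate(scores,
                predicted = ifelse(.data$r_good < rc, "poor", "good"))
}

#' Confusion-matrix summary with poor outcome as the positive class
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (poor = positive).
#' @return A one-row tibble of class `confusion_summary` with the counts
#'   and derived `recall`, `precision` and `accuracy`.
#' @export
#' @examples
#' confusion_summary(tp = 6, fp = 6, fn = 0, tn = 17)
confusion_summary <- function(tp, fp, fn, tn) {
  for (v in c(tp, fp, fn, tn)) assert_scalar_number(v, "count", lower = 0)
  total <- tp + fp + fn + tn
  out <- tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    accuracy = if (total > 0) (tp + tn) / total else NA_real_)
  class(out) <- c("confusion_summary", class(out))
  out
}

#' Evaluate predicted against true outcomes
#'
#' @param predictions Tibble with `patient_id` and `predicted`.
#' @param truths Tibble with `patient_id` and `outcome`.
#' @return A [confusion_summary()].
#' @export
evaluate_outcomes <- function(predictions, truths) {
  df <- dplyr::inner_join(predictions, truths, by = "patient_id")
  if (nrow(df) != nrow(predictions)) {
    abort("prediction/truth patient ids do not align")
  }
  bad <- setdiff(unique(c(df$predicted, df$outcome)), c("good", "poor"))
  if (length(bad)) {
    abort(paste("unknown outcome labels:", paste(bad, collapse = ", ")))
  }
  confusion_summary(
    tp = sum(df$predicted == "poor" & df$outcome == "poor"),
    fp = sum(df$predicted == "poor" & df$outcome == "good"),
    fn = sum(df$predicted == "good" & df$outcome == "poor"),
    tn = sum(df$predicted == "good" & df$outcome == "good"))
}

#' Prediction stability under tumor-section subsampling
#'
#' Emulates having only part of a tumor section: either contiguous blocks
#' of the tile grid (`mode = "contiguous"`, e.g. the two halves of the
#' section for `fraction = 0.5`) or repeated random subsets of the patches
#' (`mode = "random"`). Each subset is scored and stratified at `rc`, and
#' compared with the full-section prediction. Heterogeneous tumors can
#' yield discordant contiguous halves even when random subsets agree.
#'
#' @param patches Filtered patch tibble of a single patient (>= 4 patches).
#' @param model A trained [patch_cnn].
#' @param rc Patient-level cut-off.
#' @param fraction Fraction of the section to keep (e.g. 0.5 or 0.25).
#' @param mode `"contiguous"` (column-ordered blocks of the tile grid; one
#'   repeat per block) or `"random"` (`n_repeats` draws without
#'   replacement).
#' @param n_repeats Number of random repeats (ignored for contiguous mode).
#' @param seed Seed for the random mode.
#' @return A tibble with one row per subset: `repeat_id`, `mode`,
#'   `n_patches`, `r_good`, `predicted`, `full_predicted`, `agree`; the
#'   agreement rate is `mean(agree)`.
#' @export
subsample_robustness <- function(patches, model, rc, fraction = 0.5,
                                 mode = c("contiguous", "random"),
                                 n_repeats = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1]")
  }
  if (length(unique(patches$patient_id)) != 1L) {
    abort("`patches` must belong to a single patient")
  }
  if (nrow(patches) < 4L) abort("need at least 4 patches")
  full_pred <- stratify_subset_(patches, model, rc)
  subsets <- if (fraction == 1) {
    list(seq_len(nrow(patches)))
  } else if (mode == "contiguous") {
    ord <- order(patches$col, patches$row)
    n_blocks <- max(2L, round(1 / fraction))
    unname(split(ord, cut(seq_along(ord), n_blocks, labels = FALSE)))
  } else {
    n_keep <- max(1L, floor(fraction * nrow(patches)))
    with_seed_(seed, lapply(seq_len(n_repeats), function(i) {
      sample.int(nrow(patches), n_keep)
    }))
  }
  rows <- lapply(seq_along(subsets), function(i) {
    sub <- patches[subsets[[i]], ]
    pred <- stratify_subset_(sub, model, rc)
    tibble::tibble(repeat_id = i, mode = mode, n_patches = nrow(sub),
                   r_good = pred$r_good, predicted = pred$predicted)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(full_predicted = full_pred$predicted,
                  agree = .data$predicted == full_pred$predicted)
}

stratify_subset_ <- function(patches, model, rc) {
  scores <- score_patients(predict_patches(model, patches))
  predict_outcome(scores, rc)
}
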