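#' Training configuration for the patch classifier
#'
#' Defaults are the reference training schedule: RMSProp with learning
#' rate 5e-4 and weight decay 0.01, learning rate multiplied by 0.25 every
#' 10 epochs, mini-batches of 20 patches, 100 epochs, an 80/20 per-patient
#' train/holdout split, 3 extra copies of each minority-class patch, and a
#' 0.5 probability cutoff for calling a patch "poor". That schedule assumes
#' tens of thousands of RMSProp updates; small synthetic runs with only a
#' few hundred updates need a proportionally larger learning rate (see the
#' methods vignette).
#'
#' @param learning_rate,weight_decay,lr_factor,factor_epoch RMSProp
#'   schedule: base learning rate, L2 weight decay, decay factor, and the
#'   epoch interval at which the learning rate is multiplied by
#'   `lr_factor`.
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs.
#' @param extra_copies_minority Extra copies of each minority-class patch
#'   added for class balancing.
#' @param train_frac Per-patient fraction of patches used for training.
#' @param patch_cutoff Probability cutoff: a patch is labeled "poor" iff
#'   `prob_poor > patch_cutoff`.
#' @param seed Seed controlling weight initialization and epoch shuffles.
#' @param architecture `"small_cnn"` (3 conv blocks, ~3.7k weights) or
#'   `"deepflow_like"` (same topology, wider: ~40k weights).
#' @param rmsprop_rho Decay of the RMSProp squared-gradient accumulator.
#' @param rmsprop_eps Stabilizer added to the RMSProp denominator. Larger
#'   values damp the first updates while the accumulator is still near
#'   zero, which matters for short runs (see [study_train_config()]).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 5e-4, weight_decay = 0.01,
                         lr_factor = 0.25, factor_epoch = 10L,
                         batch_size = 20L, epochs = 100L,
                         extra_copies_minority = 3L, train_frac = 0.8,
                         patch_cutoff = 0.5, seed = 1L,
                         architecture = c("small_cnn", "deepflow_like"),
                         rmsprop_rho = 0.9, rmsprop_eps = 1e-8) {
  architecture <- match.arg(architecture)
  assert_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  assert_scalar_number(weight_decay, "weight_decay", lower = 0)
  assert_scalar_number(lr_factor, "lr_factor", lower = 1e-12, upper = 1)
  assert_scalar_number(factor_epoch, "factor_epoch", lower = 1)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  assert_scalar_number(epochs, "epochs", lower = 1)
  assert_scalar_number(extra_copies_minority, "extra_copies_minority",
                       lower = 0)
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must be strictly between 0 and 1")
  }
  if (patch_cutoff <= 0 || patch_cutoff >= 1) {
    abort("`patch_cutoff` must be strictly between 0 and 1")
  }
  assert_scalar_number(rmsprop_rho, "rmsprop_rho", lower = 0, upper = 1)
  assert_scalar_number(rmsprop_eps, "rmsprop_eps", lower = 0)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 lr_factor = lr_factor, factor_epoch = as.integer(factor_epoch),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 extra_copies_minority = as.integer(extra_copies_minority),
                 train_frac = train_frac, patch_cutoff = patch_cutoff,
                 seed = as.integer(seed), architecture = architecture,
                 rmsprop_rho = rmsprop_rho, rmsprop_eps = rmsprop_eps),
            class = "train_config")
}

arch_channels <- function(architecture) {
  switch(architecture,
         small_cnn = c(8L, 16L, 16L),
         deepflow_like = c(16L, 32L, 64L),
         abort(sprintf("unknown architecture '%s'", architecture)))
}

#' Split patches into training and holdout sets per patient
#'
#' Within each patient, `round(train_frac * n)` patches are sampled into
#' the training set and the remainder held out; the union of the two sets
#' is exactly the input. Patients whose holdout ends up empty (e.g. a
#' single-patch patient) trigger a warning because no holdout good-patch
#' fraction can be computed for them.
#'
#' @param patches Patch tibble (must carry `patient_id`).
#' @param train_frac Training fraction per patient.
#' @param seed Split seed.
#' @return A list with tibbles `train` and `holdout`.
#' @export
split_train_holdout <- function(patches, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) {
    abort("`train_frac` must be strictly between 0 and 1")
  }
  if (nrow(patches) == 0L) abort("no patches to split")
  with_seed_(seed, {
    idx <- split(seq_len(nrow(patches)), patches$patient_id)
    train_idx <- integer(0)
    empty_holdout <- character(0)
    for (pid in names(idx)) {
      rows <- idx[[pid]]
      n_train <- round(train_frac * length(rows))
      if (n_train == length(rows)) empty_holdout <- c(empty_holdout, pid)
      train_idx <- c(train_idx, sample(rows, n_train))
    }
    if (length(empty_holdout)) {
      warn(paste("no holdout patches for patient(s):",
                 paste(empty_holdout, collapse = ", ")))
    }
    train_idx <- sort(train_idx)
    list(train = patches[train_idx, ],
         holdout = patches[setdiff(seq_len(nrow(patches)), train_idx), ])
  })
}

#' Balance classes by replicating minority-class patches
#'
#' Appends `extra_copies` additional copies of every patch of the
#' less-frequent outcome class (so each appears `extra_copies + 1` times)
#' and shuffles the result deterministically. Replication changes
#' multiplicities only, never the set of distinct patches.
#'
#' @param patches Patch tibble with an `outcome` column ("good"/"poor").
#' @param extra_copies Number of extra copies (default 3).
#' @param seed Shuffle seed.
#' @return The balanced, shuffled patch tibble.
#' @export
balance_by_replication <- function(patches, extra_copies = 3L, seed = 1L) {
  assert_scalar_number(extra_copies, "extra_copies", lower = 0)
  if (!"outcome" %in% names(patches)) {
    abort("`patches` must carry an `outcome` column")
  }
  counts <- table(patches$outcome)
  if (length(counts) < 2L) {
    warn("only one outcome class present; returning patches unchanged")
    return(patches)
  }
  if (extra_copies > 0) {
    minority <- names(counts)[which.min(counts)]
    extra <- patches[rep(which(patches$outcome == minority), extra_copies), ]
    patches <- dplyr::bind_rows(patches, extra)
  }
  with_seed_(seed, patches[sample.int(nrow(patches)), ])
}

# Pack patch list-columns into the flat N x 8192 layout the CNN consumes:
# per row, the PanCK plane then the CD8 plane, each column-major.
pack_patches <- function(patches) {
  n <- nrow(patches)
  X <- matrix(0, n, 2L * 64L * 64L)
  for (r in seq_len(n)) {
    pk <- patches$panck[[r]]
    cd <- patches$cd8[[r]]
    if (!identical(dim(pk), c(64L, 64L)) || !identical(dim(cd), c(64L, 64L))) {
      abort("patches must be 64 x 64 to be classified")
    }
    X[r, ] <- c(as.numeric(pk), as.numeric(cd))
  }
  X
}

init_weights <- function(channels, seed) {
  cin <- c(2L, channels[1L], channels[2L])
  with_seed_(seed, {
    w <- numeric(0)
    for (l in 1:3) {
      fan_in <- cin[l] * 9L
      w <- c(w, rnorm(channels[l] * fan_in, sd = sqrt(2 / fan_in)),
             numeric(channels[l]))
    }
    c(w, rnorm(channels[3L], sd = sqrt(1 / channels[3L])), 0)
  })
}

#' Train the patch classifier
#'
#' Trains a small convolutional network (3x3 conv + ReLU + 2x2 maxpool,
#' three blocks, global average pooling, linear head with sigmoid) on
#' two-channel binary 64 x 64 patches with binary cross-entropy loss and
#' mini-batch RMSProp. Class encoding: poor = 1, good = 0. Training is
#' deterministic given `cfg$seed` (all randomness is drawn from R's RNG;
#' the compiled training loop is single-threaded).
#'
#' @param patches Patch tibble with an `outcome` column; normally the
#'   output of [balance_by_replication()].
#' @param cfg A [train_config()].
#' @return An object of class `patch_cnn` with the learned weights, the
#'   configuration, per-epoch loss/accuracy trace and class counts.
#'   Supports [predict()], [tidy()], [glance()] and [autoplot()].
#' @export
train_patch_classifier <- function(patches, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (!"outcome" %in% names(patches)) {
    abort("`patches` must carry an `outcome` column")
  }
  classes <- unique(patches$outcome)
  if (length(classes) < 2L) {
    abort("training data must contain both outcome classes")
  }
  y <- as.numeric(patches$outcome == "poor")
  X <- pack_patches(patches)
  channels <- arch_channels(cfg$architecture)
  w0 <- init_weights(channels, cfg$seed)
  n <- nrow(X)
  order <- with_seed_(cfg$seed + 1L, {
    t(vapply(seq_len(cfg$epochs), function(e) sample.int(n), integer(n)))
  })
  fit <- cnn_train_cpp(X, y, w0, channels, order,
                       lr = cfg$learning_rate, lr_factor = cfg$lr_factor,
                       factor_epoch = cfg$factor_epoch,
                       weight_decay = cfg$weight_decay,
                       batch_size = cfg$batch_size, rho = cfg$rmsprop_rho,
                       eps = cfg$rmsprop_eps)
  structure(list(weights = fit$weights, channels = channels, cfg = cfg,
                 trace = tibble::tibble(epoch = seq_len(cfg$epochs),
                                        loss = fit$epoch_loss,
                                        accuracy = fit$epoch_accuracy),
                 n_train = n,
                 class_counts = c(good = sum(y == 0), poor = sum(y == 1))),
            class = "patch_cnn")
}

#' @export
print.patch_cnn <- function(x, ...) {
  cat(sprintf(
    "<patch_cnn> %s (%d weights), trained %d epochs on %d patches (%d good / %d poor)\n",
    x$cfg$architecture, length(x$weights), x$cfg$epochs, x$n_train,
    x$class_counts[["good"]], x$class_counts[["poor"]]))
  cat(sprintf("  final training accuracy %.3f, loss %.4f\n",
              x$trace$accuracy[nrow(x$trace)], x$trace$loss[nrow(x$trace)]))
  invisible(x)
}

#' @export
predict.patch_cnn <- function(object, patches, ...) {
  cnn_predict_cpp(pack_patches(patches), object$weights, object$channels)
}

#' @rdname tilstrat-tidiers
#' @export
tidy.patch_cnn <- function(x, ...) x$trace

#' @rdname tilstrat-tidiers
#' @export
glance.patch_cnn <- function(x, ...) {
  tibble::tibble(architecture = x$cfg$architecture,
                 n_weights = length(x$weights), epochs = x$cfg$epochs,
                 n_train = x$n_train,
                 final_loss = x$trace$loss[nrow(x$trace)],
                 final_accuracy = x$trace$accuracy[nrow(x$trace)])
}

#' Save / load a trained patch classifier
#'
#' The checkpoint is a single JSON file holding the flat weight vector at
#' full double precision (round-trip error at most one unit in the last
#' place) together with the architecture, training configuration and
#' class counts, so a model can be inspected with any JSON tool.
#'
#' @param model A [patch_cnn].
#' @param path Checkpoint file path.
#' @return `save_patch_cnn()` returns `path` invisibly; `load_patch_cnn()`
#'   returns the restored `patch_cnn`.
#' @export
save_patch_cnn <- function(model, path) {
  stopifnot(inherits(model, "patch_cnn"))
  obj <- list(weights = model$weights, channels = model$channels,
              cfg = unclass(model$cfg), trace = model$trace,
              n_train = model$n_train,
              class_counts = as.list(model$class_counts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_patch_cnn
#' @export
load_patch_cnn <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such checkpoint: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(train_config, obj$cfg[setdiff(names(obj$cfg), NULL)])
  structure(list(weights = as.numeric(obj$weights),
                 channels = as.integer(obj$channels), cfg = cfg,
                 trace = tibble::as_tibble(obj$trace),
                 n_train = obj$n_train,
                 class_counts = unlist(obj$class_counts)),
            class = "patch_cnn")
}

#' Classify patches
#'
#' Applies a trained [patch_cnn] to a patch tibble. A patch is labeled
#' "poor" iff its predicted probability strictly exceeds `patch_cutoff`
#' (a probability of exactly the cutoff is "good").
#'
#' @param model A `patch_cnn`.
#' @param patches Patch tibble.
#' @param patch_cutoff Probability cutoff; defaults to the model's
#'   training configuration.
#' @return A tibble: `patient_id`, `row`, `col`, `prob_poor`, `label`.
#' @export
predict_patches <- function(model, patches, patch_cutoff = NULL) {
  stopifnot(inherits(model, "patch_cnn"))
  if (is.null(patch_cutoff)) patch_cutoff <- model$cfg$patch_cutoff
  assert_scalar_number(patch_cutoff, "patch_cutoff", lower = 0, upper = 1)
  if (nrow(patches) == 0L) {
    return(tibble::tibble(patient_id = character(), row = integer(),
                          col = integer(), prob_poor = numeric(),
                          label = character()))
  }
  prob <- predict(model, patches)
  tibble::tibble(patient_id = patches$patient_id, row = patches$row,
                 col = patches$col, prob_poor = prob,
                 label = ifelse(prob > patch_cutoff, "poor", "good"))
}
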