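# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb a user's stream.
with_seed_ <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-patient child seeds below 2^31.
derive_child_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower ||
      x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                  format(lower), format(upper)))
  }
  invisible(x)
}

assert_binary_matrix <- function(m, name = "mask") {
  if (!is.matrix(m) || !all(m %in% c(0, 1))) {
    abort(sprintf("`%s` must be a binary (0/1) matrix", name))
  }
  invisible(m)
}

as_binary_int <- function(m) {
  storage.mode(m) <- "integer"
  m
}
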