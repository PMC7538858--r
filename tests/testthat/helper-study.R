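# The full synthetic study is the most expensive fixture; several
# acceptance checks reuse the seed-1 run (its model, cut-off and
# parameters), so it is computed once per test session.
study_cache <- new.env(parent = emptyenv())

get_study <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- suppressWarnings(run_synthetic_study(seed = seed))
  }
  study_cache[[key]]
}
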