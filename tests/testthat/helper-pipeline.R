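# Multi-seed pipeline runs are expensive; run them once per session and
# share the results across test files.
pipeline_runs <- function(seeds = 1:5) {
  key <- paste0("pipeline_", paste(seeds, collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    two_step <- lapply(seeds, function(s) two_step_experiment(seed = s))
    headonly <- lapply(seeds, function(s)
      two_step_experiment(seed = s, pretraining = "none"))
    .fixture_env[[key]] <- list(two_step = two_step, headonly = headonly)
  }
  .fixture_env[[key]]
}
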