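# The phantom and cohort experiments are deterministic at their default
# specs; compute each once per test run and share across test files.

.exp_cache <- new.env(parent = emptyenv())

cached_phantom_experiment <- function() {
  if (is.null(.exp_cache$phantom))
    .exp_cache$phantom <- run_phantom_experiment()
  .exp_cache$phantom
}

cached_cohort_experiment <- function() {
  if (is.null(.exp_cache$cohort))
    .exp_cache$cohort <- run_cohort_experiment(methods = c("rr", "ar20"))
  .exp_cache$cohort
}
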