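# Cached synthetic cohorts and pipeline runs shared across test files so
# the expensive fixtures are built once per test session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# Small cohort for unit-level checks.
unit_cohort <- function() {
  cached("unit_cohort", function()
    generate_cohort(simulation_params(n_samples = 120, seed = 7)))
}

# The standing benchmark cohort: n = 400, delta = 3, beta_sig = 2,
# theta = 1, seed 7 (the generator defaults).
benchmark_cohort <- function() {
  cached("benchmark_cohort", function()
    generate_cohort(simulation_params(seed = 7)))
}

benchmark_config <- function(seed = 7) {
  run_config(seed = seed, n_top = 1000)
}

benchmark_result <- function() {
  cached("benchmark_result", function() {
    co <- benchmark_cohort()
    suppressWarnings(run_pipeline(co$expr, co$gene_sets, co$clinical,
                                  benchmark_config()))
  })
}

signature_genes <- function(cohort) {
  gm <- cohort$truth$gene_module
  names(gm)[!gm %in% c("background", "checkpoint")]
}
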