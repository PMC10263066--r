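# Shared fixtures, memoised so expensive cohorts are simulated and gated
# once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_tree <- function() {
  if (is.null(.fixture_env$tree)) {
    .fixture_env$tree <- load_gating_config()
  }
  .fixture_env$tree
}

# mini cohort, gated
mini_fixture <- function(seed = 101) {
  key <- paste0("mini_", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- simulate_cohort(default_cohort_spec("mini"), seed = seed)
    counts <- gate_cohort(coh$samples, default_tree())
    .fixture_env[[key]] <- list(coh = coh, counts = counts)
  }
  .fixture_env[[key]]
}

study_fixture <- function(template, seed = 101) {
  key <- paste0(template, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    coh <- simulate_cohort(default_cohort_spec(template), seed = seed)
    counts <- gate_cohort(coh$samples, default_tree())
    .fixture_env[[key]] <- list(coh = coh, counts = counts)
  }
  .fixture_env[[key]]
}

# small synthetic centroid/expression fixtures for the transcriptome tests
random_expression <- function(n_genes, n_samples, seed) {
  withr_seed <- seed
  set.seed(withr_seed)
  m <- matrix(2^stats::rnorm(n_genes * n_samples, 4, 1),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}
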