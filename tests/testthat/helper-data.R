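# Small shared fixtures, generated once per test session.

.fixture_env <- new.env(parent = emptyenv())

# A modest cohort used by several test files (segmentation is the costly
# stage, so it is shared rather than regenerated).
shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    sim <- simulate_cohort(sim_config(n_subjects = 40, days = 3, seed = 42))
    .fixture_env$sim <- sim
    .fixture_env$cohort <- build_cohort(sim$epochs, sim$covariates,
                                        sim$capacity, seg_config(seed = 42))
  }
  .fixture_env$cohort
}

shared_sim <- function() {
  shared_cohort()
  .fixture_env$sim
}
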