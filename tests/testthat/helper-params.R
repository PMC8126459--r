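# small parameter factories used across test files

tiny_params <- function(n = 4, ...) {
  model_params(group_size = n, n_generations = 10, n_replicates = 2,
               master_seed = 1, ...)
}

# the baseline economy at the size where the critical fine is 0.49
n100_params <- function(...) {
  model_params(group_size = 100, ...)
}

# build a state with an exact composition: cooperators first by default
mixed_state <- function(n_coop, n_free, v = 0, shuffle = FALSE) {
  coop <- c(rep(TRUE, n_coop), rep(FALSE, n_free))
  if (shuffle) coop <- sample(coop)
  population_state(coop, punishment_level = v)
}

# shared cache so expensive batches are computed once per test run
.instevo_test_cache <- new.env(parent = emptyenv())

baseline_batch <- function() {
  if (is.null(.instevo_test_cache$baseline)) {
    p <- model_params(n_replicates = 20, master_seed = 1)
    .instevo_test_cache$baseline <- run_batch(p)
  }
  .instevo_test_cache$baseline
}
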