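# Shared simulated fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small zero-error dataset: every stage must recover truth exactly
small_zero_dataset <- function() {
  fixture("small_zero", function() {
    cfg <- sim_config(n_samples = 4, pool_sizes = c(A = 4, B = 4, C = 4, H = 4),
                      long_mismatch = 0, long_insertion = 0,
                      long_deletion = 0, short_error = 0, long_depth = 10)
    simulate_dataset(cfg, seed = 11)
  })
}

# small default-error dataset (study-condition depth)
small_noisy_dataset <- function() {
  fixture("small_noisy", function() {
    cfg <- sim_config(n_samples = 4, pool_sizes = c(A = 4, B = 4, C = 4, H = 4))
    simulate_dataset(cfg, seed = 12)
  })
}

run_of <- function(dataset, key, ...) {
  fixture(key, function() run_simulated(dataset, ...))
}
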