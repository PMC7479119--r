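# Shared fixtures. The end-to-end ensemble used by the acceptance tests is
# expensive (minutes), so it is trained once per run and cached.

TEST_MIXTURE <- disorder_mixture(1, 2, 2, 11, 2, -2, 0.36)

# small database + quickly trained ensemble for protocol-level tests
small_spec <- function(seed = 1L) {
  network_spec(hidden_widths = c(16L, 8L, 8L), epochs = 6L,
               batch_sequences = 10L, seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

small_db <- function() {
  if (is.null(.fixture_cache$small_db)) {
    .fixture_cache$small_db <- generate_database(
      synthetic_config(n_entries = 24L, length_range = c(50L, 90L),
                       seed = 404L))
  }
  .fixture_cache$small_db
}

small_ensemble <- function() {
  if (is.null(.fixture_cache$small_ens)) {
    .fixture_cache$small_ens <- train_ensemble(small_db(), small_spec(),
                                               seed = 404L)
  }
  .fixture_cache$small_ens
}

# study-scale fixtures for the end-to-end acceptance experiment
acceptance_db <- function() {
  if (is.null(.fixture_cache$acc_db)) {
    .fixture_cache$acc_db <- generate_database(
      synthetic_config(n_entries = 200L, seed = 7L))
  }
  .fixture_cache$acc_db
}

acceptance_ensemble <- function() {
  if (is.null(.fixture_cache$acc_ens)) {
    .fixture_cache$acc_ens <- train_ensemble(acceptance_db(),
                                             network_spec(), seed = 7L)
  }
  .fixture_cache$acc_ens
}
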