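# Shared synthetic fixtures, built once per test run under a fixed seed.
.fixture_env <- new.env()

gcf_fixtures <- function() {
  if (is.null(.fixture_env$map)) {
    withr::with_seed(4242, {
      naive <- random_naive_sequence(60L)
      .fixture_env$naive <- naive
      .fixture_env$map <- synthetic_dms_map(naive = naive)
      .fixture_env$shm <- synthetic_shm_model(multiplier = 1)
    })
  }
  list(naive = .fixture_env$naive, map = .fixture_env$map, shm = .fixture_env$shm)
}

# a small, fast simulation configuration for unit tests
small_config <- function(...) {
  sim_config(capacity = 50, n_sample = 20, t_final = 10, init_pop = 8,
             min_survivors = 5, ...)
}

# count nucleotide differences between two sequences
n_diffs <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
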