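# Small fixtures generated in code; all randomness is seeded locally.

random_epochs <- function(n = 8, C = 4, T = 500, K = 4, fs = 250, seed = 1) {
  withr::with_seed(seed, {
    epoch_set(array(rnorm(n * C * T), c(n, C, T)),
              labels = rep(0:(K - 1), length.out = n), fs = fs)
  })
}

# a small mode-A scene: fewer trials and a shorter window than the presets,
# but the same generative structure
small_mode_a <- function(trials_per_class = 10, T = 500, snr_db = 12,
                         seed = 5) {
  synth_config(C = 8, T = T, trials_per_class = trials_per_class,
               snr_db = snr_db, seed = seed)
}

small_mode_b <- function(trials_per_class = 10, seed = 6) {
  synth_config(C = 8, T = 1000, trials_per_class = trials_per_class,
               mode = "B", snr_db = 12, seed = seed)
}

# band-decomposed copy of a tiny random epoch set (shared by CSP tests)
tiny_band_epochs <- function(n = 8, C = 8, T = 250, K = 4, seed = 2) {
  apply_filterbank(random_epochs(n, C, T, K, seed = seed),
                   make_bands(8, 32, 4))
}

expect_same_matrix <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
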