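# Shared fixtures, all generated in code at test time.

# small preprocessed synthetic dataset (already 250 Hz, band-limited)
make_synth <- function(n_classes = 2L, n_trials = 20L, erd_depth = 0.8,
                       seed = 1L, n_channels = 20L, snr = 2, ...) {
  generate_mi_dataset(synth_config(
    n_classes = n_classes, n_trials_per_class = n_trials,
    n_channels = n_channels, erd_depth = erd_depth, snr = snr,
    seed = seed, ...))
}

# two-class toy epochs with known diagonal covariances
# class 0 ~ diag(v0), class 1 ~ diag(v1)
make_diag_epochs <- function(v0, v1, n_per_class = 200L, n_samples = 100L,
                             seed = 1L) {
  set.seed(seed)
  m <- length(v0)
  dat <- array(0, c(2L * n_per_class, m, n_samples))
  for (i in seq_len(n_per_class))
    for (ch in seq_len(m))
      dat[i, ch, ] <- stats::rnorm(n_samples, sd = sqrt(v0[ch]))
  for (i in (n_per_class + 1L):(2L * n_per_class))
    for (ch in seq_len(m))
      dat[i, ch, ] <- stats::rnorm(n_samples, sd = sqrt(v1[ch]))
  eeg_epochs(dat, rep(0:1, each = n_per_class), 250)
}

# unit sinusoid trial matrix
sinusoid_trial <- function(freq, fs = 250, n = 1000L, channels = 1L) {
  x <- sin(2 * pi * freq * (0:(n - 1)) / fs)
  matrix(rep(x, channels), nrow = channels, byrow = TRUE)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / max(abs(expected), 1e-12), tol)
}
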