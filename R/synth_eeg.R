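#' Configuration for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the structure of a sensorimotor motor-imagery
#' recording: 20 channels at 250 Hz, 4 s trials, with class-specific
#' event-related desynchronization (ERD) modelled as multiplicative
#' amplitude attenuation of band-limited oscillatory sources mixed into
#' the channels through a fixed orthonormal spatial pattern, on top of
#' 1/f background noise.
#'
#' @param n_classes 2 or 3 motor-imagery classes.
#' @param n_trials_per_class Trials generated per class (>= 1).
#' @param n_channels Number of EEG channels (default 20).
#' @param fs Sampling rate in Hz (default 250; use 2500 to exercise
#'   decimation).
#' @param duration Trial length in seconds (default 4). `fs * duration`
#'   must be an integer.
#' @param source_freq_band Two-element `c(low, high)` Hz band containing
#'   the oscillatory sources (default `c(10, 22)`). The band is split into
#'   `n_classes` contiguous sub-bands, one per class source, so each source
#'   is spectrally identifiable.
#' @param erd_depth Amplitude attenuation in `[0, 1)` applied to class
#'   `k`'s source during class-`k` trials (ERD); 0 makes all classes
#'   identically distributed.
#' @param noise_exponent Spectral slope of the `1/f^alpha` background
#'   (default 1).
#' @param snr Source-to-noise RMS amplitude ratio per unit-norm mixing
#'   column (default 2). `Inf` disables noise entirely.
#' @param seed Integer seed; identical `(config, seed)` pairs produce
#'   bit-identical datasets.
#' @param keep_sources If `TRUE`, ground-truth source time courses and
#'   the mixing matrix are attached to the output (for filter-recovery
#'   tests); off by default to save memory.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 2L, n_trials_per_class = 50L,
                         n_channels = 20L, fs = 250, duration = 4,
                         source_freq_band = c(10, 22), erd_depth = 0.5,
                         noise_exponent = 1, snr = 2, seed = 1L,
                         keep_sources = FALSE) {
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3")
  if (n_trials_per_class < 1L)
    stop("n_trials_per_class must be >= 1")
  if (erd_depth < 0 || erd_depth >= 1)
    stop("erd_depth must lie in [0, 1)")
  n <- fs * duration
  if (abs(n - round(n)) > 1e-9)
    stop("fs * duration must be an integer number of samples")
  if (source_freq_band[1] >= source_freq_band[2])
    stop("invalid source_freq_band: low >= high")
  if (source_freq_band[2] > fs / 2)
    stop("invalid source_freq_band: high above Nyquist")
  structure(list(
    n_classes = as.integer(n_classes),
    n_trials_per_class = as.integer(n_trials_per_class),
    n_channels = as.integer(n_channels), fs = fs, duration = duration,
    source_freq_band = source_freq_band, erd_depth = erd_depth,
    noise_exponent = noise_exponent, snr = snr, seed = as.integer(seed),
    keep_sources = isTRUE(keep_sources)), class = "synth_config")
}

#' Per-class source sub-band of a synthetic configuration
#'
#' @param config A `synth_config`.
#' @param k Class index, `0 .. n_classes-1`.
#' @return `c(low, high)` in Hz.
#' @export
source_band <- function(config, k) {
  w <- diff(config$source_freq_band) / config$n_classes
  config$source_freq_band[1] + c(k, k + 1) * w
}

# Band-limited Gaussian series via frequency-domain synthesis, unit RMS.
# The band is half-open [low, high) so adjacent per-class sub-bands stay
# spectrally disjoint.
rand_band_series <- function(n, fs, band) {
  f <- (0:(n - 1)) * fs / n
  keep <- f >= band[1] & f < band[2] & f <= fs / 2
  spec <- complex(real = rep(0, n), imaginary = rep(0, n))
  m <- sum(keep)
  spec[keep] <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

# 1/f^alpha Gaussian series, unit RMS.
rand_pink_series <- function(n, fs, alpha) {
  f <- (0:(n - 1)) * fs / n
  amp <- c(0, f[2:n]^(-alpha / 2))
  amp[f > fs / 2] <- 0
  spec <- amp * complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x / stats::sd(x)
}

#' Generate a synthetic motor-imagery EEG dataset
#'
#' Each class `k` owns one band-limited oscillatory source with a fixed
#' spatial pattern (a column of a random orthonormal mixing matrix drawn
#' once per dataset). During class-`k` trials, source `k`'s amplitude is
#' scaled by `1 - erd_depth` (ERD) while the other sources stay at
#' baseline. Channels additionally receive independent `1/f` noise plus a
#' 10%-amplitude common-mode `1/f` term. Generation is fully determined
#' by the seed.
#'
#' @param config A `synth_config`.
#' @return An [eeg_epochs] object with `n_classes * n_trials_per_class`
#'   trials (class-blocked order).
#' @export
generate_mi_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  K <- config$n_classes
  nc <- config$n_channels
  n <- as.integer(round(config$fs * config$duration))
  ntr <- config$n_trials_per_class * K

  # orthonormal mixing columns, one source per class
  A <- qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))[, seq_len(K),
                                                       drop = FALSE]
  # fix column signs for reproducibility across BLAS variants
  for (j in seq_len(K)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }

  noise_amp <- if (is.infinite(config$snr)) 0 else 1
  src_amp <- if (is.infinite(config$snr)) 1 else config$snr

  data <- array(0, dim = c(ntr, nc, n))
  labels <- integer(ntr)
  sources <- if (config$keep_sources) array(0, dim = c(ntr, K, n)) else NULL
  bands <- lapply(seq_len(K) - 1L, function(k) source_band(config, k))

  t_i <- 0L
  for (k in seq_len(K) - 1L) {
    for (r in seq_len(config$n_trials_per_class)) {
      t_i <- t_i + 1L
      S <- matrix(0, K, n)
      for (j in seq_len(K))
        S[j, ] <- rand_band_series(n, config$fs, bands[[j]])
      amp <- rep(src_amp, K)
      amp[k + 1L] <- amp[k + 1L] * (1 - config$erd_depth)
      X <- A %*% (S * amp)
      if (noise_amp > 0) {
        noise <- t(vapply(seq_len(nc), function(ch)
          rand_pink_series(n, config$fs, config$noise_exponent),
          numeric(n)))
        common <- rand_pink_series(n, config$fs, config$noise_exponent)
        X <- X + noise_amp * (noise + 0.1 * matrix(common, nc, n,
                                                   byrow = TRUE))
      }
      data[t_i, , ] <- X
      labels[t_i] <- k
      if (config$keep_sources) sources[t_i, , ] <- S * amp
    }
  }

  ch <- if (nc == 20L) sensorimotor_channels() else paste0("ch", seq_len(nc))
  gt <- if (config$keep_sources)
    list(mixing = A, sources = sources, bands = bands) else list(mixing = A,
                                                                 bands = bands)
  eeg_epochs(data, labels, config$fs, ch,
             class_names = paste0("class", seq_len(K) - 1L),
             ground_truth = gt)
}

#' Integrated periodogram band power of one channel of a trial
#'
#' Sums the two-sided periodogram over `band`, returning the mean-square
#' power contribution of that band (a unit-amplitude sinusoid inside the
#' band gives ~0.5).
#'
#' @param trial Numeric channels x samples matrix.
#' @param fs Sampling rate, Hz.
#' @param band `c(low, high)` in Hz, inside `(0, fs/2)`.
#' @param channel Channel index (1-based).
#' @return Non-negative scalar power (microvolt^2).
#' @export
band_power <- function(trial, fs, band, channel = 1L) {
  if (length(band) != 2L || band[1] >= band[2])
    stop("empty or invalid band")
  if (band[1] <= 0 || band[2] > fs / 2)
    stop("band must lie inside (0, fs/2)")
  x <- trial[channel, ]
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  idx <- f >= band[1] & f <= band[2] & f <= fs / 2
  2 * sum(Mod(X[idx])^2) / n^2
}
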