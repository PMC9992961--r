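#' Preprocessing configuration
#'
#' Signal-conditioning parameters for motor-imagery epochs: sensorimotor
#' channel selection, 8-30 Hz zero-phase band-pass, decimation to 250 Hz
#' and a 4 s analysis window, yielding 20 x 1000 trials.
#'
#' @param channels Ordered channel names to keep (default the 20
#'   sensorimotor labels of [sensorimotor_channels()]).
#' @param band `c(low, high)` pass band in Hz (default `c(8, 30)`).
#' @param target_fs Output sampling rate in Hz (default 250).
#' @param window `c(t_start, duration)` seconds, cue onset at t = 0.
#' @param filter_order Butterworth section order (default 4).
#' @param zero_phase Apply the filter forward-backward (default `TRUE`).
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(channels = sensorimotor_channels(),
                           band = c(8, 30), target_fs = 250,
                           window = c(0, 4), filter_order = 4L,
                           zero_phase = TRUE) {
  if (band[1] >= band[2]) stop("band low must be below band high")
  if (band[2] >= target_fs / 2)
    stop("band high must be below the target Nyquist frequency")
  n <- window[2] * target_fs
  if (abs(n - round(n)) > 1e-9)
    stop("window duration x target_fs must be an integer")
  structure(list(channels = channels, band = band, target_fs = target_fs,
                 window = window, filter_order = as.integer(filter_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "preproc_config")
}

# polynomial from roots, ascending powers of z^-1 convention:
# returns coefficients c0, c1, ... of prod (1 - r_i z^-1) times leading 1,
# here computed as standard poly in descending powers.
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Analog prototype poles, low-pass to band-pass transformation with
#' frequency pre-warping, bilinear transform, and gain normalization at
#' the (warped) band center. Matches the conventional `butter(order,
#' c(low, high)/(fs/2), "pass")` design.
#'
#' @param order Prototype order (the digital filter has `2 * order`
#'   poles).
#' @param low,high Band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, low, high, fs) {
  if (low <= 0 || low >= high) stop("invalid band edges")
  if (high >= fs / 2) stop("band edge at or above Nyquist")
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  W1 <- warp(low); W2 <- warp(high)
  Bw <- W2 - W1; W0 <- sqrt(W1 * W2)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  # low-pass -> band-pass: each pole spawns a conjugate-free pair
  p_bp <- c()
  for (p in p_lp) {
    disc <- sqrt((p * Bw)^2 / 4 - W0^2)
    p_bp <- c(p_bp, p * Bw / 2 + disc, p * Bw / 2 - disc)
  }
  # bilinear transform
  z_p <- (2 * fs + p_bp) / (2 * fs - p_bp)
  z_z <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  b <- Re(poly_from_roots(z_z))
  a <- Re(poly_from_roots(z_p))
  # normalize gain at the warped center frequency
  f0 <- fs / pi * atan(W0 / (2 * fs))
  h0 <- Mod(freq_response(b, a, f0, fs))
  list(b = b / h0, a = a)
}

#' Complex frequency response of a digital filter
#'
#' @param b,a Filter coefficients.
#' @param f Frequencies in Hz (vectorized).
#' @param fs Sampling rate in Hz.
#' @return Complex vector `H(e^{i 2 pi f / fs})`.
#' @export
freq_response <- function(b, a, f, fs) {
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs * (seq_along(b) - 1))
    zn <- exp(-1i * 2 * pi * fi / fs * (seq_along(a) - 1))
    sum(b * z) / sum(a * zn)
  }, complex(1))
}

# zero-phase filtering with odd-reflection padding (scipy-style filtfilt)
filtfilt_pad <- function(b, a, x) {
  padlen <- 3L * max(length(a), length(b))
  n <- length(x)
  if (n <= padlen)
    stop("signal too short for zero-phase padding")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  xp <- c(pre, x, post)
  y <- cpp_iir(b, a, xp)
  y <- rev(cpp_iir(b, a, rev(y)))
  y[(padlen + 1):(padlen + n)]
}

#' Select and reorder channels
#'
#' @param epochs An [eeg_epochs] object.
#' @param names Channel names to keep, in the requested order.
#' @return A new `eeg_epochs` whose channel dimension matches `names`.
#' @export
select_channels <- function(epochs, names) {
  idx <- match(names, epochs$channel_names)
  if (anyNA(idx))
    stop("channel(s) not present: ",
         paste(names[is.na(idx)], collapse = ", "))
  eeg_epochs(epochs$data[, idx, , drop = FALSE], epochs$labels, epochs$fs,
             epochs$channel_names[idx], epochs$class_names,
             epochs$ground_truth)
}

#' Band-pass filter every channel of every trial
#'
#' Butterworth band-pass, applied forward-backward (zero phase) by
#' default, with odd-reflection edge padding.
#'
#' @param epochs An [eeg_epochs] object.
#' @param config A [preproc_config()].
#' @return Filtered `eeg_epochs` of identical shape.
#' @export
bandpass <- function(epochs, config = preproc_config()) {
  if (config$band[2] >= epochs$fs / 2)
    stop("band high at or above the Nyquist frequency of the data")
  flt <- butter_bandpass(config$filter_order, config$band[1],
                         config$band[2], epochs$fs)
  d <- dim(epochs$data)
  out <- epochs$data
  for (i in seq_len(d[1])) for (ch in seq_len(d[2])) {
    x <- epochs$data[i, ch, ]
    out[i, ch, ] <- if (config$zero_phase) filtfilt_pad(flt$b, flt$a, x)
    else cpp_iir(flt$b, flt$a, x)
  }
  eeg_epochs(out, epochs$labels, epochs$fs, epochs$channel_names,
             epochs$class_names, epochs$ground_truth)
}

#' Downsample by an integer factor
#'
#' Plain decimation (every `fs/target_fs`-th sample). The preceding
#' 8-30 Hz band-pass doubles as the anti-alias filter, so no additional
#' low-pass is applied.
#'
#' @param epochs An [eeg_epochs] object.
#' @param target_fs Target sampling rate; `fs` must be an integer
#'   multiple of it.
#' @return Decimated `eeg_epochs` with `fs = target_fs`.
#' @export
downsample <- function(epochs, target_fs) {
  r <- epochs$fs / target_fs
  if (abs(r - round(r)) > 1e-9)
    stop("fs must be an integer multiple of target_fs")
  r <- as.integer(round(r))
  if (r == 1L) return(epochs)
  keep <- seq(1L, dim(epochs$data)[3], by = r)
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$labels, target_fs,
             epochs$channel_names, epochs$class_names, epochs$ground_truth)
}

#' Cut a fixed time window out of every trial
#'
#' Windows are half-open `[t_start, t_start + duration)` in samples,
#' with t = 0 at the first sample (cue onset).
#'
#' @param epochs An [eeg_epochs] object.
#' @param t_start Window start in seconds.
#' @param duration Window length in seconds.
#' @return Windowed `eeg_epochs` with `duration * fs` samples per trial.
#' @export
window_epochs <- function(epochs, t_start, duration) {
  n <- dim(epochs$data)[3]
  i0 <- as.integer(round(t_start * epochs$fs))
  len <- as.integer(round(duration * epochs$fs))
  if (i0 < 0L || i0 + len > n)
    stop("window exceeds trial extent")
  keep <- (i0 + 1L):(i0 + len)
  eeg_epochs(epochs$data[, , keep, drop = FALSE], epochs$labels, epochs$fs,
             epochs$channel_names, epochs$class_names, epochs$ground_truth)
}

#' Full preprocessing chain
#'
#' `select_channels` -> `bandpass` -> `downsample` -> `window_epochs`,
#' producing (with defaults) 20 x 1000 trials at 250 Hz.
#'
#' @param epochs An [eeg_epochs] object.
#' @param config A [preproc_config()].
#' @return Preprocessed `eeg_epochs`.
#' @export
preprocess <- function(epochs, config = preproc_config()) {
  e <- select_channels(epochs, config$channels)
  e <- bandpass(e, config)
  e <- downsample(e, config$target_fs)
  window_epochs(e, config$window[1], config$window[2])
}
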