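#' Continuous-wavelet scalogram configuration
#'
#' @param freqs Strictly increasing center frequencies in Hz; default 64
#'   values linearly spaced over the 8-30 Hz analysis band so the
#'   frequency axis fills the 64-pixel image height exactly.
#' @param omega0 Morlet center parameter / number of cycles (default 6,
#'   the conventional neuroscience choice).
#' @param time_bins Number of time bins the trial is averaged into
#'   (default 64).
#' @param image_size Output image side length (default 64).
#' @param image_mode How multiple virtual-channel maps become one RGB
#'   image: `"mean_colormap"` (default) averages all maps and applies the
#'   colormap; `"ovr_planes"` assigns each one-vs-rest model's mean map to
#'   one color plane (requires exactly 3 models).
#' @param value `"magnitude"` (default) or `"power"` (squared magnitude).
#' @param colormap Colormap name; only `"jet"` is shipped.
#' @return A list of class `cwt_config`.
#' @export
cwt_config <- function(freqs = seq(8, 30, length.out = 64), omega0 = 6,
                       time_bins = 64L, image_size = 64L,
                       image_mode = c("mean_colormap", "ovr_planes"),
                       value = c("magnitude", "power"),
                       colormap = "jet") {
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  if (any(freqs <= 0)) stop("freqs must be positive")
  if (time_bins < 1L) stop("time_bins must be >= 1")
  structure(list(freqs = freqs, omega0 = omega0,
                 time_bins = as.integer(time_bins),
                 image_size = as.integer(image_size),
                 image_mode = match.arg(image_mode),
                 value = match.arg(value), colormap = colormap),
            class = "cwt_config")
}

# Complex Morlet wavelet at center frequency f with support +-4
# temporal standard deviations. Normalized to unit peak frequency
# response (the envelope sums to 1), so a unit-amplitude sinusoid at
# the center frequency yields |coefficient| = 0.5 in every row; this
# flat tone response is what makes scalogram rows comparable across
# frequency and pins a tone's peak to its nearest frequency bin
# (an L2-normalized wavelet tilts responses by 1/sqrt(f), biasing peak
# rows low by up to two bins at 25 Hz).
morlet_wavelet <- function(f, fs, omega0) {
  sigma_t <- omega0 / (2 * pi * f)
  half <- ceiling(4 * sigma_t * fs)
  n <- (-half):half
  env <- exp(-(n / fs)^2 / (2 * sigma_t^2))
  exp(1i * 2 * pi * f * n / fs) * env / sum(env)
}

#' Morlet continuous wavelet transform
#'
#' Convolves the signal with complex Morlet wavelets (unit peak
#' frequency response, see the vignette) at each configured center
#' frequency, using mirror padding of half the wavelet support to
#' suppress boundary artifacts. Linear in the signal; a unit-amplitude
#' sinusoid at a row's center frequency yields coefficient magnitude
#' ~0.5 in that row.
#'
#' @param x Numeric vector (one virtual-channel time series).
#' @param fs Sampling rate in Hz.
#' @param config A [cwt_config()].
#' @return Complex matrix, `length(freqs)` x `length(x)`.
#' @export
morlet_cwt <- function(x, fs, config = cwt_config()) {
  if (any(config$freqs >= fs / 2))
    stop("freqs must lie inside (0, fs/2)")
  n <- length(x)
  out <- matrix(complex(real = 0), length(config$freqs), n)
  for (fi in seq_along(config$freqs)) {
    w <- morlet_wavelet(config$freqs[fi], fs, config$omega0)
    half <- (length(w) - 1L) %/% 2L
    if (n < length(w))
      stop("signal shorter than the wavelet support at ",
           config$freqs[fi], " Hz")
    xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])  # mirror pad
    L <- stats::nextn(length(xp) + length(w) - 1L, 2)
    conv <- stats::fft(stats::fft(c(xp, rep(0, L - length(xp)))) *
                         stats::fft(c(w, rep(0, L - length(w)))),
                       inverse = TRUE) / L
    # full convolution index of original sample t: t + 2*half
    out[fi, ] <- conv[(1:n) + 2L * half]
  }
  out
}

#' Time-binned scalogram of CWT coefficients
#'
#' Magnitudes are averaged within `time_bins` contiguous segments whose
#' lengths differ by at most one sample and jointly cover every sample
#' exactly once. Row `f` corresponds to `freqs[f]` (low to high).
#'
#' @param coefs Complex (or numeric) F x N coefficient matrix.
#' @param time_bins Number of output time bins.
#' @return Non-negative F x `time_bins` magnitude matrix.
#' @export
scalogram <- function(coefs, time_bins) {
  n <- ncol(coefs)
  if (time_bins > n) stop("time_bins exceeds the number of samples")
  mag <- Mod(coefs)
  bounds <- round(n * (0:time_bins) / time_bins)
  out <- matrix(0, nrow(coefs), time_bins)
  for (j in seq_len(time_bins))
    out[, j] <- rowMeans(mag[, (bounds[j] + 1L):bounds[j + 1L],
                             drop = FALSE])
  out
}

#' The "jet" colormap lookup table
#'
#' Classic blue-cyan-yellow-red piecewise-linear colormap, shipped as a
#' fixed table so the image path has no plotting-library dependence.
#'
#' @param n Number of levels (default 256).
#' @return `n` x 3 matrix of RGB values in `[0, 1]`.
#' @export
jet_colormap <- function(n = 256L) {
  v <- seq(0, 1, length.out = n)
  clamp <- function(z) pmin(pmax(z, 0), 1)
  cbind(r = clamp(1.5 - abs(4 * v - 3)),
        g = clamp(1.5 - abs(4 * v - 2)),
        b = clamp(1.5 - abs(4 * v - 1)))
}

# bilinear resize via row/column interpolation matrices (half-pixel
# centers, edges clamped)
bilinear_resize <- function(m, out_h, out_w) {
  interp_mat <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    lo <- pmin(floor(src), n_in - ifelse(n_in > 1, 1, 0))
    frac <- src - lo
    A <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      A[i, lo[i]] <- 1 - frac[i]
      A[i, min(lo[i] + 1, n_in)] <- A[i, min(lo[i] + 1, n_in)] + frac[i]
    }
    A
  }
  interp_mat(nrow(m), out_h) %*% m %*% t(interp_mat(ncol(m), out_w))
}

# min-max normalize to [0,1]; an all-constant map becomes all zeros
minmax01 <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m * 0)
  (m - rng[1]) / (rng[2] - rng[1])
}

map_to_plane <- function(map, size) {
  minmax01(bilinear_resize(map, size, size))
}

#' Render magnitude maps as one RGB time-frequency image
#'
#' Maps are combined according to `image_mode`, min-max normalized to
#' `[0, 1]`, bilinearly resized to `image_size` x `image_size`, and
#' colormapped into three planes. All-constant input maps normalize to
#' zero and hence render as `colormap(0)`.
#'
#' @param maps List of F x T non-negative magnitude maps (uniform
#'   shapes). For `image_mode = "ovr_planes"` the list length must be a
#'   multiple of 3 (maps grouped per one-vs-rest model).
#' @param config A [cwt_config()].
#' @param trial_id,label Optional identifiers attached to the result.
#' @return Object of class `tf_image` with `pixels`
#'   (`image_size` x `image_size` x 3, values in `[0, 1]`).
#' @export
render_image <- function(maps, config = cwt_config(), trial_id = NA_integer_,
                         label = NA_integer_) {
  if (length(maps) == 0L) stop("empty map list")
  dims <- dim(maps[[1]])
  for (m in maps)
    if (!identical(dim(m), dims)) stop("maps must share one shape")
  s <- config$image_size
  px <- array(0, dim = c(s, s, 3))
  if (config$image_mode == "mean_colormap") {
    avg <- Reduce(`+`, maps) / length(maps)
    plane <- map_to_plane(avg, s)
    lut <- jet_colormap(256L)
    idx <- pmin(pmax(round(plane * 255) + 1L, 1L), 256L)
    for (ch in 1:3) px[, , ch] <- matrix(lut[idx, ch], s, s)
  } else {
    if (length(maps) %% 3L != 0L)
      stop("ovr_planes mode needs maps from exactly 3 one-vs-rest models")
    per <- length(maps) / 3L
    for (ch in 1:3) {
      grp <- maps[((ch - 1L) * per + 1L):(ch * per)]
      px[, , ch] <- map_to_plane(Reduce(`+`, grp) / per, s)
    }
  }
  structure(list(pixels = px, trial_id = trial_id, label = label),
            class = "tf_image")
}

#' Build the time-frequency image of a single trial
#'
#' Composition of the scalogram branch's data path: CSP projection,
#' head/tail virtual-channel extraction, Morlet CWT per virtual channel,
#' time binning, and RGB rendering. Fully deterministic.
#'
#' @param trial Channels x samples matrix.
#' @param models List of `csp_model` objects (one-vs-rest).
#' @param fs Sampling rate in Hz.
#' @param m Filters kept from each end of `Z` (default 1).
#' @param config A [cwt_config()].
#' @param trial_id,label Passed to [render_image()].
#' @return A `tf_image`.
#' @export
trial_to_image <- function(trial, models, fs, m = 1L,
                           config = cwt_config(), trial_id = NA_integer_,
                           label = NA_integer_) {
  M <- ncol(models[[1]]$W)
  if (nrow(trial) != M) stop("trial channel count does not match models")
  rows <- c(seq_len(m), (M - m + 1L):M)
  maps <- list()
  for (mod in models) {
    Z <- project(mod, trial)
    for (r in rows) {
      coefs <- morlet_cwt(Z[r, ], fs, config)
      map <- scalogram(coefs, config$time_bins)
      if (config$value == "power") map <- map^2
      maps[[length(maps) + 1L]] <- map
    }
  }
  render_image(maps, config, trial_id = trial_id, label = label)
}

#' Time-frequency images for every trial of an epoch set
#'
#' @param epochs An [eeg_epochs] object.
#' @param models One-vs-rest `csp_model` list (fit on training data
#'   only).
#' @param m Filters kept from each end (default 1).
#' @param config A [cwt_config()].
#' @return 4-D array `image_size x image_size x 3 x trials`, suitable as
#'   TF-branch input.
#' @export
epochs_to_images <- function(epochs, models, m = 1L, config = cwt_config()) {
  d <- dim(epochs$data)
  s <- config$image_size
  out <- array(0, dim = c(s, s, 3, d[1]))
  for (i in seq_len(d[1])) {
    img <- trial_to_image(trial_matrix(epochs, i), models, epochs$fs, m,
                          config, trial_id = i, label = epochs$labels[i])
    out[, , , i] <- img$pixels
  }
  out
}

#' Write a `tf_image` as an 8-bit PNG-style PPM file
#'
#' Images are stored internally as float arrays; this exports a plain
#' portable pixmap (P3 text) so no image library is required.
#'
#' @param image A `tf_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_ppm <- function(image, path) {
  px <- round(image$pixels * 255)
  s <- dim(px)[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(dim(px)[2], s), "255"), con)
  # image row 1 = highest frequency (flip the low->high storage order)
  for (i in s:1) {
    row <- as.vector(rbind(px[i, , 1], px[i, , 2], px[i, , 3]))
    writeLines(paste(row, collapse = " "), con)
  }
  invisible(path)
}
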