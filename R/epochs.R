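#' The 20 sensorimotor channel labels used by default
#'
#' Channel labels covering the sensorimotor cortex in the international
#' 10-20 layout: FC1-FC6, C1-C6, CP1-CP6, CZ and CPZ.
#'
#' @return Character vector of length 20.
#' @export
sensorimotor_channels <- function() {
  c(paste0("FC", 1:6), paste0("C", 1:6), paste0("CP", 1:6), "CZ", "CPZ")
}

#' Construct an epoched EEG dataset
#'
#' The common currency of the pipeline: a `trials x channels x samples`
#' array of voltages (microvolts) with per-trial integer class labels,
#' a sampling rate and ordered channel names.
#'
#' @param data Numeric 3-D array, `trials x channels x samples`. Must be
#'   finite everywhere.
#' @param labels Integer vector, one label per trial, coded `0 .. K-1`.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector matching the channel dimension.
#' @param class_names Optional character vector naming the `K` classes.
#' @param ground_truth Optional list carrying simulator ground truth
#'   (mixing matrix, source time courses); attached verbatim.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, labels, fs, channel_names = NULL,
                       class_names = NULL, ground_truth = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x samples array")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  d <- dim(data)
  labels <- as.integer(labels)
  if (length(labels) != d[1L])
    stop("length(labels) must equal the number of trials")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(d[2L]))
  if (length(channel_names) != d[2L])
    stop("length(channel_names) must equal the channel dimension")
  k <- max(labels) + 1L
  if (any(labels < 0L))
    stop("labels must be coded 0 .. K-1")
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(k) - 1L)
  if (length(class_names) < k)
    stop("class_names shorter than the number of label levels")
  structure(
    list(data = data, labels = labels, fs = fs,
         channel_names = as.character(channel_names),
         class_names = as.character(class_names),
         ground_truth = ground_truth),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  tab <- table(factor(x$labels, levels = seq_along(x$class_names) - 1L,
                      labels = x$class_names))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of trials, channels, samples of an epoch set
#' @param epochs An `eeg_epochs` object.
#' @return Integer vector `c(trials, channels, samples)`.
#' @export
epoch_dims <- function(epochs) dim(epochs$data)

#' Subset an epoch set by trial index
#'
#' @param epochs An `eeg_epochs` object.
#' @param idx Integer vector of trial indices (1-based).
#' @return A new `eeg_epochs` holding only the requested trials.
#' @export
subset_trials <- function(epochs, idx) {
  gt <- epochs$ground_truth
  if (!is.null(gt) && !is.null(gt$sources))
    gt$sources <- gt$sources[idx, , , drop = FALSE]
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$labels[idx],
             epochs$fs, epochs$channel_names, epochs$class_names, gt)
}

#' One trial as a channels x samples matrix
#' @param epochs An `eeg_epochs` object.
#' @param i Trial index.
#' @return Numeric matrix, channels x samples.
#' @export
trial_matrix <- function(epochs, i) {
  m <- epochs$data[i, , , drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}

# Deterministic sub-seed derivation (Lehmer step); stays below 2^31.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + salt) %% 2147483647)
}
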