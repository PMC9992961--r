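#' Write an epoch set as a plain-text directory
#'
#' One whitespace-delimited channels x samples matrix per trial
#' (`trial_0001.txt`, ...), a `labels.csv` with columns
#' `trial_id,label`, and a `meta.json` carrying the sampling rate and
#' the channel/class names.
#'
#' @param epochs An [eeg_epochs] object.
#' @param path Directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_epochs_dir <- function(epochs, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  for (i in seq_len(d[1])) {
    utils::write.table(trial_matrix(epochs, i),
                       file.path(path, sprintf("trial_%04d.txt", i)),
                       row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(data.frame(trial_id = seq_len(d[1]),
                              label = epochs$labels),
                   file.path(path, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = epochs$fs,
                            channel_names = epochs$channel_names,
                            class_names = epochs$class_names),
                       file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an epoch set from a plain-text directory
#'
#' Inverse of [write_epochs_dir()].
#'
#' @param path Directory written by [write_epochs_dir()].
#' @return An [eeg_epochs] object.
#' @export
read_epochs_dir <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  lab <- utils::read.csv(file.path(path, "labels.csv"))
  lab <- lab[order(lab$trial_id), ]
  n <- nrow(lab)
  first <- as.matrix(utils::read.table(
    file.path(path, sprintf("trial_%04d.txt", 1L))))
  data <- array(0, dim = c(n, nrow(first), ncol(first)))
  data[1L, , ] <- first
  if (n > 1L) for (i in 2:n)
    data[i, , ] <- as.matrix(utils::read.table(
      file.path(path, sprintf("trial_%04d.txt", i))))
  eeg_epochs(data, lab$label, meta$fs, meta$channel_names,
             meta$class_names)
}
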