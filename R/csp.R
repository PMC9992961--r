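#' Fit a binary common-spatial-patterns model
#'
#' Estimates per-trial covariances `E E' / trace(E E')`, averages them
#' per side (the positive class vs. everything else), adds diagonal
#' shrinkage, and solves the generalized eigenproblem of
#' `(C+, C+ + C-)` by whitening. The projection matrix `W` (rows =
#' spatial filters) jointly diagonalizes both composite covariances;
#' filter `j` satisfies `w_j C+ w_j' = lambda_j` and
#' `w_j C- w_j' = 1 - lambda_j`, with eigenvalues sorted descending so
#' leading filters capture variance specific to the positive class.
#'
#' @param epochs An [eeg_epochs] object.
#' @param positive_class Integer label treated as the positive side.
#' @param shrinkage Diagonal loading `eps`:
#'   `C <- (1 - eps) C + eps tr(C)/M I` (default 1e-6).
#' @return An object of class `csp_model` with fields `W`,
#'   `eigenvalues`, `positive_class`, `trace_normalized`.
#' @export
fit_csp <- function(epochs, positive_class, shrinkage = 1e-6) {
  lab <- epochs$labels
  pos <- which(lab == positive_class)
  neg <- which(lab != positive_class)
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need >= 2 trials on each side of the CSP problem")
  M <- dim(epochs$data)[2]
  if (M < 2L) stop("CSP needs >= 2 channels")

  avg_cov <- function(idx) {
    C <- matrix(0, M, M)
    for (i in idx) {
      E <- trial_matrix(epochs, i)
      Ci <- E %*% t(E)
      C <- C + Ci / sum(diag(Ci))
    }
    C <- C / length(idx)
    (1 - shrinkage) * C + shrinkage * sum(diag(C)) / M * diag(M)
  }
  Cp <- avg_cov(pos)
  Cn <- avg_cov(neg)
  Cc <- Cp + Cn
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) < 1e-10 * max(ec$values))
    stop("rank-deficient composite covariance beyond shrinkage repair")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S <- P %*% Cp %*% t(P)
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)  # descending in R
  W <- t(es$vectors) %*% P
  # sign convention: largest-magnitude coefficient of each filter positive
  for (j in seq_len(M)) {
    i <- which.max(abs(W[j, ]))
    if (W[j, i] < 0) W[j, ] <- -W[j, ]
  }
  structure(list(W = W, eigenvalues = es$values,
                 positive_class = as.integer(positive_class),
                 trace_normalized = TRUE),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters, positive class %d\n",
              nrow(x$W), x$positive_class))
  cat("  leading eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigenvalues, 4)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Fit one-vs-rest CSP models
#'
#' For two classes a single binary model is returned (positive class =
#' the smaller label); for three or more classes one model per class is
#' fit with that class as positive and the pooled remainder as negative.
#'
#' @param epochs An [eeg_epochs] object.
#' @param shrinkage Passed to [fit_csp()].
#' @return List of `csp_model` objects.
#' @export
fit_csp_ovr <- function(epochs, shrinkage = 1e-6) {
  classes <- sort(unique(epochs$labels))
  if (length(classes) < 2L) stop("need at least two classes")
  counts <- table(epochs$labels)
  if (any(counts < 2L)) stop("every class needs >= 2 trials")
  if (length(classes) == 2L)
    return(list(fit_csp(epochs, classes[1], shrinkage)))
  lapply(classes, function(k) fit_csp(epochs, k, shrinkage))
}

#' Project one trial through a CSP model
#'
#' Computes the virtual-channel signals `Z = W E`.
#'
#' @param model A `csp_model`.
#' @param trial Channels x samples matrix with `nrow == ncol(W)`.
#' @return Matrix `Z`, filters x samples.
#' @export
project <- function(model, trial) {
  if (nrow(trial) != ncol(model$W))
    stop("trial channel count does not match the CSP model")
  model$W %*% trial
}

#' Extract CSP virtual channels for every trial
#'
#' Per trial and per model, retains the first `m` and last `m` rows of
#' `Z = W E` (the most discriminative head/tail filters) and
#' concatenates them across models.
#'
#' @param models List of `csp_model` objects (one-vs-rest).
#' @param epochs An [eeg_epochs] object.
#' @param m Filters kept from each end (default 1); requires `2m < M`.
#' @return List of class `virtual_channels` with `data`
#'   (trials x `2m * n_models` x samples) and `source_rows`.
#' @export
extract_virtual_channels <- function(models, epochs, m = 1L) {
  M <- ncol(models[[1]]$W)
  if (2L * m >= M) stop("2m must be smaller than the channel count")
  d <- dim(epochs$data)
  rows <- c(seq_len(m), (M - m + 1L):M)
  nv <- length(rows) * length(models)
  out <- array(0, dim = c(d[1], nv, d[3]))
  for (i in seq_len(d[1])) {
    E <- trial_matrix(epochs, i)
    v <- 0L
    for (mod in models) {
      Z <- project(mod, E)
      for (r in rows) {
        v <- v + 1L
        out[i, v, ] <- Z[r, ]
      }
    }
  }
  structure(list(data = out, source_rows = rows, m = as.integer(m),
                 n_models = length(models)),
            class = "virtual_channels")
}
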