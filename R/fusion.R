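#' Feature-level fusion of two branch feature vectors
#'
#' Concatenates the raw-EEG branch features `A` (length m) and the
#' time-frequency branch features `B` (length n) into one vector
#' `C = (a_1, ..., a_m, b_1, ..., b_n)`, order preserved.
#'
#' @param A,B Finite numeric vectors (either may be empty).
#' @return Object of class `fusion_vector`: the concatenation with `m`
#'   and `n` attributes.
#' @export
fuse <- function(A, B) {
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("fusion inputs must be finite")
  structure(c(A, B), m = length(A), n = length(B),
            class = "fusion_vector")
}

#' Row-wise fusion of two feature matrices
#' @param A,B Matrices with equal row counts (trials).
#' @return `nrow x (m + n)` matrix, `A`'s columns first.
#' @export
fuse_features <- function(A, B) {
  if (nrow(A) != nrow(B)) stop("feature matrices disagree on trial count")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("fusion inputs must be finite")
  cbind(A, B)
}

#' Fit the fused-feature classifier
#'
#' Standardizes every feature dimension (mean/sd estimated on the
#' training features only — never on test data) and fits a linear SVM
#' on the standardized fusion vectors.
#'
#' @param features `n_trials x (m + n)` training feature matrix.
#' @param labels Integer labels `0 .. K-1`.
#' @param svm_config List with elements `kernel` (only `"linear"`) and
#'   `C` (default 1).
#' @return Object of class `fusion_classifier`.
#' @export
fit_fusion_classifier <- function(features, labels,
                                  svm_config = list(kernel = "linear",
                                                    C = 1)) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class")
  if (min(table(labels)) < 2L)
    stop("every class needs >= 2 training samples")
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(features, 2L, mu), 2L, sdv, `/`)
  svm <- svm_fit(Z, labels, C = svm_config$C %||% 1,
                 kernel = svm_config$kernel %||% "linear")
  structure(list(scaler = list(mean = mu, sd = sdv), svm = svm,
                 classes = svm$classes, width = ncol(features)),
            class = "fusion_classifier")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict with the fused-feature classifier
#'
#' @param object A `fusion_classifier`.
#' @param features Feature matrix with the width used at fit time.
#' @param ... Unused.
#' @return Integer labels, one per row.
#' @export
predict.fusion_classifier <- function(object, features, ...) {
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1L)
  if (ncol(features) != object$width)
    stop("feature width does not match the fitted classifier")
  Z <- sweep(sweep(features, 2L, object$scaler$mean), 2L,
             object$scaler$sd, `/`)
  predict(object$svm, Z)
}
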