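# L2-regularized squared-hinge linear support-vector machine, fit by
# L-BFGS-B on the (differentiable) primal. Deterministic and
# dependency-free; one-vs-rest for more than two classes.

svm_fit_binary <- function(X, y01, C = 1) {
  y <- ifelse(y01 == 1L, 1, -1)
  d <- ncol(X)
  obj <- function(wb) {
    w <- wb[seq_len(d)]; b <- wb[d + 1L]
    m <- 1 - y * (X %*% w + b)
    0.5 * sum(w * w) + C * sum(pmax(m, 0)^2)
  }
  grd <- function(wb) {
    w <- wb[seq_len(d)]; b <- wb[d + 1L]
    m <- as.numeric(1 - y * (X %*% w + b))
    act <- m > 0
    coef <- -2 * C * (m * act) * y
    c(w + as.numeric(t(X) %*% coef), sum(coef))
  }
  fit <- stats::optim(rep(0, d + 1L), obj, grd, method = "L-BFGS-B",
                      control = list(maxit = 300L))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1L])
}

#' Fit a linear support-vector machine
#'
#' Squared-hinge L2-SVM solved in the primal; one binary machine for two
#' classes, one-vs-rest machines otherwise.
#'
#' @param X `n x d` feature matrix.
#' @param labels Integer labels `0 .. K-1`.
#' @param C Misclassification cost (default 1).
#' @param kernel Only `"linear"` is implemented.
#' @return Object of class `linear_svm`.
#' @export
svm_fit <- function(X, labels, C = 1, kernel = "linear") {
  if (!identical(kernel, "linear"))
    stop("only the linear kernel is implemented")
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  machines <- if (length(classes) == 2L) {
    list(svm_fit_binary(X, as.integer(labels == classes[2]), C))
  } else {
    lapply(classes, function(k)
      svm_fit_binary(X, as.integer(labels == k), C))
  }
  structure(list(machines = machines, classes = classes, C = C,
                 kernel = kernel, d = ncol(X)), class = "linear_svm")
}

#' Decision values of a linear SVM
#' @param fit A `linear_svm`.
#' @param X Feature matrix with `d` columns.
#' @return `n x n_machines` matrix of decision values.
#' @export
svm_decision <- function(fit, X) {
  if (ncol(X) != fit$d) stop("feature width mismatch")
  matrix(vapply(fit$machines, function(m) as.numeric(X %*% m$w + m$b),
                numeric(nrow(X))), nrow = nrow(X))
}

#' Predict labels with a linear SVM
#' @param object A `linear_svm`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Integer labels.
#' @export
predict.linear_svm <- function(object, X, ...) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  dv <- svm_decision(object, X)
  if (length(object$classes) == 2L)
    ifelse(dv[, 1] > 0, object$classes[2], object$classes[1])
  else
    object$classes[max.col(dv)]
}
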