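#' Confusion matrix with predicted-label rows
#'
#' Rows index the predicted label, columns the true label.
#'
#' @param y_true,y_pred Equal-length integer label vectors (`0 .. K-1`).
#' @param n_classes Number of classes `K`; inferred if missing.
#' @return `K x K` integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, n_classes = NULL) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred))
    stop("label vectors differ in length")
  if (is.null(n_classes)) n_classes <- max(y_true, y_pred) + 1L
  if (any(c(y_true, y_pred) < 0L) || any(c(y_true, y_pred) >= n_classes))
    stop("label outside 0 .. K-1")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(pred = seq_len(n_classes) - 1L,
                               true = seq_len(n_classes) - 1L))
  for (i in seq_along(y_true))
    cm[y_pred[i] + 1L, y_true[i] + 1L] <- cm[y_pred[i] + 1L,
                                             y_true[i] + 1L] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Classification accuracy of a confusion matrix
#'
#' `trace / total`, the multiclass generalization of
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm A square count matrix.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(cm))) / total
}

#' Chance-corrected kappa from an accuracy
#'
#' `kappa = (p0 - pe) / (1 - pe)` with the chance level fixed at
#' `pe = 1/K` for a `K`-class task (the fixed-marginal reading of
#' "random classification accuracy"; back-computation against the
#' published binary/three-class values confirms this form).
#'
#' @param p0 Observed accuracy in `[0, 1]`.
#' @param n_classes Number of classes `K >= 2`.
#' @return Kappa value.
#' @export
kappa_score <- function(p0, n_classes) {
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  pe <- 1 / n_classes
  (p0 - pe) / (1 - pe)
}

#' Cohen's kappa of a confusion matrix
#'
#' @param cm A square count matrix (rows predicted, columns true).
#' @param pe `"uniform"` (default) uses `pe = 1/K`; `"marginal"` uses
#'   the classical Cohen expected agreement from the matrix marginals.
#' @return Kappa value.
#' @export
cohen_kappa <- function(cm, pe = c("uniform", "marginal")) {
  pe <- match.arg(pe)
  cm <- as.matrix(cm)
  p0 <- accuracy(cm)
  pe_val <- if (pe == "uniform") 1 / nrow(cm)
  else sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  (p0 - pe_val) / (1 - pe_val)
}

#' Two-sided paired t-test with a degenerate-variance guard
#'
#' @param acc_a,acc_b Equal-length (>= 2) per-unit accuracy vectors.
#' @return List with elements `t` and `p`.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2L)
    stop("need two equal-length vectors of length >= 2")
  d <- acc_a - acc_b
  if (stats::sd(d) < 1e-12)
    stop("degenerate paired t-test: zero difference variance")
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Stratified k-fold partition
#'
#' @param labels Integer label vector.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold assignment (1..k) per trial; folds are disjoint,
#'   cover every trial, and are class-balanced within one trial.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer trials than folds")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# log-variance CSP features (classical baseline): 2m per OvR model
csp_logvar_features <- function(models, epochs, m = 1L) {
  vc <- extract_virtual_channels(models, epochs, m)
  d <- dim(vc$data)
  feat <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      feat[i, j] <- log(stats::var(vc$data[i, j, ]) + 1e-12)
  feat
}

# Fit every model of one CV fold on the training epochs only.
# Exposed (internally) so the no-leakage property can be tested
# byte-for-byte.
fit_fold_models <- function(train, pipeline, cfg, fold_seed) {
  out <- list()
  out$csp <- fit_csp_ovr(train, shrinkage = cfg$csp$shrinkage)
  if (pipeline %in% c("mfcnn", "eeg")) {
    out$eeg_scale <- stats::sd(train$data)
    xtr <- eeg_input_tensor(train, out$eeg_scale)
    net <- build_eeg_cnn(cfg$eeg_cnn, input_shape = dim(train$data)[2:3])
    tc <- cfg$train
    tc$seed <- derive_seed(fold_seed, 11L)
    out$eeg_branch <- train_branch(net, xtr, train$labels, tc)
  }
  if (pipeline %in% c("mfcnn", "tf")) {
    xtr <- epochs_to_images(train, out$csp, cfg$csp$m, cfg$cwt)
    net <- build_tf_cnn(cfg$tf_cnn)
    tc <- cfg$train
    tc$seed <- derive_seed(fold_seed, 23L)
    out$tf_branch <- train_branch(net, xtr, train$labels, tc)
    out$train_images <- xtr
  }
  if (pipeline == "mfcnn") {
    A <- extract_features(out$eeg_branch,
                          eeg_input_tensor(train, out$eeg_scale))
    B <- extract_features(out$tf_branch, out$train_images)
    out$fusion <- fit_fusion_classifier(fuse_features(A, B), train$labels,
                                        cfg$svm)
  }
  if (pipeline == "csp") {
    feat <- csp_logvar_features(out$csp, train, cfg$csp$m)
    out$baseline <- fit_fusion_classifier(feat, train$labels, cfg$svm)
  }
  out$train_images <- NULL
  out
}

default_cv_config <- function(n_classes, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  wm <- if (profile == "desk") 0.125 else 1
  tr <- if (profile == "desk")
    train_config(lr = 1e-3, epochs = 10L, batch_size = 16L)
  else train_config()
  list(csp = list(m = 1L, shrinkage = 1e-6),
       cwt = cwt_config(),
       eeg_cnn = eeg_cnn_config(n_classes = n_classes),
       tf_cnn = tf_cnn_config(n_classes = n_classes,
                              width_multiplier = wm),
       train = tr,
       svm = list(kernel = "linear", C = 1),
       profile = profile)
}

#' Five-fold cross-validated evaluation of a decoding pipeline
#'
#' Stratified folds are drawn from the seed; within every fold, CSP
#' models, branch networks and the fusion classifier (with its feature
#' scaler) are fit on the training fold only, then the held-out fold is
#' scored. Per-fold accuracy, kappa and confusion matrices are
#' aggregated into their means.
#'
#' @param epochs A preprocessed [eeg_epochs] object.
#' @param pipeline One of `"mfcnn"` (dual-branch fusion), `"eeg"` or
#'   `"tf"` (single branch softmax), `"csp"` (log-variance baseline).
#' @param config Pipeline configuration; `NULL` selects
#'   `default_cv_config` for the given profile.
#' @param folds Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment and all branch
#'   training.
#' @param profile `"desk"` (reduced-width networks, lr 1e-3) or
#'   `"full"` (reference widths, lr 0.01).
#' @return Object of class `eval_report`.
#' @export
five_fold_cv <- function(epochs, pipeline = c("mfcnn", "eeg", "tf", "csp"),
                         config = NULL, folds = 5L, seed = 1L,
                         profile = c("desk", "full")) {
  pipeline <- match.arg(pipeline)
  n_classes <- length(unique(epochs$labels))
  if (is.null(config))
    config <- default_cv_config(n_classes, match.arg(profile))
  fold_id <- make_folds(epochs$labels, folds, seed)
  per_fold <- list()
  cm_total <- NULL
  for (f in seq_len(folds)) {
    train <- subset_trials(epochs, which(fold_id != f))
    test <- subset_trials(epochs, which(fold_id == f))
    fold_seed <- derive_seed(seed, 1000L + f)
    fits <- fit_fold_models(train, pipeline, config, fold_seed)
    res <- score_fold(fits, pipeline, train, test, config)
    cm <- confusion(test$labels, res$pred, n_classes)
    acc <- accuracy(cm)
    entry <- list(fold = f, accuracy = acc,
                  kappa = kappa_score(acc, n_classes), confusion = cm)
    if (!is.null(res$eeg_pred))
      entry$eeg_accuracy <- mean(res$eeg_pred == test$labels)
    if (!is.null(res$tf_pred))
      entry$tf_accuracy <- mean(res$tf_pred == test$labels)
    per_fold[[f]] <- entry
    cm_total <- if (is.null(cm_total)) cm else cm_total + cm
  }
  accs <- vapply(per_fold, `[[`, numeric(1), "accuracy")
  structure(list(
    pipeline = pipeline, per_fold = per_fold,
    mean_accuracy = mean(accs),
    mean_kappa = mean(vapply(per_fold, `[[`, numeric(1), "kappa")),
    confusion = cm_total,
    mean_eeg_accuracy = mean_or_null(per_fold, "eeg_accuracy"),
    mean_tf_accuracy = mean_or_null(per_fold, "tf_accuracy"),
    comparisons = list(),
    config_snapshot = config, seed = seed, folds = folds,
    n_classes = n_classes), class = "eval_report")
}

mean_or_null <- function(per_fold, field) {
  v <- unlist(lapply(per_fold, function(e) e[[field]]))
  if (is.null(v)) NULL else mean(v)
}

score_fold <- function(fits, pipeline, train, test, cfg) {
  out <- list()
  if (pipeline == "csp") {
    feat <- csp_logvar_features(fits$csp, test, cfg$csp$m)
    out$pred <- predict(fits$baseline, feat)
    return(out)
  }
  if (pipeline %in% c("mfcnn", "eeg")) {
    xte <- eeg_input_tensor(test, fits$eeg_scale)
    out$eeg_pred <- predict(fits$eeg_branch, xte)
  }
  if (pipeline %in% c("mfcnn", "tf")) {
    ite <- epochs_to_images(test, fits$csp, cfg$csp$m, cfg$cwt)
    out$tf_pred <- predict(fits$tf_branch, ite)
  }
  if (pipeline == "eeg") out$pred <- out$eeg_pred
  if (pipeline == "tf") out$pred <- out$tf_pred
  if (pipeline == "mfcnn") {
    A <- extract_features(fits$eeg_branch,
                          eeg_input_tensor(test, fits$eeg_scale))
    B <- extract_features(fits$tf_branch, ite)
    out$pred <- predict(fits$fusion, fuse_features(A, B))
  }
  out
}

#' Classical CSP log-variance baseline under five-fold CV
#'
#' Per fold: one-vs-rest CSP fit on the training trials, features are
#' the log-variances of the `2m` virtual channels per model, classified
#' with a standardized linear SVM.
#'
#' @param epochs A preprocessed [eeg_epochs] object.
#' @param m Filters kept from each end (default 1).
#' @param seed Integer seed.
#' @param folds Number of folds (default 5).
#' @param config Optional configuration (see [five_fold_cv()]).
#' @return An `eval_report`.
#' @export
csp_baseline <- function(epochs, m = 1L, seed = 1L, folds = 5L,
                         config = NULL) {
  if (is.null(config)) {
    config <- default_cv_config(length(unique(epochs$labels)))
    config$csp$m <- as.integer(m)
  }
  five_fold_cv(epochs, "csp", config, folds, seed)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> pipeline=%s, %d-fold CV, seed=%d\n",
              x$pipeline, x$folds, x$seed))
  cat(sprintf("  mean accuracy: %.4f   mean kappa: %.4f\n",
              x$mean_accuracy, x$mean_kappa))
  if (!is.null(x$mean_eeg_accuracy))
    cat(sprintf("  raw-EEG branch accuracy: %.4f\n", x$mean_eeg_accuracy))
  if (!is.null(x$mean_tf_accuracy))
    cat(sprintf("  TF-image branch accuracy: %.4f\n", x$mean_tf_accuracy))
  cat("  pooled confusion (rows = predicted, cols = true):\n")
  print(unclass(x$confusion))
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  rep <- list(
    pipeline = report$pipeline, seed = report$seed, folds = report$folds,
    n_classes = report$n_classes,
    mean_accuracy = report$mean_accuracy,
    mean_kappa = report$mean_kappa,
    mean_eeg_accuracy = report$mean_eeg_accuracy,
    mean_tf_accuracy = report$mean_tf_accuracy,
    per_fold = lapply(report$per_fold, function(e) {
      e$confusion <- unclass(e$confusion)
      e
    }),
    confusion = unclass(report$confusion))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
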