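# brute-force generalized eigendecomposition oracle on the same shrunk,
# trace-normalized covariances the implementation sees
oracle_csp <- function(epochs, positive, shrinkage = 1e-6) {
  M <- dim(epochs$data)[2]
  avg <- function(idx) {
    C <- matrix(0, M, M)
    for (i in idx) {
      E <- trial_matrix(epochs, i)
      Ci <- E %*% t(E)
      C <- C + Ci / sum(diag(Ci))
    }
    C <- C / length(idx)
    (1 - shrinkage) * C + shrinkage * sum(diag(C)) / M * diag(M)
  }
  Cp <- avg(which(epochs$labels == positive))
  Cn <- avg(which(epochs$labels != positive))
  # solve Cp v = lambda (Cp + Cn) v directly
  gev <- eigen(solve(Cp + Cn) %*% Cp)
  ord <- order(Re(gev$values), decreasing = TRUE)
  list(values = Re(gev$values)[ord],
       vectors = Re(gev$vectors)[, ord, drop = FALSE],
       Cp = Cp, Cn = Cn)
}

test_that("two-channel toy recovers the analytic eigenvalue 0.8", {
  e <- make_diag_epochs(c(4, 1), c(1, 4), n_per_class = 250L, seed = 3L)
  m <- fit_csp(e, 0L)
  expect_equal(m$eigenvalues[1], 0.8, tolerance = 0.05)
  expect_equal(m$eigenvalues[2], 0.2, tolerance = 0.05)
  # projected per-filter variance pairs match (lambda, 1 - lambda)
  vp <- vn <- matrix(0, 2, 0)
  for (i in which(e$labels == 0L))
    vp <- cbind(vp, apply(project(m, trial_matrix(e, i)), 1, var))
  for (i in which(e$labels == 1L))
    vn <- cbind(vn, apply(project(m, trial_matrix(e, i)), 1, var))
  ratio <- rowMeans(vp) / (rowMeans(vp) + rowMeans(vn))
  expect_equal(ratio, m$eigenvalues, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("identical class distributions give eigenvalues near 0.5", {
  e <- make_diag_epochs(c(1, 1, 1), c(1, 1, 1), n_per_class = 200L,
                        seed = 8L)
  m <- fit_csp(e, 0L)
  expect_true(all(abs(m$eigenvalues - 0.5) < 0.05))
})

test_that("CSP matches the brute-force generalized eigendecomposition", {
  for (seed in 1:3) {
    e <- make_synth(n_trials = 15L, n_channels = 6L, erd_depth = 0.6,
                    seed = seed)
    m <- fit_csp(e, 0L)
    o <- oracle_csp(e, 0L)
    expect_equal(m$eigenvalues, o$values, tolerance = 1e-6)
    # filters match oracle eigenvectors up to per-row sign/scale
    for (j in 1:6) {
      w <- m$W[j, ]
      v <- o$vectors[, j]
      cosang <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
      expect_gt(cosang, 1 - 1e-6)
    }
    # simultaneous diagonalization and eigenvalue pairing
    Dp <- m$W %*% o$Cp %*% t(m$W)
    Dn <- m$W %*% o$Cn %*% t(m$W)
    expect_lt(max(abs(Dp - diag(diag(Dp)))), 1e-8)
    expect_lt(max(abs(Dn - diag(diag(Dn)))), 1e-8)
    expect_lt(max(abs(diag(Dp) + diag(Dn) - 1)), 1e-10)
    expect_lt(max(abs(diag(Dp) - m$eigenvalues)), 1e-10)
  }
})

test_that("one-vs-rest returns one model per class (single model when binary)", {
  e3 <- make_synth(n_classes = 3L, n_trials = 10L, seed = 2L)
  mods <- fit_csp_ovr(e3)
  expect_length(mods, 3L)
  expect_equal(vapply(mods, `[[`, integer(1), "positive_class"), 0:2)

  e2 <- make_synth(n_classes = 2L, n_trials = 10L, seed = 2L)
  expect_length(fit_csp_ovr(e2), 1L)

  few <- subset_trials(e3, c(1L, which(e3$labels == 1L),
                             which(e3$labels == 2L)))
  expect_error(fit_csp_ovr(few), ">= 2 trials")
})

test_that("each OvR model is most discriminative for its own class", {
  e <- make_synth(n_classes = 3L, n_trials = 25L, erd_depth = 0.7,
                  seed = 5L)
  mods <- fit_csp_ovr(e)
  # mean log-variance of each model's top filter, per true class
  lv <- matrix(0, 3, 3)  # model x class
  for (k in 1:3) for (cl in 0:2) {
    idx <- which(e$labels == cl)
    lv[k, cl + 1] <- mean(vapply(idx, function(i)
      log(var(project(mods[[k]], trial_matrix(e, i))[1, ])), numeric(1)))
  }
  # model k's top filter mixes the non-k sources, all of which are at
  # full (non-ERD) amplitude only during class-k trials, so the top
  # filter's output variance peaks on the model's own class
  for (k in 1:3)
    expect_equal(which.max(lv[k, ]), k)
})

test_that("projection is an exact linear matrix product", {
  set.seed(1)
  W <- matrix(rnorm(16), 4, 4)
  E <- matrix(rnorm(40), 4, 10)
  m <- structure(list(W = W, eigenvalues = rep(0.5, 4),
                      positive_class = 0L, trace_normalized = TRUE),
                 class = "csp_model")
  # naive double-loop oracle
  Z <- matrix(0, 4, 10)
  for (i in 1:4) for (j in 1:10) Z[i, j] <- sum(W[i, ] * E[, j])
  expect_lt(max(abs(project(m, E) - Z)), 1e-12)
  m$W <- diag(4)
  expect_identical(project(m, E), E)
  expect_identical(project(m, E * 0), E * 0)
  expect_error(project(m, E[1:3, ]), "channel count")
})

test_that("virtual-channel extraction keeps head/tail rows per model", {
  e <- make_synth(n_classes = 3L, n_trials = 4L, seed = 7L)
  mods <- fit_csp_ovr(e)
  vc <- extract_virtual_channels(mods, e, m = 1L)
  expect_equal(dim(vc$data), c(12L, 6L, 1000L))
  expect_equal(vc$source_rows, c(1L, 20L))

  # identity W: virtual channels equal physical channels 1 and M
  id <- mods[1]
  id[[1]]$W <- diag(20)
  vi <- extract_virtual_channels(id, e, m = 1L)
  expect_equal(vi$data[2, 1, ], e$data[2, 1, ])
  expect_equal(vi$data[2, 2, ], e$data[2, 20, ])

  expect_error(extract_virtual_channels(mods, e, m = 10L), "2m")
})

test_that("the top filter recovers the ground-truth discriminative source", {
  cfg <- synth_config(n_classes = 2L, n_trials_per_class = 30L,
                      erd_depth = 0.8, seed = 12L, keep_sources = TRUE)
  e <- generate_mi_dataset(cfg)
  m <- fit_csp(e, 0L)
  # for the binary model (positive = class 0), the top filter captures
  # the source attenuated in the *other* class (source 1), the last
  # filter the class-0 source; correlate each filter on the trials
  # where its source is at full (non-ERD) amplitude
  cors <- c(top = 0, bottom = 0)
  cl0 <- which(e$labels == 0L)[1:10]
  cl1 <- which(e$labels == 1L)[1:10]
  for (j in seq_len(10)) {
    Z0 <- project(m, trial_matrix(e, cl0[j]))
    cors["top"] <- cors["top"] +
      abs(cor(Z0[1, ], e$ground_truth$sources[cl0[j], 2, ])) / 10
    Z1 <- project(m, trial_matrix(e, cl1[j]))
    cors["bottom"] <- cors["bottom"] +
      abs(cor(Z1[20, ], e$ground_truth$sources[cl1[j], 1, ])) / 10
  }
  expect_gt(cors["top"], 0.8)
  expect_gt(cors["bottom"], 0.8)
})
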