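# independent convolution/pooling shape oracle
conv_out <- function(n, k, stride = 1L, pad = 0L)
  (n + 2L * pad - k) %/% stride + 1L

test_that("network shapes match the convolution-arithmetic oracle", {
  net <- build_eeg_cnn(eeg_cnn_config(n_classes = 2L),
                       input_shape = c(20L, 1000L))
  shapes <- mifusion:::net_shapes(net)
  t1 <- conv_out(1000L, 3L)              # 998
  p1 <- conv_out(t1, 2L, 2L)             # 499
  t2 <- conv_out(p1, 3L)                 # 497
  p2 <- conv_out(t2, 2L, 2L)             # 248
  expect_equal(shapes[[1]][2], t1)
  expect_equal(shapes[[3]][2], p1)
  expect_equal(shapes[[4]][2], t2)
  expect_equal(shapes[[6]][2], p2)
  expect_equal(shapes[[7]], 32L * p2)    # flatten
  expect_equal(net$feature_dim, 128L)

  tf <- build_tf_cnn(tf_cnn_config(n_classes = 3L,
                                   width_multiplier = 0.125))
  tfs <- mifusion:::net_shapes(tf)
  # 64 -> 32 -> 16 -> 8 -> 4 -> 2 through the five pooling stages
  flat_idx <- which(vapply(tf$layers, function(l) l$type == "flatten",
                           logical(1)))
  expect_equal(tfs[[flat_idx - 1L]][1:2], c(2L, 2L))
  expect_equal(sum(vapply(tf$layers, function(l) l$type == "conv",
                          logical(1))), 13L)
  expect_equal(sum(vapply(tf$layers, function(l) l$type == "dense",
                          logical(1))), 3L)

  eighth <- vapply(tf$layers[vapply(tf$layers, function(l)
    l$type == "conv", logical(1))], `[[`, integer(1), "out_ch")
  expect_equal(eighth,
               as.integer(c(64, 64, 128, 128, 256, 256, 256, 512, 512,
                            512, 512, 512, 512) / 8))

  expect_error(build_eeg_cnn(eeg_cnn_config(n_classes = 2L),
                             input_shape = c(20L, 4L)), "too small")
  expect_error(tf_cnn_config(width_multiplier = 0), "positive")
})

test_that("relu and softplus behave as defined", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(0), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(mifusion:::apply_act(c(-3, 0, 2.5), "softplus"),
               log1p(exp(c(-3, 0, 2.5))))
})

test_that("backpropagation matches numeric gradients (double path)", {
  withr::local_options(mifusion.precision = "double")
  set.seed(2)
  net <- build_eeg_cnn(eeg_cnn_config(filters = c(2L, 3L), fc_units = 5L,
                                      n_classes = 2L),
                       input_shape = c(3L, 20L))
  net <- mifusion:::init_net(net, 42L)
  x <- array(rnorm(3 * 20 * 4), dim = c(1, 20, 3, 4))
  y <- c(0L, 1L, 0L, 1L)
  loss_of <- function(n) {
    fw <- mifusion:::net_forward(n, x)
    mifusion:::softmax_ce(fw$out, y)$loss
  }
  fw <- mifusion:::net_forward(net, x, keep_cache = TRUE)
  ce <- mifusion:::softmax_ce(fw$out, y)
  gr <- mifusion:::net_backward(net, fw$caches, ce$dlogits)
  eps <- 1e-6
  for (li in seq_along(net$layers)) {
    if (is.null(net$layers[[li]]$W)) next
    for (rep in 1:3) {
      i <- sample(length(net$layers[[li]]$W), 1L)
      np <- net; np$layers[[li]]$W[i] <- np$layers[[li]]$W[i] + eps
      nm <- net; nm$layers[[li]]$W[i] <- nm$layers[[li]]$W[i] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(gr[[li]]$W[i], num, tolerance = 1e-5)
    }
  }
})

test_that("single- and double-precision forward passes agree closely", {
  set.seed(3)
  net <- build_tf_cnn(tf_cnn_config(n_classes = 2L,
                                    width_multiplier = 0.06,
                                    fc_units = 16L),
                      input_shape = c(32L, 32L, 3L))
  net <- mifusion:::init_net(net, 7L)
  x <- array(runif(32 * 32 * 3 * 2), dim = c(32, 32, 3, 2))
  f32 <- mifusion:::net_forward(net, x)$out
  f64 <- withr::with_options(list(mifusion.precision = "double"),
                             mifusion:::net_forward(net, x)$out)
  expect_lt(max(abs(f32 - f64)) / max(abs(f64)), 1e-4)
})

test_that("training is deterministic, recorded, and NaN-guarded", {
  set.seed(5)
  x <- array(rnorm(6 * 40 * 20), dim = c(1, 40, 6, 20))
  y <- rep(0:1, 10)
  net <- build_eeg_cnn(eeg_cnn_config(filters = c(4L, 4L),
                                      fc_units = 8L, n_classes = 2L),
                       input_shape = c(6L, 40L))
  tc <- train_config(lr = 1e-3, epochs = 3L, batch_size = 8L, seed = 9L)
  b1 <- train_branch(net, x, y, tc)
  b2 <- train_branch(net, x, y, tc)
  expect_identical(b1$net, b2$net)
  expect_equal(nrow(b1$history), 3L)

  b0 <- train_branch(net, x, y, train_config(epochs = 0L, seed = 9L))
  expect_equal(nrow(b0$history), 0L)
  expect_false(is.null(b0$net$layers[[1]]$W))

  expect_error(train_branch(net, x, rep(0L, 20), tc), "two classes")
  expect_error(train_branch(net, x, y, train_config(lr = 1e12,
                                                    epochs = 2L,
                                                    batch_size = 8L,
                                                    seed = 9L)),
               "NaN|Inf")
})

test_that("one small Adam step decreases the batch loss", {
  set.seed(6)
  x <- array(rnorm(6 * 40 * 16), dim = c(1, 40, 6, 16))
  y <- rep(0:1, 8)
  net <- build_eeg_cnn(eeg_cnn_config(filters = c(4L, 4L), fc_units = 8L,
                                      n_classes = 2L),
                       input_shape = c(6L, 40L))
  net <- mifusion:::init_net(net, 11L)
  st <- mifusion:::adam_init(net)
  fw <- mifusion:::net_forward(net, x, keep_cache = TRUE)
  ce <- mifusion:::softmax_ce(fw$out, y)
  gr <- mifusion:::net_backward(net, fw$caches, ce$dlogits)
  up <- mifusion:::adam_step(net, gr, st, lr = 1e-3)
  loss2 <- mifusion:::softmax_ce(mifusion:::net_forward(up$net, x)$out,
                                 y)$loss
  expect_lt(loss2, ce$loss)
})

test_that("separable toy images are fit to >= 99% accuracy quickly", {
  set.seed(7)
  n <- 24L
  x <- array(0, dim = c(64, 64, 3, n))
  y <- rep(0:1, n / 2)
  for (i in seq_len(n))
    x[, , , i] <- ifelse(y[i] == 1L, 0.8, 0.2) +
      array(rnorm(64 * 64 * 3, sd = 0.02), dim = c(64, 64, 3))
  net <- build_tf_cnn(tf_cnn_config(n_classes = 2L,
                                    width_multiplier = 0.0625,
                                    fc_units = 32L))
  tb <- train_branch(net, x, y, train_config(lr = 1e-3, epochs = 10L,
                                             batch_size = 8L, seed = 3L))
  expect_gte(tail(tb$history$accuracy, 1), 0.99)
})

test_that("feature extraction is deterministic with the configured width", {
  set.seed(8)
  x <- array(rnorm(6 * 40 * 10), dim = c(1, 40, 6, 10))
  y <- rep(0:1, 5)
  net <- build_eeg_cnn(eeg_cnn_config(filters = c(4L, 4L), fc_units = 8L,
                                      n_classes = 2L),
                       input_shape = c(6L, 40L))
  tb <- train_branch(net, x, y, train_config(lr = 1e-3, epochs = 2L,
                                             batch_size = 4L, seed = 2L))
  f1 <- extract_features(tb, x)
  f2 <- extract_features(tb, x)
  expect_identical(f1, f2)
  expect_equal(dim(f1), c(10L, 8L))
  expect_true(all(f1 >= 0))  # post-ReLU activations
  expect_error(extract_features(tb, x[, 1:20, , , drop = FALSE]),
               "shape")
})

test_that("each branch beats chance clearly on easy synthetic data", {
  accs_eeg <- c(); accs_tf <- c()
  for (s in 1:3) {
    # band-pass as the pipeline always does before the raw-EEG branch;
    # broadband 1/f noise otherwise swamps the band-limited ERD signal
    e <- preprocess(make_synth(n_trials = 30L, erd_depth = 0.8,
                               seed = s), preproc_config())
    tr_idx <- c(1:20, 31:50)
    te_idx <- setdiff(1:60, tr_idx)
    train <- subset_trials(e, tr_idx)
    test <- subset_trials(e, te_idx)
    sc <- sd(train$data)
    net <- build_eeg_cnn(eeg_cnn_config(n_classes = 2L),
                         input_shape = dim(train$data)[2:3])
    tb <- train_branch(net, mifusion:::eeg_input_tensor(train, sc),
                       train$labels,
                       train_config(lr = 1e-3, epochs = 10L,
                                    batch_size = 16L, seed = s))
    pe <- predict(tb, mifusion:::eeg_input_tensor(test, sc))
    accs_eeg <- c(accs_eeg, mean(pe == test$labels))

    mods <- fit_csp_ovr(train)
    itr <- epochs_to_images(train, mods)
    ite <- epochs_to_images(test, mods)
    ntf <- build_tf_cnn(tf_cnn_config(n_classes = 2L,
                                      width_multiplier = 0.125))
    tbf <- train_branch(ntf, itr, train$labels,
                        train_config(lr = 1e-3, epochs = 10L,
                                     batch_size = 16L, seed = s))
    accs_tf <- c(accs_tf, mean(predict(tbf, ite) == test$labels))
  }
  expect_gte(median(accs_eeg), 0.7)
  expect_gte(median(accs_tf), 0.7)
})
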