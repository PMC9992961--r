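#' Configuration of the raw-EEG convolutional branch
#'
#' Two 1-D convolution blocks along the time axis (kernel 3 x 1,
#' stride 1, valid padding) each followed by 2 x 1 stride-2 max pooling,
#' a flattening stage, one hidden fully connected layer (the penultimate
#' feature layer) and a softmax head.
#'
#' @param filters Convolution filter counts per block (default
#'   `c(16, 32)`).
#' @param kernel Temporal kernel length (default 3).
#' @param pool Pooling length and stride (default 2).
#' @param fc_units Penultimate fully connected width `m` (default 128).
#' @param n_classes Output classes.
#' @param activation `"relu"` (default) or `"softplus"`.
#' @return List of class `eeg_cnn_config`.
#' @export
eeg_cnn_config <- function(filters = c(16L, 32L), kernel = 3L, pool = 2L,
                           fc_units = 128L, n_classes = 2L,
                           activation = c("relu", "softplus")) {
  if (fc_units < n_classes) stop("fc_units must be >= n_classes")
  structure(list(filters = as.integer(filters), kernel = as.integer(kernel),
                 pool = as.integer(pool), fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes),
                 activation = match.arg(activation)),
            class = "eeg_cnn_config")
}

#' Configuration of the time-frequency image branch (VGG16 layout)
#'
#' Thirteen 3 x 3 stride-1 same-padded convolution layers with 2 x 2
#' stride-2 max pooling after the standard VGG16 stages, then three
#' fully connected layers (the second is the penultimate feature layer).
#' `width_multiplier` scales every convolutional and fully connected
#' width for desk-scale runs.
#'
#' @param n_classes Output classes.
#' @param width_multiplier Fraction of the full VGG16 widths (default 1).
#' @param fc_units Width of the two hidden FC layers; default
#'   `round(4096 * width_multiplier)`.
#' @param activation `"relu"` (default) or `"softplus"`.
#' @return List of class `tf_cnn_config`.
#' @export
tf_cnn_config <- function(n_classes = 2L, width_multiplier = 1,
                          fc_units = NULL,
                          activation = c("relu", "softplus")) {
  if (width_multiplier <= 0) stop("width_multiplier must be positive")
  if (is.null(fc_units)) fc_units <- max(4L, round(4096 * width_multiplier))
  structure(list(n_classes = as.integer(n_classes),
                 width_multiplier = width_multiplier,
                 fc_units = as.integer(fc_units),
                 activation = match.arg(activation)),
            class = "tf_cnn_config")
}

#' Training configuration (Adam)
#'
#' Adam with `beta1 = 0.9`, `beta2 = 0.999` and initial learning rate
#' 0.01 are the reference defaults; the desk-scale profile lowers the
#' rate to 1e-3.
#'
#' @param lr Initial learning rate (default 0.01).
#' @param beta1,beta2 Adam moment decays (defaults 0.9, 0.999).
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling initialization and batch order.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 0.01, beta1 = 0.9, beta2 = 0.999,
                         epochs = 50L, batch_size = 32L, seed = 1L) {
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "train_config")
}

#' Build the raw-EEG branch network
#'
#' @param config An [eeg_cnn_config()].
#' @param input_shape `c(channels, samples)` of one trial.
#' @return An (uninitialized) network specification; shapes are
#'   validated at build time.
#' @export
build_eeg_cnn <- function(config = eeg_cnn_config(),
                          input_shape = c(20L, 1000L)) {
  ch <- input_shape[1]; n <- input_shape[2]
  layers <- list()
  in_ch <- ch
  for (f in config$filters) {
    layers <- c(layers, list(
      layer_conv(in_ch, f, kh = 1L, kw = config$kernel, stride = 1L,
                 pad = 0L),
      layer_act(config$activation),
      layer_pool(kh = 1L, kw = config$pool, stride = config$pool)))
    in_ch <- f
  }
  layers <- c(layers, list(layer_flatten()))
  net <- list(layers = layers, input_shape = c(1L, n, ch),
              n_classes = config$n_classes)
  flat <- net_shapes(net)[[length(layers)]]  # validates conv arithmetic
  layers <- c(layers, list(layer_dense(flat, config$fc_units),
                           layer_act(config$activation),
                           layer_dense(config$fc_units, config$n_classes)))
  net$layers <- layers
  net$feature_layer <- length(layers) - 1L
  net$feature_dim <- config$fc_units
  net$kind <- "eeg"
  net_shapes(net)
  net
}

#' Build the time-frequency image branch network
#'
#' @param config A [tf_cnn_config()].
#' @param input_shape `c(height, width, channels)` (default 64 x 64 x 3).
#' @return An (uninitialized) network specification.
#' @export
build_tf_cnn <- function(config = tf_cnn_config(),
                         input_shape = c(64L, 64L, 3L)) {
  base <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  widths <- pmax(1L, as.integer(round(base * config$width_multiplier)))
  pool_after <- c(2L, 4L, 7L, 10L, 13L)
  layers <- list()
  in_ch <- input_shape[3]
  for (i in seq_along(widths)) {
    layers <- c(layers, list(
      layer_conv(in_ch, widths[i], kh = 3L, kw = 3L, stride = 1L,
                 pad = 1L),
      layer_act(config$activation)))
    in_ch <- widths[i]
    if (i %in% pool_after)
      layers <- c(layers, list(layer_pool(2L, 2L, 2L)))
  }
  layers <- c(layers, list(layer_flatten()))
  net <- list(layers = layers, input_shape = as.integer(input_shape),
              n_classes = config$n_classes)
  flat <- net_shapes(net)[[length(layers)]]
  layers <- c(layers, list(
    layer_dense(flat, config$fc_units), layer_act(config$activation),
    layer_dense(config$fc_units, config$fc_units),
    layer_act(config$activation),
    layer_dense(config$fc_units, config$n_classes)))
  net$layers <- layers
  net$feature_layer <- length(layers) - 1L
  net$feature_dim <- config$fc_units
  net$kind <- "tf"
  net_shapes(net)
  net
}

#' Rectified linear activation
#'
#' `max(0, a)`, elementwise. The alternative `"softplus"` form
#' `log(1 + exp(a))` is available network-wide through the branch
#' configurations' `activation` field.
#'
#' @param a Numeric input (vectorized).
#' @return `pmax(a, 0)`.
#' @export
relu <- function(a) pmax(a, 0)

# epochs (eeg_epochs) -> (1, samples, channels, trials) input tensor
eeg_input_tensor <- function(epochs, scale = 1) {
  d <- dim(epochs$data)
  x <- aperm(epochs$data, c(3L, 2L, 1L)) / scale   # samples, ch, trials
  array(x, dim = c(1L, d[3], d[2], d[1]))
}

#' Train one CNN branch
#'
#' Mini-batch Adam on softmax cross-entropy. Initialization and batch
#' order are fully determined by `train_config$seed`, so identical calls
#' reproduce identical weights.
#'
#' @param net A network specification from [build_eeg_cnn()] or
#'   [build_tf_cnn()].
#' @param inputs 4-D input tensor `(H, W, C, N)`.
#' @param labels Integer labels `0 .. K-1`, length `N`.
#' @param config A [train_config()].
#' @return Object of class `trained_branch` with the fitted weights,
#'   per-epoch `history` (loss, training accuracy) and `feature_dim`.
#' @export
train_branch <- function(net, inputs, labels, config = train_config()) {
  d <- dim(inputs)
  n <- d[4]
  labels <- as.integer(labels)
  if (length(labels) != n) stop("labels do not match the input count")
  present <- sort(unique(labels))
  if (length(present) < 2L && config$epochs > 0L)
    stop("training set must contain at least two classes")
  if (net$n_classes < max(labels) + 1L)
    stop("label outside the network's class range")
  net <- init_net(net, config$seed)
  state <- adam_init(net)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  if (config$epochs > 0L) {
    set.seed(derive_seed(config$seed, 7L))
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_hit <- 0
      for (bi in batches) {
        xb <- inputs[, , , bi, drop = FALSE]
        fw <- net_forward(net, xb, keep_cache = TRUE)
        ce <- softmax_ce(fw$out, labels[bi])
        if (!is.finite(ce$loss))
          stop(sprintf("NaN/Inf loss in epoch %d; lower the learning rate",
                       ep))
        grads <- net_backward(net, fw$caches, ce$dlogits)
        up <- adam_step(net, grads, state, config$lr, config$beta1,
                        config$beta2)
        net <- up$net; state <- up$state
        ep_loss <- ep_loss + ce$loss * length(bi)
        ep_hit <- ep_hit + sum(max.col(fw$out) - 1L == labels[bi])
      }
      history <- rbind(history,
                       data.frame(epoch = ep, loss = ep_loss / n,
                                  accuracy = ep_hit / n))
    }
  }
  structure(list(net = net, config = config, history = history,
                 feature_dim = net$feature_dim,
                 n_classes = net$n_classes),
            class = "trained_branch")
}

#' Penultimate-layer feature extraction
#'
#' Activations of the penultimate fully connected layer (after its
#' activation function), evaluated deterministically.
#'
#' @param branch A `trained_branch`.
#' @param inputs 4-D input tensor `(H, W, C, N)`.
#' @return `N x feature_dim` feature matrix.
#' @export
extract_features <- function(branch, inputs) {
  check_branch_input(branch, inputs)
  fw <- net_forward(branch$net, inputs,
                    upto = branch$net$feature_layer)
  fw$out
}

#' Class predictions of a trained branch (softmax head)
#'
#' @param object A `trained_branch`.
#' @param inputs 4-D input tensor.
#' @param ... Unused.
#' @return Integer labels `0 .. K-1`.
#' @export
predict.trained_branch <- function(object, inputs, ...) {
  check_branch_input(object, inputs)
  fw <- net_forward(object$net, inputs)
  max.col(fw$out) - 1L
}

check_branch_input <- function(branch, inputs) {
  d <- dim(inputs)
  if (length(d) != 4L || !all(d[1:3] == branch$net$input_shape))
    stop("input shape does not match the branch network")
  invisible(TRUE)
}
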