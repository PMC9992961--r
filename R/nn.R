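# Minimal deterministic CNN engine.
#
# Tensors travel through the network as column-major 4-D arrays
# (H, W, C, N); convolutions are im2col + BLAS matrix products with the
# column<->image bookkeeping in C++ (src/ops.cpp). The heavy products
# run in single precision by default (see mm below); execution is
# single-path deterministic, which the cross-validation leakage tests
# rely on.

# Matrix product dispatcher. The convolution/dense products dominate
# training cost; by default they run through single-precision BLAS
# (cpp_gemm32), which more than suffices for SGD while roughly doubling
# single-core throughput. options(mifusion.precision = "double")
# switches to the double path (used by the numeric gradient-check
# tests).
single_precision <- function()
  identical(getOption("mifusion.precision", "single"), "single")

mm <- function(A, B, ta = FALSE, tb = FALSE) {
  if (single_precision())
    return(cpp_gemm32(A, B, ta, tb))
  if (ta && !tb) crossprod(A, B)
  else if (!ta && tb) tcrossprod(A, B)
  else if (!ta && !tb) A %*% B
  else t(A) %*% t(B)
}

new_layer <- function(type, ...) c(list(type = type), list(...))

layer_conv <- function(in_ch, out_ch, kh, kw, stride = 1L, pad = 0L)
  new_layer("conv", in_ch = in_ch, out_ch = out_ch, kh = kh, kw = kw,
            stride = stride, pad = pad, W = NULL, b = NULL)
layer_pool <- function(kh, kw, stride)
  new_layer("pool", kh = kh, kw = kw, stride = stride)
layer_act <- function(fun = "relu") new_layer("act", fun = fun)
layer_flatten <- function() new_layer("flatten")
layer_dense <- function(in_dim, out_dim)
  new_layer("dense", in_dim = in_dim, out_dim = out_dim, W = NULL, b = NULL)

# shape oracle: output (H, W, C) of one layer given its input shape
layer_out_shape <- function(layer, s) {
  switch(layer$type,
    conv = {
      h <- (s[1] + 2 * layer$pad - layer$kh) %/% layer$stride + 1L
      w <- (s[2] + 2 * layer$pad - layer$kw) %/% layer$stride + 1L
      if (h < 1L || w < 1L)
        stop(sprintf("input too small for conv: %dx%d", s[1], s[2]))
      c(h, w, layer$out_ch)
    },
    pool = {
      h <- (s[1] - layer$kh) %/% layer$stride + 1L
      w <- (s[2] - layer$kw) %/% layer$stride + 1L
      if (h < 1L || w < 1L)
        stop(sprintf("input too small for pooling: %dx%d", s[1], s[2]))
      c(h, w, s[3])
    },
    act = s,
    flatten = prod(s),
    dense = {
      if (prod(s) != layer$in_dim)
        stop(sprintf("dense layer expects %d inputs, got %d",
                     layer$in_dim, prod(s)))
      layer$out_dim
    })
}

net_shapes <- function(net) {
  s <- net$input_shape
  shapes <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    s <- layer_out_shape(net$layers[[i]], s)
    shapes[[i]] <- s
  }
  shapes
}

# He-normal initialization, seeded
init_net <- function(net, seed) {
  set.seed(seed)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      fan_in <- l$kh * l$kw * l$in_ch
      l$W <- matrix(stats::rnorm(fan_in * l$out_ch, sd = sqrt(2 / fan_in)),
                    fan_in, l$out_ch)
      l$b <- rep(0, l$out_ch)
    } else if (l$type == "dense") {
      l$W <- matrix(stats::rnorm(l$in_dim * l$out_dim,
                                 sd = sqrt(2 / l$in_dim)),
                    l$in_dim, l$out_dim)
      l$b <- rep(0, l$out_dim)
    }
    net$layers[[i]] <- l
  }
  net
}

apply_act <- function(x, fun) {
  if (fun == "relu") pmax(x, 0)
  else if (fun == "softplus") ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
  else stop("unknown activation: ", fun)
}

act_grad <- function(x, fun) {
  if (fun == "relu") (x > 0) * 1
  else 1 / (1 + exp(-pmin(pmax(x, -30), 30)))
}

# Forward pass. x: (H, W, C, N) array (or N x D matrix once flattened).
# Returns list(out = logits N x K, caches, feature = activations at
# net$feature_layer as N x D matrix).
net_forward <- function(net, x, keep_cache = FALSE, upto = NA_integer_) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  feature <- NULL
  last <- if (is.na(upto)) length(net$layers) else upto
  for (i in seq_len(last)) {
    l <- net$layers[[i]]
    if (l$type == "conv") {
      d <- dim(x)
      oh <- (d[1] + 2 * l$pad - l$kh) %/% l$stride + 1L
      ow <- (d[2] + 2 * l$pad - l$kw) %/% l$stride + 1L
      if (single_precision()) {
        out <- cpp_conv_forward32(x, as.integer(d), l$W, l$b, l$kh,
                                  l$kw, l$stride, l$pad)
        if (keep_cache) caches[[i]] <- list(input = x, in_dims = d,
                                            oh = oh, ow = ow)
      } else {
        col <- cpp_im2col(x, as.integer(d), l$kh, l$kw, l$stride, l$pad)
        out <- sweep(col %*% l$W, 2L, l$b, `+`)
        if (keep_cache) caches[[i]] <- list(col = col, in_dims = d,
                                            oh = oh, ow = ow)
      }
      x <- aperm(array(out, dim = c(oh, ow, d[4], l$out_ch)),
                 c(1L, 2L, 4L, 3L))
    } else if (l$type == "pool") {
      d <- dim(x)
      p <- cpp_maxpool(x, as.integer(d), l$kh, l$kw, l$stride)
      if (keep_cache) caches[[i]] <- list(argmax = p$argmax,
                                          in_len = prod(d))
      x <- array(p$out, dim = p$odims)
    } else if (l$type == "act") {
      if (keep_cache) caches[[i]] <- list(pre = x)
      x <- apply_act(x, l$fun)
    } else if (l$type == "flatten") {
      d <- dim(x)
      if (keep_cache) caches[[i]] <- list(in_dims = d)
      x <- t(array(x, dim = c(prod(d[1:3]), d[4])))  # N x D
    } else if (l$type == "dense") {
      if (keep_cache) caches[[i]] <- list(input = x)
      x <- sweep(mm(x, l$W), 2L, l$b, `+`)
    }
    if (!is.null(net$feature_layer) && i == net$feature_layer)
      feature <- x
  }
  list(out = x, caches = caches, feature = feature)
}

# Backward pass from dlogits (N x K); returns list of per-layer grads.
net_backward <- function(net, caches, dlogits) {
  grads <- vector("list", length(net$layers))
  g <- dlogits
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- caches[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(W = mm(cc$input, g, ta = TRUE), b = colSums(g))
      g <- mm(g, l$W, tb = TRUE)
    } else if (l$type == "flatten") {
      d <- cc$in_dims
      g <- array(t(g), dim = d)
    } else if (l$type == "act") {
      g <- g * act_grad(cc$pre, l$fun)
    } else if (l$type == "pool") {
      g <- cpp_maxpool_backward(cc$argmax, g, cc$in_len)
      g <- array(g, dim = caches_in_dims(caches, net, i))
    } else if (l$type == "conv") {
      d <- cc$in_dims
      n <- d[4]
      gmat <- aperm(g, c(1L, 2L, 4L, 3L))
      dim(gmat) <- c(cc$oh * cc$ow * n, l$out_ch)
      if (single_precision()) {
        r <- cpp_conv_backward32(cc$input, as.integer(d), l$W, gmat,
                                 l$kh, l$kw, l$stride, l$pad)
        grads[[i]] <- list(W = r$dW, b = r$db)
        g <- array(r$dx, dim = d)
      } else {
        grads[[i]] <- list(W = crossprod(cc$col, gmat),
                           b = colSums(gmat))
        dcol <- tcrossprod(gmat, l$W)
        g <- array(cpp_col2im(dcol, as.integer(d), l$kh, l$kw, l$stride,
                              l$pad), dim = d)
      }
    }
  }
  grads
}

# input dims of layer i (for reshaping pool gradients)
caches_in_dims <- function(caches, net, i) {
  # the pool cache stores only the flat length; recover dims from the
  # previous layer's cached tensor
  prev <- caches[[i - 1L]]
  if (!is.null(prev$pre)) dim(prev$pre)
  else stop("pooling must follow an activation layer in this engine")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy + gradient wrt logits
softmax_ce <- function(logits, labels01) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels01 + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  onehot <- matrix(0, n, ncol(logits))
  onehot[idx] <- 1
  list(loss = loss, dlogits = (p - onehot) / n)
}

adam_init <- function(net) {
  st <- list(t = 0L, m = list(), v = list())
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (!is.null(l$W))
      st$m[[as.character(i)]] <- list(W = l$W * 0, b = l$b * 0)
  }
  st$v <- st$m
  st
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$layers)) {
    key <- as.character(i)
    if (is.null(state$m[[key]])) next
    for (p in c("W", "b")) {
      g <- grads[[i]][[p]]
      state$m[[key]][[p]] <- beta1 * state$m[[key]][[p]] + (1 - beta1) * g
      state$v[[key]][[p]] <- beta2 * state$v[[key]][[p]] +
        (1 - beta2) * g * g
      mh <- state$m[[key]][[p]] / bc1
      vh <- state$v[[key]][[p]] / bc2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * mh / (sqrt(vh) + eps)
    }
  }
  list(net = net, state = state)
}
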