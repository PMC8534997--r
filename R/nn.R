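# Minimal neural-network engine for the gait classifier.
#
# Activations are stored channels-first: a convolutional activation is a
# (channels x positions) matrix whose columns are indexed by (y, x, batch)
# — y fastest — and dense activations are (features x batch) matrices.
# With channels as rows, R's column-major recycling applies per-channel
# scale/shift vectors without any broadcast allocation, and convolutions
# reduce to a column gather plus one BLAS matrix multiply (im2col).
# Gradients are checked against finite differences in the test suite.

conv_tensor <- function(x, h, w, b) list(x = x, h = h, w = w, b = b)

# Glorot-uniform initialization, drawn from the current RNG stream.
glorot <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Convolution weights are stored (cout x ksize^2 * cin); column blocks of
# width cin correspond to kernel offsets in column-major (dy, dx) order.
layer_conv <- function(cin, cout, ksize = 3L, stride = 2L) {
  list(type = "conv", cin = cin, cout = cout, ksize = ksize, stride = stride,
       W = glorot(cout, ksize * ksize * cin, ksize * ksize * cin,
                  ksize * ksize * cout),
       b = numeric(cout))
}

# Batch normalization with an optionally fused rectified-linear activation
# (`act = "relu"`), saving a full memory pass over the activation tensor.
# The moving statistics are zero-initialized exponential averages debiased
# by 1 - momentum^t at inference (as in Adam's moment correction), so they
# are unbiased estimates of the batch statistics from the very first update
# step — short training schedules see no cold-start transient.
layer_bn <- function(c, momentum = 0.9, eps = 1e-3, act = "linear") {
  list(type = "bn", c = c, momentum = momentum, eps = eps, act = act,
       gamma = rep(1, c), beta = numeric(c),
       mmean = numeric(c), mvar = numeric(c), t = 0L)
}

# Debiased moving mean/variance; before any update fall back to (0, 1).
bn_moving_stats <- function(layer) {
  if (layer$t == 0L) return(list(mean = numeric(layer$c), var = rep(1, layer$c)))
  corr <- 1 - layer$momentum^layer$t
  list(mean = layer$mmean / corr, var = layer$mvar / corr)
}

layer_relu <- function() list(type = "relu")
layer_flatten <- function() list(type = "flatten")

# Dense weights are (nout x nin); activations flow as (features x batch).
layer_dense <- function(nin, nout) {
  list(type = "dense", nin = nin, nout = nout,
       W = glorot(nout, nin, nin, nout), b = numeric(nout))
}

layer_dropout <- function(rate = 0.5) list(type = "dropout", rate = rate)

# "same" padding before a strided convolution: output = ceil(input / stride).
conv_geometry <- function(h, w, ksize, stride) {
  oh <- ceiling(h / stride); ow <- ceiling(w / stride)
  pad_h <- max((oh - 1) * stride + ksize - h, 0)
  pad_w <- max((ow - 1) * stride + ksize - w, 0)
  list(oh = oh, ow = ow,
       pt = pad_h %/% 2, pb = pad_h - pad_h %/% 2,
       pl = pad_w %/% 2, pr = pad_w - pad_w %/% 2)
}

conv_forward <- function(layer, tin) {
  g <- conv_geometry(tin$h, tin$w, layer$ksize, layer$stride)
  P <- cpp_im2col(tin$x, tin$h, tin$w, tin$b, layer$ksize, layer$stride,
                  g$pt, g$pl)
  Y <- layer$W %*% P
  # in front of batch norm the bias is inert and its gradient vanishes, so
  # it stays at zero during training; skip the add while it is all-zero
  if (any(layer$b != 0)) Y <- Y + layer$b
  list(out = conv_tensor(Y, g$oh, g$ow, tin$b),
       cache = list(P = P, tin_dim = c(tin$h, tin$w, tin$b), geom = g))
}

conv_backward <- function(layer, cache, dout) {
  dY <- dout$x
  grads <- list(W = tcrossprod(dY, cache$P), b = rowSums(dY))
  dP <- crossprod(layer$W, dY)
  d <- cache$tin_dim
  g <- cache$geom
  dX <- cpp_col2im(dP, d[1L], d[2L], d[3L], layer$ksize, layer$stride,
                   g$pt, g$pl)
  list(dinput = conv_tensor(dX, d[1L], d[2L], d[3L]), grads = grads)
}

tensor_mat <- function(x) if (is.list(x)) x$x else x
with_mat <- function(x, m) { if (is.list(x)) { x$x <- m; x } else m }

bn_forward <- function(layer, tin, training) {
  M <- tensor_mat(tin)
  relu <- identical(layer$act, "relu")
  if (training) {
    r <- cpp_bn_forward(M, layer$gamma, layer$beta, layer$eps, relu)
    mom <- layer$momentum
    updates <- list(mmean = mom * layer$mmean + (1 - mom) * r$mu,
                    mvar = mom * layer$mvar + (1 - mom) * r$va)
    list(out = with_mat(tin, r$Y),
         cache = list(xhat = r$xhat, istd = r$istd, training = TRUE),
         updates = updates)
  } else {
    st <- bn_moving_stats(layer)
    scale <- layer$gamma / sqrt(st$var + layer$eps)
    Y <- cpp_bn_infer(M, scale, layer$beta - st$mean * scale, relu)
    list(out = with_mat(tin, Y),
         cache = list(scale = scale, Y = if (relu) Y, training = FALSE))
  }
}

bn_backward <- function(layer, cache, dout) {
  dY <- tensor_mat(dout)
  relu <- identical(layer$act, "relu")
  if (!cache$training) {
    dX <- dY * cache$scale
    if (relu) dX <- dX * (cache$Y > 0)
    return(list(dinput = with_mat(dout, dX),
                grads = list(gamma = numeric(length(cache$scale)),
                             beta = numeric(length(cache$scale)))))
  }
  r <- cpp_bn_backward(dY, cache$xhat, cache$istd, layer$gamma, layer$beta,
                       relu)
  list(dinput = with_mat(dout, r$dX),
       grads = list(gamma = r$dgamma, beta = r$dbeta))
}

relu_forward <- function(tin) {
  M <- tensor_mat(tin)
  keep <- M > 0
  list(out = with_mat(tin, M * keep), cache = list(keep = keep))
}

relu_backward <- function(cache, dout) {
  list(dinput = with_mat(dout, tensor_mat(dout) * cache$keep), grads = NULL)
}

# Channels-first columns are already grouped by batch item: flattening is a
# zero-copy reshape to (channels * positions_per_item) x batch.
flatten_forward <- function(tin) {
  M <- tin$x
  dim(M) <- c(nrow(tin$x) * tin$h * tin$w, tin$b)
  list(out = M, cache = list(h = tin$h, w = tin$w, b = tin$b,
                             c = nrow(tin$x)))
}

flatten_backward <- function(cache, dout) {
  dim(dout) <- c(cache$c, cache$h * cache$w * cache$b)
  list(dinput = conv_tensor(dout, cache$h, cache$w, cache$b), grads = NULL)
}

dense_forward <- function(layer, X) {
  list(out = layer$W %*% X + layer$b, cache = list(X = X))
}

dense_backward <- function(layer, cache, dY) {
  list(dinput = crossprod(layer$W, dY),
       grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
}

dropout_forward <- function(layer, X, training) {
  if (!training || layer$rate <= 0)
    return(list(out = X, cache = list(mask = NULL)))
  keep <- 1 - layer$rate
  mask <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X)) / keep
  list(out = X * mask, cache = list(mask = mask))
}

dropout_backward <- function(cache, dY) {
  list(dinput = if (is.null(cache$mask)) dY else dY * cache$mask, grads = NULL)
}

# Full forward pass. Returns the logits (classes x batch), per-layer caches,
# each layer's output (for activation dumps) and batch-norm moving-statistic
# updates.
net_forward <- function(net, input, training = FALSE, keep_outputs = FALSE) {
  caches <- vector("list", length(net))
  outs <- if (keep_outputs) vector("list", length(net)) else NULL
  updates <- vector("list", length(net))
  x <- input
  for (i in seq_along(net)) {
    l <- net[[i]]
    r <- switch(l$type,
      conv = conv_forward(l, x),
      bn = bn_forward(l, x, training),
      relu = relu_forward(x),
      flatten = flatten_forward(x),
      dense = dense_forward(l, x),
      dropout = dropout_forward(l, x, training))
    x <- r$out
    caches[[i]] <- r$cache
    if (keep_outputs) outs[[i]] <- r$out
    if (!is.null(r$updates)) updates[[i]] <- r$updates
  }
  list(out = x, caches = caches, outs = outs, updates = updates)
}

# Full backward pass from a gradient at the logits. Returns per-layer
# parameter gradients, the gradient with respect to the network input, and
# (optionally) the gradient at each layer's output.
net_backward <- function(net, caches, dlogits, keep_douts = FALSE) {
  grads <- vector("list", length(net))
  douts <- if (keep_douts) vector("list", length(net)) else NULL
  g <- dlogits
  for (i in rev(seq_along(net))) {
    if (keep_douts) douts[[i]] <- g
    l <- net[[i]]
    r <- switch(l$type,
      conv = conv_backward(l, caches[[i]], g),
      bn = bn_backward(l, caches[[i]], g),
      relu = relu_backward(caches[[i]], g),
      flatten = flatten_backward(caches[[i]], g),
      dense = dense_backward(l, caches[[i]], g),
      dropout = dropout_backward(caches[[i]], g))
    if (!is.null(r$grads)) grads[[i]] <- r$grads
    g <- r$dinput
  }
  list(grads = grads, dinput = g, douts = douts)
}

apply_bn_updates <- function(net, updates) {
  for (i in seq_along(updates)) {
    if (!is.null(updates[[i]])) {
      net[[i]]$mmean <- updates[[i]]$mmean
      net[[i]]$mvar <- updates[[i]]$mvar
      net[[i]]$t <- net[[i]]$t + 1L
    }
  }
  net
}

# Softmax over the class dimension of a (classes x batch) logit matrix.
softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# Categorical cross entropy on logits; onehot is (classes x batch).
softmax_ce <- function(logits, onehot) {
  p <- softmax_cols(logits)
  eps <- 1e-12
  loss <- -mean(colSums(onehot * log(p + eps)))
  list(loss = loss, dlogits = (p - onehot) / ncol(logits), probs = p)
}

# --- Nesterov-Adam (Nadam) ----------------------------------------------

trainable_fields <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"), dense = c("W", "b"),
         bn = c("gamma", "beta"), NULL)
}

nadam_init <- function(net) {
  lapply(net, function(l) {
    f <- trainable_fields(l)
    if (is.null(f)) return(NULL)
    st <- list()
    for (nm in f) st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    st
  })
}

# One Nadam step (Adam with Nesterov momentum): the momentum term is
# "looked ahead" by mixing the bias-corrected first moment with the current
# gradient before the update.
nadam_step <- function(net, grads, state, t, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-7) {
  b1t <- 1 - beta1^t; b2t <- 1 - beta2^t
  for (i in seq_along(net)) {
    f <- trainable_fields(net[[i]])
    if (is.null(f) || is.null(grads[[i]])) next
    for (nm in f) {
      g <- grads[[i]][[nm]]
      s <- state[[i]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / b1t
      vhat <- s$v / b2t
      net[[i]][[nm]] <- net[[i]][[nm]] -
        lr * (beta1 * mhat + (1 - beta1) * g / b1t) / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- s
    }
  }
  list(net = net, state = state)
}
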