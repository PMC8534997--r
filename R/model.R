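# The lightweight CNN gait-type classifier.
#
# Five 3x3 stride-2 convolutional layers (widths 32, 32, 32, 64, 64), each
# followed by batch normalization and a rectified-linear activation, then a
# 512-unit dense layer, dropout 0.5, and a 5-way softmax. The grayscale
# energy image is replicated to 3 input channels. With "same" padding the
# 224 input halves to 7 over the five layers (224 -> 112 -> 56 -> 28 -> 14
# -> 7), the flattened feature length is 7*7*64 = 3136, and the total
# parameter count — counting the batch-normalization moving statistics —
# is exactly 1,684,421.

#' Configure the gait classifier
#'
#' Returns a validated model configuration. The defaults pin the canonical
#' architecture; `input_size`, `conv_channels` and `dense_units` may be
#' shrunk for small-scale experiments, in which case the parameter-count
#' invariant of the default architecture no longer applies.
#'
#' @param input_size side length of the square input image (default 224).
#' @param channels input channels; the grayscale energy image is replicated
#'   to all of them (default 3).
#' @param conv_channels widths of the five convolutional layers.
#' @param dense_units widths of the dense head; the last entry must equal
#'   the number of classes.
#' @param classes class labels in canonical order.
#' @param dropout dropout rate between the two dense layers.
#' @param learning_rate Nesterov-Adam learning rate.
#' @param epochs,batch_size,patience training-loop parameters; early
#'   stopping monitors validation loss with the given patience.
#' @param seed integer seed controlling weight initialization and the
#'   training-time randomness (shuffling, dropout, validation split).
#' @return object of class `model_config`.
#' @export
model_config <- function(input_size = 224L, channels = 3L,
                         conv_channels = c(32L, 32L, 32L, 64L, 64L),
                         dense_units = c(512L, 5L),
                         classes = gait_types(),
                         dropout = 0.5, learning_rate = 0.001,
                         epochs = 50L, batch_size = 32L, patience = 10L,
                         seed = 1L) {
  if (length(conv_channels) != 5L)
    stop("the classifier has five convolutional layers", call. = FALSE)
  if (dense_units[length(dense_units)] != length(classes))
    stop("last dense width must equal the number of classes", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 conv_channels = as.integer(conv_channels),
                 kernel = 3L, stride = 2L,
                 dense_units = as.integer(dense_units),
                 classes = classes, dropout = dropout,
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Spatial side lengths after each convolutional layer (ceil-division).
conv_spatial_sizes <- function(config) {
  s <- config$input_size
  sizes <- integer(length(config$conv_channels))
  for (i in seq_along(sizes)) {
    s <- ceiling(s / config$stride)
    sizes[i] <- s
  }
  sizes
}

#' Build an untrained gait classifier
#'
#' Assembles the layer stack from a [model_config()] and initializes the
#' weights (Glorot-uniform) from the configuration's seed; two builds with
#' the same seed are identical.
#'
#' @param config a `model_config`.
#' @return object of class `gait_classifier`.
#' @export
build_classifier <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  net <- with_seed(config$seed, {
    layers <- list()
    cin <- config$channels
    for (cout in config$conv_channels) {
      layers <- c(layers, list(layer_conv(cin, cout, config$kernel, config$stride),
                               layer_bn(cout, act = "relu")))
      cin <- cout
    }
    layers <- c(layers, list(layer_flatten()))
    sizes <- conv_spatial_sizes(config)
    nin <- sizes[length(sizes)]^2 * cin
    nd <- length(config$dense_units)
    for (i in seq_len(nd)) {
      layers <- c(layers, list(layer_dense(nin, config$dense_units[i])))
      if (i < nd)
        layers <- c(layers, list(layer_relu(), layer_dropout(config$dropout)))
      nin <- config$dense_units[i]
    }
    layers
  })
  structure(list(net = net, config = config, classes = config$classes,
                 history = NULL), class = "gait_classifier")
}

#' Count the classifier's parameters
#'
#' Totals every per-layer parameter, counting each batch-normalization layer
#' as 4 values per channel: scale, shift, moving mean and moving variance
#' (the moving statistics are not trained by gradient descent but are part
#' of the stored model). The default architecture totals 1,684,421.
#'
#' @param classifier a `gait_classifier`.
#' @return integer parameter count.
#' @export
count_parameters <- function(classifier) {
  stopifnot(inherits(classifier, "gait_classifier"))
  total <- 0
  for (l in classifier$net) {
    total <- total + switch(l$type,
      conv = length(l$W) + length(l$b),
      bn = 4L * l$c,
      dense = length(l$W) + length(l$b),
      0L)
  }
  as.integer(total)
}

# Stack a list of representations/matrices into a channels-first conv input
# tensor, replicating the grayscale image across the input channels.
input_tensor <- function(images, config) {
  sz <- config$input_size
  mats <- lapply(images, function(im) {
    px <- if (inherits(im, "gait_representation")) im$pixels else im
    stopifnot(identical(dim(px), c(sz, sz)))
    as.vector(px)
  })
  v <- unlist(mats, use.names = FALSE)
  x <- matrix(0, config$channels, length(v))
  for (ch in seq_len(config$channels)) x[ch, ] <- v
  conv_tensor(x, sz, sz, length(images))
}

#' Class probabilities for gait representations
#'
#' Runs the network in inference mode (batch-norm moving statistics, no
#' dropout) and returns the softmax class probabilities.
#'
#' @param object a `gait_classifier`.
#' @param representations a single `gait_representation` (or matrix in
#'   \[0,1\]) or a list of them.
#' @param type `"prob"` for the probability matrix, `"class"` for predicted
#'   labels.
#' @param ... unused.
#' @return numeric matrix (one row per input, one column per class) or a
#'   character vector of labels.
#' @export
predict.gait_classifier <- function(object, representations,
                                    type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (inherits(representations, "gait_representation") ||
      is.matrix(representations))
    representations <- list(representations)
  n <- length(representations)
  bs <- max(1L, object$config$batch_size)
  probs <- matrix(0, n, length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (start in seq(1L, n, by = bs)) {
    idx <- start:min(n, start + bs - 1L)
    tin <- input_tensor(representations[idx], object$config)
    logits <- net_forward(object$net, tin, training = FALSE)$out
    probs[idx, ] <- t(softmax_cols(logits))
  }
  if (type == "class") object$classes[max.col(probs, ties.method = "first")]
  else probs
}

# One-hot labels as a (classes x n) matrix, matching the logit layout.
onehot_labels <- function(labels, classes) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  Y <- matrix(0, length(classes), length(labels))
  Y[cbind(match(labels, classes), seq_along(labels))] <- 1
  Y
}

#' Train the gait classifier
#'
#' Minimizes categorical cross entropy with the Nesterov-Adam optimizer at
#' the configured learning rate. A stratified validation split monitors
#' generalization; early stopping restores the weights of the best
#' validation-loss epoch. Training is reproducible given the configuration
#' seed and a fixed data order.
#'
#' @param classifier a built `gait_classifier`.
#' @param representations list of `gait_representation`s (or matrices).
#' @param labels class labels, one per representation, within the
#'   classifier's class set; at least two classes must be present.
#' @param validation_fraction fraction of the data held out for validation
#'   (stratified by class); 0 disables validation and early stopping.
#' @param epochs,batch_size overrides of the configured values.
#' @param verbose print per-epoch progress.
#' @return the classifier with trained weights and an epoch-indexed
#'   `history` data frame (loss, accuracy, and validation metrics).
#' @export
train_classifier <- function(classifier, representations, labels,
                             validation_fraction = 0.2,
                             epochs = NULL, batch_size = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(classifier, "gait_classifier"))
  cfg <- classifier$config
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  labels <- as.character(labels)
  if (length(representations) != length(labels))
    stop("one label per representation is required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training needs at least two classes present", call. = FALSE)
  Y <- onehot_labels(labels, classifier$classes)

  with_seed(cfg$seed + 1L, {
    n <- length(representations)
    val_idx <- integer(0)
    if (validation_fraction > 0) {
      for (cl in unique(labels)) {
        members <- which(labels == cl)
        k <- max(1L, round(length(members) * validation_fraction))
        val_idx <- c(val_idx, sample(members, k))
      }
    }
    tr_idx <- setdiff(seq_len(n), val_idx)

    net <- classifier$net
    state <- nadam_init(net)
    t <- 0L
    hist <- list()
    best <- list(loss = Inf, net = net, epoch = 0L)
    wait <- 0L

    eval_set <- function(net, idx) {
      if (length(idx) == 0L) return(c(NA_real_, NA_real_))
      loss <- 0; correct <- 0
      for (start in seq(1L, length(idx), by = batch_size)) {
        bi <- idx[start:min(length(idx), start + batch_size - 1L)]
        tin <- input_tensor(representations[bi], cfg)
        logits <- net_forward(net, tin, training = FALSE)$out
        r <- softmax_ce(logits, Y[, bi, drop = FALSE])
        loss <- loss + r$loss * length(bi)
        correct <- correct + sum(max.col(t(r$probs), ties.method = "first") ==
                                   max.col(t(Y[, bi, drop = FALSE])))
      }
      c(loss / length(idx), correct / length(idx))
    }

    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, length(ord), by = batch_size)) {
        bi <- ord[start:min(length(ord), start + batch_size - 1L)]
        tin <- input_tensor(representations[bi], cfg)
        fw <- net_forward(net, tin, training = TRUE)
        r <- softmax_ce(fw$out, Y[, bi, drop = FALSE])
        bw <- net_backward(net, fw$caches, r$dlogits)
        net <- apply_bn_updates(net, fw$updates)
        t <- t + 1L
        upd <- nadam_step(net, bw$grads, state, t, cfg$learning_rate)
        net <- upd$net; state <- upd$state
        ep_loss <- ep_loss + r$loss * length(bi)
        ep_correct <- ep_correct + sum(max.col(t(r$probs), ties.method = "first") ==
                                         max.col(t(Y[, bi, drop = FALSE])))
      }
      val <- eval_set(net, val_idx)
      hist[[ep]] <- data.frame(epoch = ep,
                               loss = ep_loss / length(ord),
                               accuracy = ep_correct / length(ord),
                               val_loss = val[1L], val_accuracy = val[2L])
      if (verbose)
        message(sprintf("epoch %d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                        ep, hist[[ep]]$loss, hist[[ep]]$accuracy, val[1L], val[2L]))
      if (length(val_idx) > 0L) {
        if (val[1L] < best$loss) {
          best <- list(loss = val[1L], net = net, epoch = ep)
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$patience) break
        }
      }
    }
    classifier$net <- if (length(val_idx) > 0L) best$net else net
    classifier$history <- do.call(rbind, hist)
    classifier
  })
}

#' Save / load a trained classifier
#'
#' The layered weights are stored in R's native serialized container with a
#' YAML sidecar describing the configuration and class order.
#'
#' @param classifier a `gait_classifier`.
#' @param path file path for the weights container (`.rds`).
#' @return `save_classifier` returns `path` invisibly; `load_classifier`
#'   returns the classifier.
#' @export
save_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "gait_classifier"))
  saveRDS(classifier, path)
  cfg <- classifier$config
  yaml::write_yaml(list(classes = cfg$classes, input_size = cfg$input_size,
                        channels = cfg$channels,
                        conv_channels = cfg$conv_channels,
                        dense_units = cfg$dense_units, seed = cfg$seed),
                   paste0(sub("\\.rds$", "", path), "_config.yaml"))
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "gait_classifier"))
  obj
}
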