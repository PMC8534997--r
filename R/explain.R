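# Diagnostic visualizations: which parts of the energy image drive the
# classification. Gradients are taken at the pre-softmax class scores, the
# standard choice for both gradient saliency and grad-CAM.

new_explanation_map <- function(map, method, target_class, layer = NULL) {
  structure(list(map = map, method = method, target_class = target_class,
                 layer = layer), class = "explanation_map")
}

# Rescale a nonnegative map so its maximum is 1; an all-zero map stays zero.
rescale_map <- function(m) {
  mx <- max(m)
  if (mx > 0) m / mx else m
}

resolve_class <- function(classifier, target_class) {
  if (is.character(target_class)) {
    idx <- match(target_class, classifier$classes)
    if (is.na(idx)) stop("unknown class: ", target_class, call. = FALSE)
    idx
  } else {
    idx <- as.integer(target_class)
    if (idx < 1L || idx > length(classifier$classes))
      stop("class index out of range", call. = FALSE)
    idx
  }
}

# Forward (inference mode, caches kept) then backward from a one-hot
# gradient at the logits of the target class.
backprop_class_score <- function(classifier, representation, class_idx) {
  tin <- input_tensor(list(representation), classifier$config)
  fw <- net_forward(classifier$net, tin, training = FALSE, keep_outputs = TRUE)
  dlogits <- matrix(0, length(classifier$classes), 1L)
  dlogits[class_idx, 1L] <- 1
  bw <- net_backward(classifier$net, fw$caches, dlogits, keep_douts = TRUE)
  list(fw = fw, bw = bw, tin = tin)
}

#' Gradient saliency map
#'
#' Per-pixel magnitude of the gradient of the target class's pre-softmax
#' score with respect to the input image, max-reduced over the replicated
#' input channels and rescaled to \[0,1\] (an identically zero map is
#' returned as zeros, not rescaled).
#'
#' @param classifier a trained `gait_classifier`.
#' @param representation a `gait_representation` or input-sized matrix.
#' @param target_class class name or index whose score is differentiated.
#' @return an `explanation_map` with a `input_size` x `input_size` map.
#' @export
saliency_map <- function(classifier, representation, target_class) {
  idx <- resolve_class(classifier, target_class)
  r <- backprop_class_score(classifier, representation, idx)
  dx <- r$bw$dinput
  g <- abs(tensor_mat(dx))            # channels x positions
  gmax <- g[1L, ]
  if (nrow(g) > 1L)
    for (ch in 2:nrow(g)) gmax <- pmax(gmax, g[ch, ])
  sz <- classifier$config$input_size
  new_explanation_map(rescale_map(matrix(gmax, sz, sz)), "saliency",
                      classifier$classes[idx])
}

# Index of the activation output of the n-th conv block (the fused
# batch-norm + rectifier, or a plain rectifier, whichever follows the conv).
conv_block_relu <- function(net, layer_index) {
  conv_pos <- which(vapply(net, function(l) l$type == "conv", logical(1)))
  if (layer_index < 1L || layer_index > length(conv_pos))
    stop("layer_index must name one of the ", length(conv_pos),
         " convolutional layers", call. = FALSE)
  i <- conv_pos[layer_index]
  while (i <= length(net) &&
         !(net[[i]]$type == "relu" ||
           (net[[i]]$type == "bn" && identical(net[[i]]$act, "relu"))))
    i <- i + 1L
  if (i > length(net)) stop("no activation after that conv layer", call. = FALSE)
  i
}

#' Grad-CAM class-activation map
#'
#' Channel-weighted sum of a convolutional layer's activations, with
#' channel weights given by the spatial average of the class-score gradient
#' at that layer; negative values are clipped, the map is upsampled to the
#' input size and rescaled to \[0,1\].
#'
#' @param classifier a trained `gait_classifier`.
#' @param representation a `gait_representation` or input-sized matrix.
#' @param target_class class name or index.
#' @param layer_index which of the 5 conv layers to use (default: last).
#' @return an `explanation_map`.
#' @export
grad_cam <- function(classifier, representation, target_class,
                     layer_index = 5L) {
  idx <- resolve_class(classifier, target_class)
  pos <- conv_block_relu(classifier$net, layer_index)
  r <- backprop_class_score(classifier, representation, idx)
  A <- r$fw$outs[[pos]]
  dA <- r$bw$douts[[pos]]
  alpha <- rowMeans(tensor_mat(dA))
  cam <- colSums(tensor_mat(A) * alpha)
  cam[cam < 0] <- 0
  cam <- matrix(cam, A$h, A$w)
  sz <- classifier$config$input_size
  up <- from_ebimage(EBImage::resize(as_ebimage(cam), w = sz, h = sz))
  up[up < 0] <- 0
  new_explanation_map(rescale_map(up), "grad_cam", classifier$classes[idx],
                      layer = layer_index)
}

#' Dump a convolutional layer's feature maps
#'
#' Returns each channel's activation grid (after normalization and the
#' rectified-linear unit) at the chosen layer's spatial resolution — for
#' the default 224 input, sizes 112/56/28/14/7 for layers 1 to 5.
#'
#' @param classifier a `gait_classifier`.
#' @param representation a `gait_representation` or input-sized matrix.
#' @param layer_index which conv layer (1 to 5).
#' @return list of matrices, one per channel.
#' @export
dump_feature_maps <- function(classifier, representation, layer_index) {
  pos <- conv_block_relu(classifier$net, layer_index)
  tin <- input_tensor(list(representation), classifier$config)
  fw <- net_forward(classifier$net, tin, training = FALSE, keep_outputs = TRUE)
  A <- fw$outs[[pos]]
  lapply(seq_len(nrow(A$x)), function(ch) matrix(A$x[ch, ], A$h, A$w))
}

#' Render an explanation overlay
#'
#' Composites an explanation map over its source energy image with a
#' perceptually graded colormap at 50% alpha, for visual inspection.
#'
#' @param representation the explained `gait_representation` or matrix.
#' @param explanation an `explanation_map`.
#' @return h x w x 3 RGB array in \[0,1\].
#' @export
explanation_overlay <- function(representation, explanation) {
  px <- if (inherits(representation, "gait_representation"))
    representation$pixels else representation
  m <- explanation$map
  cols <- grDevices::hcl.colors(256, "viridis")
  rgbm <- grDevices::col2rgb(cols) / 255
  idx <- pmin(256L, pmax(1L, 1L + floor(m * 255)))
  out <- array(0, c(nrow(px), ncol(px), 3L))
  for (ch in 1:3)
    out[, , ch] <- 0.5 * px + 0.5 * matrix(rgbm[ch, idx], nrow(px), ncol(px))
  out
}
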