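# Chroma-key silhouette extraction.
#
# A background-only frame is modelled in HSV: per-channel valid intervals are
# learned from the channel histograms, and pixels of walking frames falling
# outside the background range are classified as subject. A morphological
# opening-then-closing removes speckle, and only the largest connected
# component is kept.

hsv_of_frame <- function(frame) {
  d <- dim(frame)
  rgb <- rbind(as.vector(frame[, , 1L]), as.vector(frame[, , 2L]),
               as.vector(frame[, , 3L]))
  grDevices::rgb2hsv(rgb, maxColorValue = 1)
}

# Circular [lo, hi] interval for hue: recentre hues on their circular mean so
# percentiles are taken on an unwrapped axis.
circular_interval <- function(h, probs, widen) {
  ang <- 2 * pi * h
  mu <- atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)
  centered <- (h - mu + 0.5) %% 1 - 0.5          # in (-0.5, 0.5]
  q <- stats::quantile(centered, probs, names = FALSE, type = 7)
  pad <- max(widen * (q[2] - q[1]), 0.002)
  list(center = mu %% 1, lo = q[1] - pad, hi = q[2] + pad)
}

linear_interval <- function(x, probs, widen) {
  q <- stats::quantile(x, probs, names = FALSE, type = 7)
  pad <- max(widen * (q[2] - q[1]), 0.002)
  c(q[1] - pad, q[2] + pad)
}

#' Fit an HSV background model from a background-only frame
#'
#' Converts the frame to HSV and learns per-channel valid intervals covering
#' the central mass of each channel's histogram: the \[1st, 99th\] percentile
#' range, widened by 25% of its width (with a small absolute floor) so that
#' background pixels drawn from the same noise distribution fall inside the
#' model. The hue interval is computed circularly around the circular mean
#' hue. A multi-modal background yields one wide interval covering the modes.
#'
#' @param background_frame h x w x 3 RGB array with values in \[0,1\].
#' @return object of class `background_model` with elements `hue`
#'   (center/lo/hi on the centered hue axis), `sat`, `val`.
#' @export
fit_background <- function(background_frame) {
  stopifnot(length(dim(background_frame)) == 3L, dim(background_frame)[3L] == 3L)
  if (all(background_frame == 0))
    stop("degenerate background frame: all pixels are zero", call. = FALSE)
  hsv <- hsv_of_frame(background_frame)
  structure(list(
    hue = circular_interval(hsv[1L, ], c(0.01, 0.99), 0.25),
    sat = linear_interval(hsv[2L, ], c(0.01, 0.99), 0.25),
    val = linear_interval(hsv[3L, ], c(0.01, 0.99), 0.25),
    dim = dim(background_frame)[1:2]), class = "background_model")
}

# Per-pixel background membership under the model, by channel.
background_membership <- function(frame, model) {
  hsv <- hsv_of_frame(frame)
  hc <- (hsv[1L, ] - model$hue$center + 0.5) %% 1 - 0.5
  list(hue = hc >= model$hue$lo & hc <= model$hue$hi,
       sat = hsv[2L, ] >= model$sat[1] & hsv[2L, ] <= model$sat[2],
       val = hsv[3L, ] >= model$val[1] & hsv[3L, ] <= model$val[2])
}

#' Extract a binary silhouette from a chroma-background frame
#'
#' A pixel is labelled foreground when its hue lies outside the background
#' hue interval, or when both its saturation and value lie outside theirs
#' (hue is the discriminative channel over a chroma backdrop; the S/V clause
#' catches gray or desaturated clothing whose hue is unstable). The raw mask
#' is cleaned by morphological opening then closing with a 5 x 5 elliptical
#' structuring element, and only the largest connected component is retained.
#' An empty mask (no foreground) is a valid result.
#'
#' @param frame h x w x 3 RGB array in \[0,1\].
#' @param model a `background_model` from [fit_background()].
#' @return h x w integer matrix with foreground = 1.
#' @export
extract_silhouette <- function(frame, model) {
  stopifnot(inherits(model, "background_model"))
  d <- dim(frame)
  if (!identical(as.integer(d[1:2]), as.integer(model$dim)))
    stop("frame size does not match the background model", call. = FALSE)
  memb <- background_membership(frame, model)
  fg <- !memb$hue | (!memb$sat & !memb$val)
  mask <- matrix(fg, d[1L], d[2L])
  mask <- clean_silhouette(mask)
  largest_component(mask) * 1L
}

# Opening then closing with a 5x5 elliptical (disc) structuring element.
clean_silhouette <- function(mask) {
  kern <- EBImage::makeBrush(5L, shape = "disc")
  img <- as_ebimage(mask * 1)
  img <- EBImage::closing(EBImage::opening(img, kern), kern)
  from_ebimage(img) > 0.5
}

largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask * 1)))
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Extract silhouettes for a whole frame sequence
#'
#' Applies [extract_silhouette()] to each frame and wraps the result as a
#' `silhouette_sequence` carrying the effective framerate.
#'
#' @param frames list of RGB arrays, all the same size.
#' @param model a `background_model`.
#' @param fps effective framerate of the sequence.
#' @return object of class `silhouette_sequence`.
#' @export
extract_silhouettes <- function(frames, model, fps = 10) {
  masks <- lapply(frames, extract_silhouette, model = model)
  new_silhouette_sequence(masks, fps)
}

new_silhouette_sequence <- function(masks, fps = 10) {
  stopifnot(length(masks) >= 1L, fps > 0)
  d <- dim(masks[[1L]])
  for (m in masks) stopifnot(identical(dim(m), d))
  structure(list(masks = masks, height = d[1L], width = d[2L], fps = fps),
            class = "silhouette_sequence")
}
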