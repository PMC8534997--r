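# Gait representations.
#
# Silhouette and pose sequences are turned into 224 x 224 energy images:
# the GEI averages normalized binary silhouettes over a gait cycle (or over
# the whole sequence); the SEI applies exactly the same averaging to
# rasterized skeleton images. Cycles are detected from the periodicity of
# the silhouette bounding-box width.

REPRESENTATION_SIZE <- 224L

#' Resample a sequence to a lower framerate
#'
#' Uniform frame subsampling: output frame `k` (0-based) takes source frame
#' `round(k * source_fps / target_fps)`. Upsampling is refused.
#'
#' @param sequence a `silhouette_sequence` or `pose_sequence`.
#' @param target_fps target framerate (must not exceed the source rate).
#' @return the same type of sequence at `target_fps`.
#' @export
resample_framerate <- function(sequence, target_fps = 10) {
  src <- sequence$fps
  if (target_fps > src)
    stop("cannot upsample: target framerate exceeds source framerate", call. = FALSE)
  if (target_fps == src) return(sequence)
  n <- sequence_length(sequence)
  n_out <- floor(n * target_fps / src)
  idx <- round((seq_len(n_out) - 1) * src / target_fps) + 1
  idx <- idx[idx <= n]
  out <- subset_frames(sequence, idx)
  out$fps <- target_fps
  out
}

sequence_length <- function(sequence) {
  if (inherits(sequence, "silhouette_sequence")) length(sequence$masks)
  else if (inherits(sequence, "pose_sequence")) dim(sequence$keypoints)[3L]
  else stop("not a silhouette or pose sequence", call. = FALSE)
}

subset_frames <- function(sequence, idx) {
  if (inherits(sequence, "silhouette_sequence")) {
    sequence$masks <- sequence$masks[idx]
  } else {
    sequence$keypoints <- sequence$keypoints[, , idx, drop = FALSE]
  }
  sequence
}

#' Mirror a sequence so it faces left-to-right
#'
#' Right-to-left sequences are mirrored horizontally: masks are flipped
#' column-wise; pose x-coordinates are reflected (`x' = width - 1 - x` in the
#' 0-based pixel convention) and anatomical left/right keypoint indices are
#' swapped. Left-to-right input is returned unchanged; applying the mirror
#' twice is the identity.
#'
#' @param sequence a `silhouette_sequence` or `pose_sequence`.
#' @param direction the recorded walking direction of the sequence.
#' @return the canonicalized sequence.
#' @export
canonicalize_direction <- function(sequence,
                                   direction = c("left_to_right", "right_to_left")) {
  direction <- match.arg(direction)
  if (direction == "left_to_right") return(sequence)
  if (inherits(sequence, "silhouette_sequence")) {
    sequence$masks <- lapply(sequence$masks, function(m) m[, ncol(m):1, drop = FALSE])
  } else {
    kp <- sequence$keypoints
    kp[, 1L, ] <- sequence$width - 1 - kp[, 1L, ]
    pairs <- body25_lr_pairs() + 1L
    swapped <- kp
    swapped[pairs[, 1L], , ] <- kp[pairs[, 2L], , ]
    swapped[pairs[, 2L], , ] <- kp[pairs[, 1L], , ]
    sequence$keypoints <- swapped
  }
  sequence
}

#' Crop, size-normalize and horizontally align a binary silhouette
#'
#' The mask is cropped to its foreground bounding box, scaled so the box
#' height is 224 while preserving aspect ratio, and pasted on a 224 x 224
#' canvas with the silhouette's horizontal centroid at column 112; columns
#' overflowing the canvas are clipped. Resizing is bilinear followed by
#' binarization at 0.5, so the output is strictly binary. A degenerate mask
#' (e.g. a single pixel) scales to the full canvas height under the same
#' aspect-preserving rule.
#'
#' @param mask binary matrix (foreground > 0); must be nonempty.
#' @return 224 x 224 integer matrix with values 0/1.
#' @export
normalize_silhouette <- function(mask) {
  bb <- mask_bbox(mask > 0)
  if (is.null(bb)) stop("empty mask cannot be normalized", call. = FALSE)
  crop <- (mask > 0)[bb$r0:bb$r1, bb$c0:bb$c1, drop = FALSE] * 1
  sz <- REPRESENTATION_SIZE
  sc <- sz / nrow(crop)
  out_w <- max(1L, as.integer(round(ncol(crop) * sc)))
  res <- from_ebimage(EBImage::resize(as_ebimage(crop), w = out_w, h = sz))
  bin <- res >= 0.5
  if (!any(bin)) bin <- res > 0
  canvas <- matrix(0L, sz, sz)
  colmass <- colSums(bin)
  centroid <- sum(colmass * seq_len(out_w)) / sum(colmass)
  offset <- round(sz / 2 - centroid)
  src <- seq_len(out_w)
  dst <- src + offset
  keep <- dst >= 1 & dst <= sz
  canvas[, dst[keep]] <- bin[, src[keep], drop = FALSE] * 1L
  canvas
}

# Silhouette bounding-box width per frame (0 for empty frames).
silhouette_widths <- function(sequence) {
  vapply(sequence$masks, function(m) {
    bb <- mask_bbox(m > 0)
    if (is.null(bb)) 0 else bb$c1 - bb$c0 + 1
  }, numeric(1))
}

#' Detect gait cycles from silhouette width periodicity
#'
#' The silhouette bounding-box width oscillates twice per gait cycle (the
#' legs pass each other at every step). The width signal is smoothed with a
#' 3-frame moving average; local minima closer than 3 frames are merged; and
#' cycle boundaries are taken at alternate minima, so each cycle spans two
#' strides. A constant width signal (or fewer than three minima) yields no
#' cycle.
#'
#' @param sequence a `silhouette_sequence` covering at least about 1.5
#'   gait periods.
#' @return `data.frame` with columns `start_frame`, `end_frame` (inclusive,
#'   non-overlapping, ordered); zero rows when no cycle is found.
#' @export
detect_gait_cycles <- function(sequence) {
  stopifnot(inherits(sequence, "silhouette_sequence"))
  w <- silhouette_widths(sequence)
  n <- length(w)
  no_cycle <- data.frame(start_frame = integer(0), end_frame = integer(0))
  if (n < 5L) return(no_cycle)
  s <- stats::filter(w, rep(1 / 3, 3), sides = 2)
  s[1L] <- mean(w[1:2]); s[n] <- mean(w[(n - 1):n])
  s <- as.numeric(s)
  cand <- which(vapply(2:(n - 1), function(i)
    s[i] < s[i - 1] && s[i] <= s[i + 1], logical(1))) + 1L
  if (length(cand) == 0L) return(no_cycle)
  minima <- cand[1L]
  for (i in cand[-1L]) {
    if (i - minima[length(minima)] < 3L) {
      if (s[i] < s[minima[length(minima)]]) minima[length(minima)] <- i
    } else minima <- c(minima, i)
  }
  if (length(minima) < 3L) return(no_cycle)
  bounds <- minima[seq(1L, length(minima), by = 2L)]
  if (length(bounds) < 2L) return(no_cycle)
  data.frame(start_frame = bounds[-length(bounds)],
             end_frame = bounds[-1L] - 1L)
}

#' Average binary images into an energy image
#'
#' The pixel-wise mean of `N` normalized binary images:
#' `E(x, y) = (1/N) * sum_i B_i(x, y)`. With silhouettes as input this is the
#' Gait Energy Image; with rasterized skeletons it is the Skeleton Energy
#' Image — the two share this code path by construction.
#'
#' @param images nonempty list of 224 x 224 binary matrices.
#' @param kind `"GEI"` or `"SEI"` tag recorded on the result.
#' @param scope `"whole_sequence"` or `"per_cycle"`.
#' @param cycle optional `c(start_frame, end_frame)` provenance.
#' @return object of class `gait_representation` with `pixels` in \[0,1\].
#' @export
compute_energy_image <- function(images, kind = c("GEI", "SEI"),
                                 scope = c("whole_sequence", "per_cycle"),
                                 cycle = NULL) {
  kind <- match.arg(kind); scope <- match.arg(scope)
  if (length(images) == 0L) stop("no images to average", call. = FALSE)
  sz <- REPRESENTATION_SIZE
  for (im in images) stopifnot(identical(dim(im), c(sz, sz)))
  pixels <- Reduce(`+`, images) / length(images)
  structure(list(kind = kind, pixels = pixels, scope = scope, cycle = cycle,
                 n_frames = length(images)), class = "gait_representation")
}

#' BODY_25 limb pairs
#'
#' The standard skeleton edges of the BODY_25 convention as 0-based keypoint
#' index pairs, one row per limb.
#'
#' @return integer matrix with columns `a`, `b`.
#' @export
skeleton_limb_pairs <- function() {
  m <- rbind(c(1, 8), c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(5, 6), c(6, 7),
             c(8, 9), c(9, 10), c(10, 11), c(8, 12), c(12, 13), c(13, 14),
             c(1, 0), c(0, 15), c(15, 17), c(0, 16), c(16, 18),
             c(14, 19), c(19, 20), c(14, 21), c(11, 22), c(22, 23), c(11, 24))
  colnames(m) <- c("a", "b")
  m
}

#' Rasterize a single pose frame into a binary skeleton image
#'
#' Draws a line segment of fixed thickness between every BODY_25 limb pair
#' whose two endpoints both exceed the confidence threshold, on a canvas of
#' the capture frame size. The result is normalized downstream with
#' [normalize_silhouette()] for SEI averaging.
#'
#' @param pose_frame 25 x 3 matrix of (x, y, confidence), 0-based pixel
#'   coordinates.
#' @param width,height canvas size in pixels.
#' @param thickness stroke width in pixels.
#' @param conf_threshold minimum keypoint confidence.
#' @return height x width integer 0/1 matrix, or `NULL` (skip signal) when
#'   fewer than two keypoints pass the threshold.
#' @export
rasterize_skeleton <- function(pose_frame, width, height, thickness = 3,
                               conf_threshold = 0.1) {
  stopifnot(is.matrix(pose_frame), nrow(pose_frame) == 25L, ncol(pose_frame) == 3L)
  ok <- pose_frame[, 3L] > conf_threshold
  if (sum(ok) < 2L) return(NULL)
  pairs <- skeleton_limb_pairs() + 1L
  keep <- ok[pairs[, 1L]] & ok[pairs[, 2L]]
  if (!any(keep)) return(NULL)
  pairs <- pairs[keep, , drop = FALSE]
  segs <- cbind(pose_frame[pairs[, 1L], 1L] + 1, pose_frame[pairs[, 1L], 2L] + 1,
                pose_frame[pairs[, 2L], 1L] + 1, pose_frame[pairs[, 2L], 2L] + 1)
  rasterize_segments(segs, height, width, thickness) * 1L
}

#' Compute a GEI or SEI for a sequence
#'
#' High-level wrapper: silhouettes (GEI) or poses (SEI) are normalized
#' frame-by-frame and averaged over the whole sequence or over each detected
#' gait cycle. Empty silhouettes and un-rasterizable pose frames are skipped.
#'
#' @param x a `silhouette_sequence` (GEI) or `pose_sequence` (SEI).
#' @param kind `"GEI"` or `"SEI"`; defaults to match the input type.
#' @param scope `"whole_sequence"` (one representation) or `"per_cycle"`
#'   (one per detected cycle).
#' @param cycles optional cycle table (as from [detect_gait_cycles()]); for
#'   `scope = "per_cycle"` with a pose input it must be supplied, since
#'   cycles are detected on silhouettes.
#' @return a `gait_representation`, or a list of them for `"per_cycle"`.
#' @export
gait_representation <- function(x, kind = NULL,
                                scope = c("whole_sequence", "per_cycle"),
                                cycles = NULL) {
  scope <- match.arg(scope)
  is_pose <- inherits(x, "pose_sequence")
  if (is.null(kind)) kind <- if (is_pose) "SEI" else "GEI"
  frames_to_images <- function(idx) {
    out <- list()
    for (f in idx) {
      m <- if (is_pose)
        rasterize_skeleton(x$keypoints[, , f], x$width, x$height)
      else if (any(x$masks[[f]] > 0)) x$masks[[f]] else NULL
      if (!is.null(m)) out[[length(out) + 1L]] <- normalize_silhouette(m)
    }
    out
  }
  if (scope == "whole_sequence") {
    imgs <- frames_to_images(seq_len(sequence_length(x)))
    return(compute_energy_image(imgs, kind, "whole_sequence"))
  }
  if (is.null(cycles)) {
    if (is_pose)
      stop("per-cycle SEI needs a cycle table detected on the silhouettes",
           call. = FALSE)
    cycles <- detect_gait_cycles(x)
  }
  if (nrow(cycles) == 0L) stop("no gait cycle found", call. = FALSE)
  lapply(seq_len(nrow(cycles)), function(i) {
    imgs <- frames_to_images(cycles$start_frame[i]:cycles$end_frame[i])
    compute_energy_image(imgs, kind, "per_cycle",
                         cycle = c(cycles$start_frame[i], cycles$end_frame[i]))
  })
}
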