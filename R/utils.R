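# Low-level raster helpers shared by the walker simulator (sprite rendering)
# and the skeleton rasterizer. Masks are base-R logical/numeric matrices with
# rows = image y (top to bottom) and columns = image x; continuous coordinates
# are 1-based pixel centers.

#' Rasterize thick line segments into a binary mask
#'
#' Draws each segment as a capsule (all pixels whose center lies within
#' `thickness/2` of the segment) on an `h` x `w` canvas. Used for walker limb
#' sprites and for skeleton images.
#'
#' @param segments numeric matrix with columns `x0,y0,x1,y1`, one row per
#'   segment, in pixel coordinates (x = column, y = row).
#' @param h,w canvas size in pixels.
#' @param thickness stroke width in pixels (capsule diameter).
#' @return logical `h` x `w` matrix.
#' @keywords internal
rasterize_segments <- function(segments, h, w, thickness) {
  mask <- matrix(FALSE, h, w)
  if (is.null(segments) || nrow(segments) == 0L) return(mask)
  r <- thickness / 2
  for (s in seq_len(nrow(segments))) {
    x0 <- segments[s, 1L]; y0 <- segments[s, 2L]
    x1 <- segments[s, 3L]; y1 <- segments[s, 4L]
    cx0 <- max(1L, floor(min(x0, x1) - r)); cx1 <- min(w, ceiling(max(x0, x1) + r))
    cy0 <- max(1L, floor(min(y0, y1) - r)); cy1 <- min(h, ceiling(max(y0, y1) + r))
    if (cx0 > cx1 || cy0 > cy1) next
    xs <- cx0:cx1; ys <- cy0:cy1
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    dx <- x1 - x0; dy <- y1 - y0
    len2 <- dx * dx + dy * dy
    if (len2 < .Machine$double.eps) {
      d2 <- (px - x0)^2 + (py - y0)^2
    } else {
      t <- ((px - x0) * dx + (py - y0) * dy) / len2
      t[t < 0] <- 0; t[t > 1] <- 1
      d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
    }
    hit <- d2 <= r * r
    mask[ys, xs] <- mask[ys, xs] | hit
  }
  mask
}

#' Rasterize a filled axis-aligned ellipse
#' @keywords internal
rasterize_ellipse <- function(cx, cy, rx, ry, h, w) {
  mask <- matrix(FALSE, h, w)
  cx0 <- max(1L, floor(cx - rx)); cx1 <- min(w, ceiling(cx + rx))
  cy0 <- max(1L, floor(cy - ry)); cy1 <- min(h, ceiling(cy + ry))
  if (cx0 > cx1 || cy0 > cy1) return(mask)
  xs <- cx0:cx1; ys <- cy0:cy1
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))
  mask[ys, xs] <- ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
  mask
}

# Convert a row-major (y, x) matrix to an EBImage Image (x, y) and back.
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(img) t(EBImage::imageData(img))

# Bounding box of a nonempty binary mask: list(r0, r1, c0, c1).
mask_bbox <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  if (length(rows) == 0L) return(NULL)
  list(r0 = rows[1L], r1 = rows[length(rows)], c0 = cols[1L], c1 = cols[length(cols)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
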