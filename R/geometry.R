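#' Rotated bounding box
#'
#' The universal geometry record for stomata labels and detections: a
#' rectangle given by its center, long-axis length, short-axis width and the
#' orientation of the long axis. Coordinates follow the raster convention:
#' 0-based pixel centers, x rightward, y downward. The angle is measured in
#' degrees counter-clockwise from the +x axis to the long axis and is reduced
#' modulo 180 (a rectangle is symmetric under a half turn).
#'
#' @param cx,cy center coordinates in pixels.
#' @param length long-axis extent in pixels, must be positive.
#' @param width short-axis extent in pixels, must be positive and not exceed
#'   `length`.
#' @param angle_deg orientation of the long axis in `[0, 180)` degrees.
#' @return An object of class `rotated_box` (a named list).
#' @seealso [canonicalize_box()] to build a box from unordered sides,
#'   [box_corners()], [rotated_iou()].
#' @export
rotated_box <- function(cx, cy, length, width, angle_deg) {
  stopifnot(is.finite(cx), is.finite(cy))
  if (!is.finite(length) || !is.finite(width) || length <= 0 || width <= 0)
    stop("rotated_box: length and width must be positive and finite")
  if (width > length + 1e-9)
    stop("rotated_box: width (", width, ") exceeds length (", length,
         "); use canonicalize_box() for unordered sides")
  angle_deg <- angle_deg %% 180
  structure(list(cx = as.numeric(cx), cy = as.numeric(cy),
                 length = as.numeric(length), width = as.numeric(min(width, length)),
                 angle_deg = as.numeric(angle_deg)),
            class = "rotated_box")
}

#' @export
print.rotated_box <- function(x, ...) {
  cat(sprintf("<rotated_box> center (%.2f, %.2f)  %.2f x %.2f px  angle %.1f deg\n",
              x$cx, x$cy, x$length, x$width, x$angle_deg))
  invisible(x)
}

#' Canonicalize rotated-box sides and angle
#'
#' Builds a [rotated_box()] from two unordered side lengths: the long side
#' becomes `length`; if the sides had to be swapped the angle is rotated by
#' 90 degrees, and in all cases the angle is reduced modulo 180 into
#' `[0, 180)`.
#'
#' @param cx,cy center coordinates in pixels.
#' @param a_side,b_side the two side lengths (any order), both positive.
#' @param angle_deg orientation of the `a_side` axis in degrees.
#' @return A `rotated_box`.
#' @examples
#' canonicalize_box(0, 0, 4, 10, 30)  # length 10, width 4, angle 120
#' @export
canonicalize_box <- function(cx, cy, a_side, b_side, angle_deg) {
  if (!is.finite(a_side) || !is.finite(b_side) || a_side <= 0 || b_side <= 0)
    stop("canonicalize_box: sides must be positive")
  if (a_side >= b_side) {
    rotated_box(cx, cy, a_side, b_side, angle_deg %% 180)
  } else {
    rotated_box(cx, cy, b_side, a_side, (angle_deg + 90) %% 180)
  }
}

#' Corner vertices of a rotated box
#'
#' @param box a [rotated_box()].
#' @return A 4x2 numeric matrix of (x, y) vertices in counter-clockwise order
#'   (in the y-down image convention).
#' @export
box_corners <- function(box) {
  th <- box$angle_deg * pi / 180
  u <- c(cos(th), sin(th)) * box$length / 2   # long-axis half vector
  v <- c(-sin(th), cos(th)) * box$width / 2   # short-axis half vector
  c0 <- c(box$cx, box$cy)
  m <- rbind(c0 - u - v, c0 + u - v, c0 + u + v, c0 - u + v)
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

## ---- convex polygon helpers (shoelace area, Sutherland-Hodgman clip) ----

polygon_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Clip convex polygon `subj` (n x 2) by the half plane on the inner side of
# the directed edge a -> b of a counter-clockwise clip polygon.
clip_halfplane <- function(subj, a, b) {
  n <- nrow(subj)
  if (is.null(n) || n == 0) return(subj)
  ex <- b[1] - a[1]; ey <- b[2] - a[2]
  s <- ex * (subj[, 2] - a[2]) - ey * (subj[, 1] - a[1])  # >= 0 is inside (CCW)
  out <- matrix(0, n + 4, 2); k <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (s[i] >= -1e-12) { k <- k + 1; out[k, ] <- subj[i, ] }
    if ((s[i] > 1e-12 && s[j] < -1e-12) || (s[i] < -1e-12 && s[j] > 1e-12)) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1
      out[k, ] <- subj[i, ] + t * (subj[j, ] - subj[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# Intersection polygon of two convex polygons (both CCW in the working frame).
convex_intersect <- function(p, q) {
  out <- p
  nq <- nrow(q)
  for (i in seq_len(nq)) {
    j <- if (i == nq) 1L else i + 1L
    out <- clip_halfplane(out, q[i, ], q[j, ])
    if (nrow(out) == 0) return(out)
  }
  out
}

# Ensure counter-clockwise vertex order (positive signed area) in the (x, y)
# frame used for clipping.
ccw <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  if (s < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Rotated-box intersection over union
#'
#' Exact IoU of two oriented rectangles via convex polygon clipping
#' (Sutherland-Hodgman); no sampling or approximation.
#'
#' @param a,b [rotated_box()] objects.
#' @return IoU in `[0, 1]`.
#' @export
rotated_iou <- function(a, b) {
  pa <- ccw(box_corners(a)); pb <- ccw(box_corners(b))
  inter <- polygon_area(convex_intersect(pa, pb))
  aa <- a$length * a$width; ab <- b$length * b$width
  u <- aa + ab - inter
  if (u <= 0) return(0)
  min(1, max(0, inter / u))
}

#' Fraction of a rotated box inside an image frame
#'
#' Area of the intersection between the box and the axis-aligned frame
#' rectangle `[-0.5, w-0.5] x [-0.5, h-0.5]` (pixel-center convention: a
#' frame of `w` x `h` pixels spans half a pixel beyond the outermost pixel
#' centers), divided by the box area. A box is considered valid for labeling
#' when this fraction exceeds 2/3.
#'
#' @param box a [rotated_box()].
#' @param frame_w,frame_h frame dimensions in pixels.
#' @return Visible area fraction in `[0, 1]`.
#' @export
visibility_fraction <- function(box, frame_w, frame_h) {
  frame <- rbind(c(-0.5, -0.5), c(frame_w - 0.5, -0.5),
                 c(frame_w - 0.5, frame_h - 0.5), c(-0.5, frame_h - 0.5))
  p <- ccw(box_corners(box))
  inter <- polygon_area(convex_intersect(p, ccw(frame)))
  min(1, max(0, inter / (box$length * box$width)))
}

# Minimum-area-style refit used in tests and round trips: rebuild a
# rotated_box from 4 corner points (assumed a rectangle's vertices in order).
box_from_corners <- function(m) {
  e1 <- m[2, ] - m[1, ]; e2 <- m[3, ] - m[2, ]
  l1 <- sqrt(sum(e1^2)); l2 <- sqrt(sum(e2^2))
  ctr <- colMeans(m)
  if (l1 >= l2) {
    ang <- atan2(e1[2], e1[1]) * 180 / pi
    canonicalize_box(ctr[1], ctr[2], l1, l2, ang)
  } else {
    ang <- atan2(e2[2], e2[1]) * 180 / pi
    canonicalize_box(ctr[1], ctr[2], l2, l1, ang)
  }
}
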