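# Independent oracles and small fixture builders shared across tests.

# Brute-force peak scan: a cell survives iff it is >= all 8 neighbors
# (literal nested-loop reading of the rule, independent of extract_peaks).
brute_force_peaks <- function(hm) {
  h <- nrow(hm); w <- ncol(hm)
  keep <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && hm[ii, jj] > hm[i, j])
        ok <- FALSE
    }
    keep[i, j] <- ok
  }
  keep
}

# Monte-Carlo rotated IoU from uniform point sampling over the joint
# bounding box of the two rectangles.
mc_iou <- function(a, b, n = 20000) {
  pts_in_box <- function(px, py, bx) {
    th <- bx$angle_deg * pi / 180
    u <- cos(th) * (px - bx$cx) + sin(th) * (py - bx$cy)
    v <- -sin(th) * (px - bx$cx) + cos(th) * (py - bx$cy)
    abs(u) <= bx$length / 2 & abs(v) <= bx$width / 2
  }
  ca <- box_corners(a); cb <- box_corners(b)
  xr <- range(c(ca[, 1], cb[, 1])); yr <- range(c(ca[, 2], cb[, 2]))
  px <- stats::runif(n, xr[1], xr[2]); py <- stats::runif(n, yr[1], yr[2])
  ina <- pts_in_box(px, py, a); inb <- pts_in_box(px, py, b)
  if (!any(ina | inb)) return(0)
  sum(ina & inb) / sum(ina | inb)
}

# Random valid rotated box inside a frame.
random_box <- function(w = 100, h = 100) {
  len <- stats::runif(1, 10, 40)
  wid <- stats::runif(1, 5, len)
  rotated_box(stats::runif(1, 15, w - 15), stats::runif(1, 15, h - 15),
              len, wid, stats::runif(1, 0, 180))
}

# Ellipse re-measurement oracle: collect every rendered stoma pixel (any
# pixel deviating from the flat background level — dark rim, interior, and
# bright pore slit alike) around a known center and fit principal axes. For
# a uniformly filled ellipse the variance along a semi-axis a is a^2/4, so
# the axis extents are 4 * sqrt(eigenvalues).
refit_ellipse <- function(img, box, bg = 205, dev = 18) {
  r <- ceiling(box$length / 2) + 3
  x0 <- max(0, floor(box$cx - r)); x1 <- min(ncol(img) - 1, ceiling(box$cx + r))
  y0 <- max(0, floor(box$cy - r)); y1 <- min(nrow(img) - 1, ceiling(box$cy + r))
  sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  idx <- which(abs(sub - bg) > dev, arr.ind = TRUE)
  if (nrow(idx) < 10) return(NULL)
  xs <- idx[, 2] - 1 + x0; ys <- idx[, 1] - 1 + y0
  cx <- mean(xs); cy <- mean(ys)
  cv <- stats::cov(cbind(xs, ys))
  e <- eigen(cv)
  ang <- atan2(e$vectors[2, 1], e$vectors[1, 1]) * 180 / pi
  list(cx = cx, cy = cy,
       length = 4 * sqrt(e$values[1]), width = 4 * sqrt(e$values[2]),
       angle_deg = ang %% 180)
}

# Small deterministic annotation set.
tiny_annotations <- function() {
  annotation_set("tiny", 200, 150, 0.625,
                 list(rotated_box(60, 40, 64, 22.4, 30),
                      rotated_box(140, 100, 50, 20, 120),
                      rotated_box(100, 75, 70, 25, 0)))
}

angle_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}
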