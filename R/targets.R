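# Gaussian radius for heatmap targets: the minimum-overlap rule exactly as
# shipped throughout the keypoint-detection lineage (a center proposal
# shifted by up to r cells still overlaps the true box by at least
# `min_overlap` IoU in three limiting configurations; the lineage's root
# convention (b + sqrt(disc)) / 2 is kept on purpose — its wider radii make
# the learned blobs smooth and single-peaked, which the 3x3 max-pool
# decoding relies on).
gaussian_radius <- function(height, width, min_overlap = 0.7) {
  b1 <- height + width
  c1 <- width * height * (1 - min_overlap) / (1 + min_overlap)
  r1 <- (b1 + sqrt(max(0, b1^2 - 4 * c1))) / 2
  a2 <- 4
  b2 <- 2 * (height + width)
  c2 <- (1 - min_overlap) * width * height
  r2 <- (b2 + sqrt(max(0, b2^2 - 4 * a2 * c2))) / 2
  a3 <- 4 * min_overlap
  b3 <- -2 * min_overlap * (height + width)
  c3 <- (min_overlap - 1) * width * height
  r3 <- (b3 + sqrt(max(0, b3^2 - 4 * a3 * c3))) / 2
  max(1, min(r1, r2, r3))
}

# Idealized head arrays from encoded targets (a noiseless "perfect
# prediction"): used for encode/decode round trips.
targets_as_heads <- function(tg) {
  gh <- nrow(tg$heatmap_q); gw <- ncol(tg$heatmap_q)
  size <- array(1e-3, c(gh, gw, 2))
  off <- array(0, c(gh, gw, 2))
  ang <- matrix(0, gh, gw)
  for (k in seq_len(tg$K)) {
    yi <- tg$center_cells[k, 2] + 1L; xi <- tg$center_cells[k, 1] + 1L
    size[yi, xi, ] <- tg$size_S[k, ]
    off[yi, xi, ] <- tg$offset_O[k, ]
    ang[yi, xi] <- tg$angle_theta[k]
  }
  list(heatmap = tg$heatmap_q, size = size, offset = off, angle = ang,
       stride = tg$stride)
}

#' Encode annotations into head-aligned training targets
#'
#' Each box contributes: its center cell `floor(c / R)` on the stride-R
#' output grid; the sub-cell offset `c/R - floor(c/R)`; its size in
#' output-grid units `(length/R, width/R)`; its angle; and its per-stoma
#' maximum conductance (from the box's physical length/width and the image's
#' ground-truth density). The heatmap target is the pointwise maximum of a
#' Gaussian bump per object, with variance set by the minimum-overlap radius
#' rule (floor of one cell), and is exactly 1 at each center cell.
#'
#' @param annotations an [annotation_set()] (box centers must lie inside the
#'   image).
#' @param stride output stride `R` (default 4).
#' @param grid_h,grid_w output grid size; defaults to `ceiling(dim / stride)`
#'   (pass the network's padded grid when training).
#' @param density ground-truth stomatal density (mm^-2) used for the
#'   conductance targets; defaults to the set's own count/area.
#' @param params a [conductance_params()].
#' @return A list of class `head_targets`: `heatmap_q` (grid matrix),
#'   `size_S` (K x 2), `offset_O` (K x 2), `angle_theta` (K), `center_cells`
#'   (K x 2, 0-based x,y), `center_lin` (1-based linear indices), `gsmax_G`
#'   (K), `K`, `stride`.
#' @export
encode_targets <- function(annotations, stride = 4,
                           grid_h = NULL, grid_w = NULL,
                           density = NULL, params = conductance_params()) {
  h <- annotations$image_height_px
  w <- annotations$image_width_px
  if (is.null(grid_h)) grid_h <- as.integer(ceiling(h / stride))
  if (is.null(grid_w)) grid_w <- as.integer(ceiling(w / stride))
  boxes <- annotations$boxes
  K <- length(boxes)
  if (is.null(density))
    density <- if (K > 0) stomatal_density(K, w, h, annotations$pixel_scale) else 0
  q <- matrix(0, grid_h, grid_w)
  size_S <- matrix(0, K, 2)
  offset_O <- matrix(0, K, 2)
  angle_theta <- numeric(K)
  cells <- matrix(0L, K, 2)
  G <- numeric(K)
  for (k in seq_len(K)) {
    b <- boxes[[k]]
    if (b$cx < 0 || b$cx > w - 1 || b$cy < 0 || b$cy > h - 1)
      stop("encode_targets: box ", k, " center outside image; filter first")
    cxg <- b$cx / stride; cyg <- b$cy / stride
    cx0 <- floor(cxg); cy0 <- floor(cyg)
    cells[k, ] <- c(cx0, cy0)
    offset_O[k, ] <- c(cxg - cx0, cyg - cy0)
    size_S[k, ] <- c(b$length / stride, b$width / stride)
    angle_theta[k] <- b$angle_deg
    G[k] <- gsmax(b$length * annotations$pixel_scale,
                  b$width * annotations$pixel_scale, density, params)
    r <- gaussian_radius(b$width / stride, b$length / stride)
    sigma <- (2 * r + 1) / 6
    rr <- ceiling(3 * sigma)
    xs <- max(0, cx0 - rr):min(grid_w - 1, cx0 + rr)
    ys <- max(0, cy0 - rr):min(grid_h - 1, cy0 + rr)
    gx <- exp(-((xs - cx0)^2) / (2 * sigma^2))
    gy <- exp(-((ys - cy0)^2) / (2 * sigma^2))
    bump <- outer(gy, gx)
    win <- q[ys + 1, xs + 1, drop = FALSE]
    q[ys + 1, xs + 1] <- pmax(win, bump)
  }
  if (K > 0) {
    lin <- cells[, 2] + cells[, 1] * grid_h + 1L
    q[cbind(cells[, 2] + 1L, cells[, 1] + 1L)] <- 1
  } else lin <- integer(0)
  structure(list(heatmap_q = q, size_S = size_S, offset_O = offset_O,
                 angle_theta = angle_theta, center_cells = cells,
                 center_lin = as.integer(lin), gsmax_G = G, K = K,
                 stride = stride, density = density,
                 pixel_scale = annotations$pixel_scale),
            class = "head_targets")
}
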