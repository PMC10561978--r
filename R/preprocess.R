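#' Pad an image with a black border
#'
#' Adds a `border_px`-wide black (zero) border on all four sides so stomata
#' touching the frame edge can still be enclosed by a rotated box, shifting
#' every annotation center by `+border_px` in x and y. Length, width and
#' angle are unchanged.
#'
#' @param image numeric matrix, 8-bit grayscale (rows = y).
#' @param annotations an [annotation_set()] or `NULL`.
#' @param border_px non-negative border width (default 30).
#' @return A list with `image` and `annotations`.
#' @export
pad_border <- function(image, annotations = NULL, border_px = 30) {
  if (border_px < 0) stop("pad_border: border_px must be >= 0")
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h + 2 * border_px, w + 2 * border_px)
  out[(border_px + 1):(border_px + h), (border_px + 1):(border_px + w)] <- image
  ann <- annotations
  if (!is.null(ann)) {
    ann$boxes <- lapply(ann$boxes, function(b)
      rotated_box(b$cx + border_px, b$cy + border_px, b$length, b$width,
                  b$angle_deg))
    ann$image_width_px <- ann$image_width_px + 2L * as.integer(border_px)
    ann$image_height_px <- ann$image_height_px + 2L * as.integer(border_px)
  }
  list(image = out, annotations = ann)
}

#' Grayscale stretching parameters
#'
#' @param lo,hi input gray band mapped onto the full output range; must
#'   satisfy `0 <= lo < hi <= 255`. Defaults 210 and 255, the band occupied
#'   by translucent imprint backgrounds.
#' @return A list of class `stretch_params`.
#' @export
stretch_params <- function(lo = 210, hi = 255) {
  if (lo < 0 || hi > 255 || lo >= hi)
    stop("stretch_params: need 0 <= lo < hi <= 255")
  structure(list(lo = lo, hi = hi), class = "stretch_params")
}

#' Grayscale stretch
#'
#' Linearly maps the input band `[lo, hi]` onto the full 8-bit range:
#' `g' = round(255 * clip((g - lo) / (hi - lo), 0, 1))`. Values below `lo`
#' clip to 0 and above `hi` to 255, amplifying stomata/background contrast.
#' Monotone non-decreasing in `g`; the identity for `(lo, hi) = (0, 255)`.
#'
#' @param image numeric matrix of gray levels in `[0, 255]`.
#' @param params a [stretch_params()].
#' @return Stretched image matrix (integer-valued doubles in `[0, 255]`).
#' @export
gray_stretch <- function(image, params = stretch_params()) {
  if (!inherits(params, "stretch_params")) params <- do.call(stretch_params, params)
  t <- (image - params$lo) / (params$hi - params$lo)
  t[t < 0] <- 0; t[t > 1] <- 1
  round(255 * t)
}

#' Rotation augmentation with label transform
#'
#' Rotates the image about its center by `angle_deg` (counter-clockwise in
#' the y-down pixel frame, i.e. the same sense in which box angles are
#' measured), expanding the canvas to contain the whole rotated frame (fill
#' value 0, bilinear resampling). Box centers are mapped through the
#' identical affine transform; box angles become `(angle + angle_deg) mod
#' 180`; length and width are unchanged. Boxes whose visible fraction on the
#' new canvas is not greater than 2/3 are dropped.
#'
#' The defaults used for dataset expansion are 30, 45 and 90 degrees, but any
#' angle is accepted.
#'
#' @param image numeric matrix of gray levels.
#' @param annotations an [annotation_set()] or `NULL`.
#' @param angle_deg rotation angle in degrees.
#' @return A list with `image`, `annotations` and the 2x3 affine `transform`
#'   mapping source pixel coordinates to destination coordinates.
#' @export
rotate_augment <- function(image, annotations = NULL, angle_deg) {
  h <- nrow(image); w <- ncol(image)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # snap the right-angle cases exactly (cos(pi/2) is ~6e-17 in floating
  # point, which would otherwise grow the canvas by a spurious pixel)
  if (abs(ct) < 1e-12) ct <- 0
  if (abs(st) < 1e-12) st <- 0
  if (abs(abs(ct) - 1) < 1e-12) ct <- sign(ct)
  if (abs(abs(st) - 1) < 1e-12) st <- sign(st)
  # Expanded canvas
  w2 <- ceiling(w * abs(ct) + h * abs(st))
  h2 <- ceiling(w * abs(st) + h * abs(ct))
  cx0 <- (w - 1) / 2; cy0 <- (h - 1) / 2
  cx1 <- (w2 - 1) / 2; cy1 <- (h2 - 1) / 2
  # forward map: p' = R (p - c0) + c1, with R = [ct -st; st ct] (angle adds)
  # inverse map for resampling: p = R^T (p' - c1) + c0
  xs <- rep(0:(w2 - 1), each = h2) - cx1
  ys <- rep(0:(h2 - 1), times = w2) - cy1
  sx <- ct * xs + st * ys + cx0
  sy <- -st * xs + ct * ys + cy0
  out <- bilinear_sample(image, sx, sy)
  dim(out) <- c(h2, w2)
  ann <- annotations
  if (!is.null(ann)) {
    newb <- list()
    for (b in ann$boxes) {
      nx <- ct * (b$cx - cx0) - st * (b$cy - cy0) + cx1
      ny <- st * (b$cx - cx0) + ct * (b$cy - cy0) + cy1
      nb <- rotated_box(nx, ny, b$length, b$width, (b$angle_deg + angle_deg) %% 180)
      if (visibility_fraction(nb, w2, h2) > 2 / 3) newb[[length(newb) + 1]] <- nb
    }
    ann$boxes <- newb
    ann$image_width_px <- as.integer(w2)
    ann$image_height_px <- as.integer(h2)
    ann$image_id <- paste0(ann$image_id, sprintf("_rot%g", angle_deg))
  }
  list(image = out,
       annotations = ann,
       transform = matrix(c(ct, st, -st, ct, cx1 - ct * cx0 + st * cy0,
                            cy1 - st * cx0 - ct * cy0), 2, 3))
}

# Bilinear sampling of matrix `img` at fractional (x, y); zero outside.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- numeric(length(x))
  gather <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  val <- gather(x0, y0) * (1 - fx) * (1 - fy) +
    gather(x0 + 1, y0) * fx * (1 - fy) +
    gather(x0, y0 + 1) * (1 - fx) * fy +
    gather(x0 + 1, y0 + 1) * fx * fy
  val
}
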