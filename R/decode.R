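#' Extract heatmap peaks by 3x3 max pooling
#'
#' A grid cell survives iff its value equals the maximum of its 3x3
#' neighborhood (so plateau ties are all kept), replacing IoU-based NMS.
#' Survivors are sorted by score descending (ties broken by linear index),
#' truncated to the `top_k` strongest, then filtered by `score_threshold`.
#'
#' @param heatmap numeric matrix (rows = y, columns = x) with values in
#'   `(0, 1)`.
#' @param top_k maximum number of peaks retained (default 100).
#' @param score_threshold minimum peak score (default 0, keep all).
#' @return A data.frame with columns `x`, `y` (0-based grid coordinates) and
#'   `score`, ordered by decreasing score.
#' @export
extract_peaks <- function(heatmap, top_k = 100, score_threshold = 0) {
  h <- nrow(heatmap); w <- ncol(heatmap)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- heatmap
  nb_max <- heatmap
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb_max <- pmax(nb_max, pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
  }
  keep <- which(heatmap >= nb_max)
  if (!length(keep))
    return(data.frame(x = integer(0), y = integer(0), score = numeric(0)))
  sc <- heatmap[keep]
  ord <- order(-sc, keep)
  keep <- keep[ord]; sc <- sc[ord]
  if (length(keep) > top_k) { keep <- keep[seq_len(top_k)]; sc <- sc[seq_len(top_k)] }
  ok <- sc >= score_threshold
  keep <- keep[ok]; sc <- sc[ok]
  data.frame(x = ((keep - 1L) %/% h), y = ((keep - 1L) %% h), score = sc)
}

#' Decode head outputs into rotated-box detections
#'
#' For every surviving heatmap peak at grid cell `(x, y)` the sub-pixel
#' offset head gives `(dx, dy)`, so the object center in image pixels is
#' `((x + dx) * R, (y + dy) * R)`; the size head (in output-grid units) is
#' scaled by the stride `R`; the angle head gives the long-axis orientation.
#' No IoU-based NMS is applied.
#'
#' @param heads a `head_outputs` list with elements `heatmap` (H x W matrix),
#'   `size` (H x W x 2, length then width in grid units), `offset`
#'   (H x W x 2), `angle` (H x W matrix, degrees) and `stride`.
#' @param stride output stride `R`; defaults to `heads$stride`.
#' @param top_k,score_threshold passed to [extract_peaks()].
#' @return A list of detections, each a list with `box` (a [rotated_box()])
#'   and `score`.
#' @export
decode_detections <- function(heads, stride = heads$stride, top_k = 100,
                              score_threshold = 0.3) {
  pk <- extract_peaks(heads$heatmap, top_k = top_k,
                      score_threshold = score_threshold)
  out <- vector("list", nrow(pk))
  for (i in seq_len(nrow(pk))) {
    xi <- pk$x[i] + 1L; yi <- pk$y[i] + 1L
    dx <- heads$offset[yi, xi, 1]; dy <- heads$offset[yi, xi, 2]
    len <- heads$size[yi, xi, 1] * stride
    wid <- heads$size[yi, xi, 2] * stride
    len <- max(len, 1e-3); wid <- max(wid, 1e-3)
    ang <- heads$angle[yi, xi]
    box <- canonicalize_box((pk$x[i] + dx) * stride, (pk$y[i] + dy) * stride,
                            len, wid, ang)
    out[[i]] <- list(box = box, score = pk$score[i])
  }
  out
}

#' Per-image stomatal trait record
#'
#' Converts detections to physical traits: lengths and widths in micrometers,
#' count, stomatal density, and the anatomical maximum conductance computed
#' from the per-image mean length and mean width (the mean guard-cell width
#' standing in for pore depth) together with the image's density. Reported
#' `avg_*`, `density` and `gsmax` values are rounded half away from zero to 2
#' decimals; the raw per-stoma lists are kept unrounded.
#'
#' @param detections list of detections (`box` + `score`) or of
#'   [rotated_box()]es, in un-padded image coordinates.
#' @param image_w_px,image_h_px frame dimensions in pixels.
#' @param pixel_scale micrometers per pixel.
#' @param params a [conductance_params()].
#' @param image_id identifier copied into the record.
#' @return A list of class `trait_record` with fields `image_id`,
#'   `lengths_um`, `widths_um`, `count`, `avg_length_um`, `avg_width_um`,
#'   `density_per_mm2`, `gsmax_mol_m2_s`.
#' @export
measure_image <- function(detections, image_w_px, image_h_px,
                          pixel_scale = 0.625, params = conductance_params(),
                          image_id = "image") {
  boxes <- lapply(detections, function(d) if (inherits(d, "rotated_box")) d else d$box)
  lens <- vapply(boxes, function(b) b$length, numeric(1)) * pixel_scale
  wids <- vapply(boxes, function(b) b$width, numeric(1)) * pixel_scale
  n <- length(boxes)
  if (n == 0) {
    dens <- 0; g <- 0; al <- 0; aw <- 0
  } else {
    dens <- stomatal_density(n, image_w_px, image_h_px, pixel_scale)
    al <- mean(lens); aw <- mean(wids)
    g <- gsmax(al, aw, dens, params)
  }
  structure(list(image_id = image_id,
                 lengths_um = lens, widths_um = wids, count = n,
                 avg_length_um = round_half_up(al),
                 avg_width_um = round_half_up(aw),
                 density_per_mm2 = round_half_up(dens),
                 gsmax_mol_m2_s = round_half_up(g)),
            class = "trait_record")
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf("<trait_record> %s: %d stomata, %.2f x %.2f um (mean), %.2f mm^-2, gsmax %.2f mol m^-2 s^-1\n",
              x$image_id, x$count, x$avg_length_um, x$avg_width_um,
              x$density_per_mm2, x$gsmax_mol_m2_s))
  invisible(x)
}

#' Write trait records as a CSV table
#'
#' Columns mirror the standard trait table layout: image_id, avg_length_um,
#' avg_width_um, count, density_per_mm2, gsmax.
#'
#' @param records list of `trait_record`s.
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_trait_table <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(image_id = r$image_id, avg_length_um = r$avg_length_um,
               avg_width_um = r$avg_width_um, count = r$count,
               density_per_mm2 = r$density_per_mm2,
               gsmax = r$gsmax_mol_m2_s)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
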