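#' Configuration for the synthetic epidermis image generator
#'
#' Describes the study conditions the generator emulates: elliptical stomata
#' 30-47 um long and 12-18 um wide at random orientation, densities of
#' 34-62 stomata per mm^2, a textured pavement-cell background, additive
#' sensor noise, and occasional unannotated bubble distractors. The nominal
#' production frame is 1000 x 667 px at 0.625 um/px; the default here is a
#' 256 x 256 px test-scale frame at the same physical scale.
#'
#' @param image_width_px,image_height_px frame size in pixels.
#' @param pixel_scale micrometers per pixel (default 0.625).
#' @param n_stomata_range integer pair; if `NULL`, derived from the 34-62
#'   mm^-2 density band and the frame area (minimum 1).
#' @param length_range_um,width_range_um stomatal long/short axis ranges in
#'   micrometers.
#' @param angle_range_deg orientation range in degrees, within `[0, 180)`.
#' @param background_texture one of `"cell-grid"` (pavement-cell walls,
#'   default), `"perlin"` (smooth blotches) or `"flat"`.
#' @param noise_sd additive Gaussian noise standard deviation in gray levels.
#' @param distractor_rate expected number of circular bubble/droplet
#'   distractors per image (Poisson); distractors are rendered but never
#'   annotated.
#' @param max_overlap maximum allowed rotated IoU between placed stomata.
#' @param max_retries bounded rejection-sampling retries per stoma before a
#'   placement error is raised.
#' @param bg_gray,rim_gray,interior_gray,pore_gray rendering gray levels: the
#'   background plateau, the dark guard-cell rim, the guard-cell interior and
#'   the light pore slit. The source micrograph intensity statistics are not
#'   standardized, so these are free contrast parameters.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_width_px = 256, image_height_px = 256,
                         pixel_scale = 0.625,
                         n_stomata_range = NULL,
                         length_range_um = c(30, 47),
                         width_range_um = c(12, 18),
                         angle_range_deg = c(0, 180),
                         background_texture = c("cell-grid", "perlin", "flat"),
                         noise_sd = 6,
                         distractor_rate = 0.3,
                         max_overlap = 0.05,
                         max_retries = 100,
                         bg_gray = 205, rim_gray = 95, interior_gray = 170,
                         pore_gray = 235) {
  background_texture <- match.arg(background_texture)
  if (pixel_scale <= 0) stop("synth_config: pixel_scale must be positive")
  if (image_width_px < 8 || image_height_px < 8)
    stop("synth_config: frame too small")
  chk_range <- function(r, nm) {
    if (length(r) != 2 || any(!is.finite(r)) || r[1] > r[2] || r[1] <= 0)
      stop("synth_config: invalid ", nm)
  }
  chk_range(length_range_um, "length_range_um")
  chk_range(width_range_um, "width_range_um")
  if (length(angle_range_deg) != 2 || angle_range_deg[1] < 0 ||
      angle_range_deg[2] > 180 || angle_range_deg[1] > angle_range_deg[2])
    stop("synth_config: angle_range_deg must lie within [0, 180]")
  area_mm2 <- image_width_px * image_height_px * pixel_scale^2 * 1e-6
  if (is.null(n_stomata_range)) {
    n_stomata_range <- c(max(1, round(34 * area_mm2)),
                         max(1, round(62 * area_mm2)))
  }
  n_stomata_range <- as.integer(n_stomata_range)
  if (n_stomata_range[1] < 0 || n_stomata_range[1] > n_stomata_range[2])
    stop("synth_config: invalid n_stomata_range")
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 pixel_scale = pixel_scale,
                 n_stomata_range = n_stomata_range,
                 length_range_um = length_range_um,
                 width_range_um = width_range_um,
                 angle_range_deg = angle_range_deg,
                 background_texture = background_texture,
                 noise_sd = noise_sd,
                 distractor_rate = distractor_rate,
                 max_overlap = max_overlap,
                 max_retries = as.integer(max_retries),
                 bg_gray = bg_gray, rim_gray = rim_gray,
                 interior_gray = interior_gray, pore_gray = pore_gray,
                 area_mm2 = area_mm2),
            class = "synth_config")
}

# Run expr under a private, seeded RNG stream; the caller's RNG state is
# untouched.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

render_background <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  img <- matrix(cfg$bg_gray, h, w)
  if (cfg$background_texture == "flat") return(img)
  if (cfg$background_texture == "perlin") {
    # value-noise blotches: coarse random grid, bilinear upsample
    gh <- max(3, h %/% 32); gw <- max(3, w %/% 32)
    coarse <- matrix(stats::rnorm(gh * gw, 0, 10), gh, gw)
    xs <- rep(seq(0, gw - 1, length.out = w), each = h)
    ys <- rep(seq(0, gh - 1, length.out = h), times = w)
    img <- img + matrix(bilinear_sample(coarse, xs, ys), h, w)
    return(img)
  }
  # "cell-grid": pavement cells as a jittered Voronoi partition; cell walls
  # (where the two nearest seeds are nearly equidistant) drawn darker, with
  # a faint per-cell brightness offset.
  n_cells <- max(4, round(w * h / 2500))
  sx <- stats::runif(n_cells, 0, w - 1)
  sy <- stats::runif(n_cells, 0, h - 1)
  shade <- stats::rnorm(n_cells, 0, 4)
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  d1 <- rep(Inf, w * h); d2 <- rep(Inf, w * h); nearest <- integer(w * h)
  for (i in seq_len(n_cells)) {
    d <- (px - sx[i])^2 + (py - sy[i])^2
    upd2 <- d < d2 & d >= d1
    d2[upd2] <- d[upd2]
    upd1 <- d < d1
    d2[upd1] <- d1[upd1]
    d1[upd1] <- d[upd1]
    nearest[upd1] <- i
  }
  wallness <- pmax(0, 1 - (sqrt(d2) - sqrt(d1)) / 1.5)  # ~1 on cell borders
  vals <- cfg$bg_gray + shade[nearest] - 28 * wallness
  matrix(vals, h, w)
}

# Render one elliptical stoma onto img (in place via return): two concentric
# ellipses (dark guard-cell rim around a lighter interior) plus a bright pore
# slit along the long axis. Soft ~1 px edge blending.
render_stoma <- function(img, cx, cy, a, b, angle_deg) {
  h <- nrow(img); w <- ncol(img)
  th <- angle_deg * pi / 180; ct <- cos(th); st <- sin(th)
  r <- max(a, b) + 2
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- rep(x0:x1, each = y1 - y0 + 1) - cx
  ys <- rep(y0:y1, times = x1 - x0 + 1) - cy
  u <- ct * xs + st * ys
  v <- -st * xs + ct * ys
  rho <- sqrt((u / a)^2 + (v / b)^2)
  sub <- img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)]
  vals <- as.vector(sub)
  # edge softness ~1 px in the radial direction (approximate by rho units)
  soft <- 1 / max(1, min(a, b))
  aa_out <- pmin(1, pmax(0, (1 - rho) / soft))       # 1 inside outer ellipse
  rim_gray <- attr(img, "rim_gray"); int_gray <- attr(img, "interior_gray")
  pore_gray <- attr(img, "pore_gray")
  inner <- pmin(1, pmax(0, (0.72 - rho) / soft))     # 1 inside interior
  base <- rim_gray * (1 - inner) + int_gray * inner
  pr <- sqrt((u / (0.80 * a))^2 + (v / (0.20 * b))^2)
  pore <- pmin(1, pmax(0, (1 - pr) / (3 * soft)))
  base <- base * (1 - pore) + pore_gray * pore
  vals <- vals * (1 - aa_out) + base * aa_out
  img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- vals
  img
}

render_bubble <- function(img, cx, cy, r) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(0, floor(cx - r - 2)); x1 <- min(w - 1, ceiling(cx + r + 2))
  y0 <- max(0, floor(cy - r - 2)); y1 <- min(h - 1, ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- rep(x0:x1, each = y1 - y0 + 1) - cx
  ys <- rep(y0:y1, times = x1 - x0 + 1) - cy
  rho <- sqrt(xs^2 + ys^2) / r
  sub <- as.vector(img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)])
  ring <- pmin(1, pmax(0, 1 - abs(rho - 0.9) / 0.18))   # dark ring
  core <- pmin(1, pmax(0, (0.7 - rho) / 0.15))          # bright center
  sub <- sub * (1 - ring) + 80 * ring
  sub <- sub * (1 - core) + 240 * core
  img[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- sub
  img
}

#' Generate one synthetic epidermis image with ground truth
#'
#' Renders `n` stomata (drawn uniformly from `config$n_stomata_range`) as
#' darker-rimmed ellipses with a lighter pore slit on a textured background,
#' using bounded rejection sampling so that placed stomata overlap at most
#' `config$max_overlap` in rotated IoU and every annotated stoma has more
#' than 2/3 of its box area inside the frame (stomata may hang up to 1/3 off
#' the edge). Circular bubble distractors are rendered but never annotated.
#' The annotations are the tight rotated bounding boxes of the rendered
#' ellipses. Deterministic for a fixed `(config, seed)`.
#'
#' @param config a [synth_config()].
#' @param seed non-negative integer seed.
#' @return A list of class `synth_sample`: `image` (H x W gray matrix,
#'   0-255), `annotations` (an [annotation_set()]), `pixel_scale`,
#'   `seed_used`.
#' @export
generate_sample <- function(config, seed) {
  stopifnot(inherits(config, "synth_config"), seed >= 0)
  with_seed(seed, {
    w <- config$image_width_px; h <- config$image_height_px
    img <- render_background(config)
    attr(img, "rim_gray") <- config$rim_gray
    attr(img, "interior_gray") <- config$interior_gray
    attr(img, "pore_gray") <- config$pore_gray
    n <- if (config$n_stomata_range[1] == config$n_stomata_range[2])
      config$n_stomata_range[1]
    else sample(config$n_stomata_range[1]:config$n_stomata_range[2], 1)
    boxes <- list()
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(config$max_retries)) {
        len_um <- stats::runif(1, config$length_range_um[1], config$length_range_um[2])
        wid_um <- stats::runif(1, config$width_range_um[1], config$width_range_um[2])
        wid_um <- min(wid_um, len_um)  # each stoma satisfies length >= width
        ang <- stats::runif(1, config$angle_range_deg[1], config$angle_range_deg[2])
        if (ang >= 180) ang <- ang - 180
        len <- len_um / config$pixel_scale
        wid <- wid_um / config$pixel_scale
        cx <- stats::runif(1, 0, w - 1)
        cy <- stats::runif(1, 0, h - 1)
        cand <- rotated_box(cx, cy, len, wid, ang)
        if (visibility_fraction(cand, w, h) <= 2 / 3) next
        ious <- vapply(boxes, function(b) rotated_iou(b, cand), numeric(1))
        if (length(ious) && max(ious) > config$max_overlap) next
        boxes[[length(boxes) + 1]] <- cand
        placed <- TRUE
        break
      }
      if (!placed)
        stop("generate_sample: could not place stoma ", i, " within ",
             config$max_retries, " retries (frame too crowded)")
    }
    for (b in boxes)
      img <- render_stoma(img, b$cx, b$cy, b$length / 2, b$width / 2, b$angle_deg)
    n_bub <- stats::rpois(1, config$distractor_rate)
    for (k in seq_len(n_bub)) {
      img <- render_bubble(img, stats::runif(1, 0, w - 1),
                           stats::runif(1, 0, h - 1), stats::runif(1, 5, 12))
    }
    if (config$noise_sd > 0)
      img <- img + matrix(stats::rnorm(w * h, 0, config$noise_sd), h, w)
    img <- round(pmin(pmax(img, 0), 255))
    attributes(img) <- list(dim = c(h, w))
    structure(list(image = img,
                   annotations = annotation_set(
                     sprintf("synth_%06d", as.integer(seed)), w, h,
                     config$pixel_scale, boxes),
                   pixel_scale = config$pixel_scale,
                   seed_used = as.integer(seed)),
              class = "synth_sample")
  })
}

#' @export
print.synth_sample <- function(x, ...) {
  cat(sprintf("<synth_sample> %s: %dx%d px, %d stomata (seed %d)\n",
              x$annotations$image_id, ncol(x$image), nrow(x$image),
              length(x$annotations$boxes), x$seed_used))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` 8-bit grayscale PNGs, one annotation JSON per image, and
#' a `manifest.json` recording per-image seeds and a 3:1 train/validation
#' split (the first `floor(3 n / 4)` images train, the rest validation).
#' Rerunning with the same configuration and seed reproduces identical files.
#'
#' @param config a [synth_config()].
#' @param n_images number of images (0 gives an empty manifest, no files).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; image `i` uses `seed + 7919 * i`.
#' @return The manifest, invisibly (also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
generate_dataset <- function(config, n_images, out_dir, seed = 0) {
  stopifnot(inherits(config, "synth_config"), n_images >= 0)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stop("generate_dataset: cannot create output directory: ", out_dir)
  }
  n_train <- floor(3 * n_images / 4)
  entries <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    si <- as.integer(seed) + 7919L * i
    smp <- generate_sample(config, si)
    id <- sprintf("img_%04d", i)
    img_file <- paste0(id, ".png")
    ann_file <- paste0(id, ".json")
    png::writePNG(smp$image / 255, file.path(out_dir, img_file))
    smp$annotations$image_id <- id
    write_annotations(smp$annotations, file.path(out_dir, ann_file))
    entries[[i]] <- list(image_id = id, image = img_file,
                         annotations = ann_file, seed = si,
                         split = if (i <= n_train) "train" else "val")
  }
  manifest <- list(n_images = n_images,
                   pixel_scale_um_per_px = config$pixel_scale,
                   image_width_px = config$image_width_px,
                   image_height_px = config$image_height_px,
                   master_seed = as.integer(seed),
                   images = entries)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

#' Read a dataset manifest and its samples
#'
#' @param dir dataset directory holding `manifest.json`.
#' @return A list with `manifest` and `samples` (each with `image` matrix in
#'   0-255 gray levels, `annotations`, `split`).
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("read_dataset: no manifest.json in ", dir)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  samples <- lapply(manifest$images, function(e) {
    arr <- png::readPNG(file.path(dir, e$image))
    if (length(dim(arr)) == 3) arr <- arr[, , 1]
    list(image = round(arr * 255),
         annotations = read_annotations(file.path(dir, e$annotations)),
         split = e$split)
  })
  list(manifest = manifest, samples = samples)
}
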