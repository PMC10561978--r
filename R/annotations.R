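#' Annotation set for one image
#'
#' Container pairing an image's identity and geometry (dimensions, physical
#' pixel scale) with its rotated-box stomata labels.
#'
#' @param image_id character scalar.
#' @param image_width_px,image_height_px positive integer dimensions.
#' @param pixel_scale physical scale in micrometers per pixel (default 0.625,
#'   the nominal scale of the 10x objective micrographs this toolkit targets).
#' @param boxes list of [rotated_box()] objects (may be empty).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, image_width_px, image_height_px,
                           pixel_scale = 0.625, boxes = list()) {
  if (image_width_px <= 0 || image_height_px <= 0)
    stop("annotation_set: image dimensions must be positive")
  if (pixel_scale <= 0) stop("annotation_set: pixel_scale must be positive")
  if (!all(vapply(boxes, inherits, logical(1), "rotated_box")))
    stop("annotation_set: boxes must be rotated_box objects")
  structure(list(image_id = as.character(image_id),
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 pixel_scale = as.numeric(pixel_scale),
                 boxes = boxes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s  %dx%d px @ %.4g um/px  %d stomata\n",
              x$image_id, x$image_width_px, x$image_height_px,
              x$pixel_scale, length(x$boxes)))
  invisible(x)
}

#' Write rotated-box annotations to JSON
#'
#' The on-disk dialect is a single JSON object:
#' `{"image_id", "width", "height", "pixel_scale_um_per_px",
#'   "stomata": [{"cx","cy","length","width","angle_deg"}, ...]}`.
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  stom <- lapply(set$boxes, function(b)
    list(cx = b$cx, cy = b$cy, length = b$length, width = b$width,
         angle_deg = b$angle_deg))
  obj <- list(image_id = set$image_id,
              width = set$image_width_px,
              height = set$image_height_px,
              pixel_scale_um_per_px = set$pixel_scale,
              stomata = stom)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) stop("write_annotations: cannot write '",
                                          path, "': ", conditionMessage(e)))
  invisible(path)
}

#' Read rotated-box annotations from JSON
#'
#' Boxes whose stored `width` exceeds `length` are canonicalized on load
#' (sides swapped, angle rotated by 90 degrees modulo 180). Unknown JSON keys
#' are ignored. Malformed records raise an error naming the offending box.
#'
#' @param path input file path.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("read_annotations: no such file: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("read_annotations: malformed JSON in '",
                                           path, "': ", conditionMessage(e)))
  need <- c("image_id", "width", "height", "pixel_scale_um_per_px", "stomata")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("read_annotations: missing mandatory key(s): ",
         paste(miss, collapse = ", "))
  boxes <- lapply(seq_along(obj$stomata), function(i) {
    s <- obj$stomata[[i]]
    f <- c("cx", "cy", "length", "width", "angle_deg")
    if (!all(f %in% names(s)))
      stop("read_annotations: stomata record ", i, " lacks field(s): ",
           paste(setdiff(f, names(s)), collapse = ", "))
    vals <- vapply(f, function(k) as.numeric(s[[k]]), numeric(1))
    if (any(!is.finite(vals)))
      stop("read_annotations: stomata record ", i, " has non-finite values")
    if (vals["length"] <= 0 || vals["width"] <= 0)
      stop("read_annotations: stomata record ", i, " has non-positive sides")
    canonicalize_box(vals["cx"], vals["cy"], vals["length"], vals["width"],
                     vals["angle_deg"])
  })
  annotation_set(obj$image_id, obj$width, obj$height,
                 obj$pixel_scale_um_per_px, boxes)
}
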