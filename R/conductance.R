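#' Physical constants for the anatomical conductance model
#'
#' Diffusivity of water vapor in air and molar volume of air, both at 25
#' degrees Celsius and 101.3 kPa.
#'
#' @param d diffusivity of water in air, m^2 s^-1 (default 24.9e-6).
#' @param v molar volume of air, m^3 mol^-1 (default 22.4e-3).
#' @return A list of class `conductance_params`.
#' @export
conductance_params <- function(d = 24.9e-6, v = 22.4e-3) {
  if (d <= 0 || v <= 0) stop("conductance_params: d and v must be positive")
  structure(list(d = d, v = v), class = "conductance_params")
}

#' Maximum stomatal aperture area
#'
#' Models the fully open pore as a circle-equivalent ellipse of the stomatal
#' length: `alpha_max = pi * SL^2 / 4`.
#'
#' @param SL stomatal length in micrometers (vectorized, all `>= 0`).
#' @return Aperture area in square micrometers.
#' @export
alpha_max <- function(SL) {
  if (any(!is.finite(SL)) || any(SL < 0))
    stop("alpha_max: SL must be finite and non-negative")
  pi * SL^2 / 4
}

#' Anatomical maximum stomatal conductance
#'
#' The diffusion-limited upper bound on stomatal conductance to water vapor,
#' computed from anatomy alone:
#' \deqn{g_{smax} = \frac{d \, SD \, \alpha_{max}}
#'   {v \left(l + \frac{\pi}{2}\sqrt{\alpha_{max}/\pi}\right)}}
#' with \eqn{\alpha_{max} = \pi SL^2/4}, so the end-correction term
#' \eqn{(\pi/2)\sqrt{\alpha_{max}/\pi}} equals \eqn{(\pi/4) SL}. The pore
#' (cavity) depth `l` is taken equal to the guard-cell width, the usual
#' anatomical proxy.
#'
#' @param SL stomatal length in micrometers.
#' @param l pore depth (guard-cell width) in micrometers.
#' @param SD stomatal density in stomata per square millimeter.
#' @param params a [conductance_params()].
#' @return Conductance in mol m^-2 s^-1. Vectorized over `SL`, `l`, `SD`.
#'   The degenerate case `SL = 0` (and hence zero aperture) returns 0.
#' @examples
#' gsmax(42.09, 14.35, 53.74)  # 1.7533
#' @export
gsmax <- function(SL, l, SD, params = conductance_params()) {
  if (any(!is.finite(SL)) || any(!is.finite(l)) || any(!is.finite(SD)))
    stop("gsmax: inputs must be finite")
  if (any(SL < 0) || any(l < 0) || any(SD < 0))
    stop("gsmax: inputs must be non-negative")
  n <- max(length(SL), length(l), length(SD))
  SL <- rep_len(SL, n); l <- rep_len(l, n); SD <- rep_len(SD, n)
  am_m2 <- alpha_max(SL) * 1e-12          # um^2 -> m^2
  depth_m <- (l + (pi / 4) * SL) * 1e-6   # um  -> m
  sd_m2 <- SD * 1e6                       # mm^-2 -> m^-2
  out <- numeric(n)
  ok <- depth_m > 0
  out[ok] <- (params$d * sd_m2 * am_m2 / (params$v * depth_m))[ok]
  out
}

#' Stomatal density of an imaged frame
#'
#' @param count number of stomata in the frame.
#' @param image_w_px,image_h_px frame dimensions in pixels (excluding any
#'   added border padding).
#' @param pixel_scale micrometers per pixel.
#' @return Density in stomata per square millimeter.
#' @examples
#' stomatal_density(11, 1000, 667, 0.625)  # 42.22 mm^-2
#' @export
stomatal_density <- function(count, image_w_px, image_h_px, pixel_scale = 0.625) {
  if (image_w_px <= 0 || image_h_px <= 0 || pixel_scale <= 0)
    stop("stomatal_density: frame dimensions and pixel scale must be positive")
  area_mm2 <- image_w_px * image_h_px * pixel_scale^2 * 1e-6
  if (area_mm2 <= 0) stop("stomatal_density: zero imaged area")
  count / area_mm2
}

# Round half away from zero (base round() is half-to-even); reported traits
# use this convention at 2 decimals.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
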