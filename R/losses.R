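#' Loss weights and focal-loss hyperparameters
#'
#' @param alpha focal exponent on the prediction (default 2).
#' @param beta suppression exponent on the Gaussian neighborhood of centers
#'   (default 4).
#' @param heatmap,offset,size,angle,conductance per-term weights; the default
#'   of 1 everywhere reproduces the plain five-term sum.
#' @return A list of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 2, beta = 4, heatmap = 1, offset = 1,
                         size = 1, angle = 1, conductance = 1) {
  if (alpha <= 0 || beta <= 0) stop("loss_weights: alpha, beta must be > 0")
  w <- c(heatmap = heatmap, offset = offset, size = size, angle = angle,
         conductance = conductance)
  if (any(w < 0)) stop("loss_weights: weights must be >= 0")
  structure(list(alpha = alpha, beta = beta, w = w), class = "loss_weights")
}

## ---- plain numeric forms (public API; shared with the tape ops) ----

focal_value_grad <- function(p, q, alpha, beta, n_norm, want_grad = FALSE) {
  pos <- q == 1
  lv <- numeric(length(p))
  lv[pos] <- -(1 - p[pos])^alpha * log(p[pos])
  lv[!pos] <- -(1 - q[!pos])^beta * p[!pos]^alpha * log1p(-p[!pos])
  out <- sum(lv) / n_norm
  if (!want_grad) return(out)
  g <- numeric(length(p))
  g[pos] <- (alpha * (1 - p[pos])^(alpha - 1) * log(p[pos]) -
               (1 - p[pos])^alpha / p[pos])
  g[!pos] <- -(1 - q[!pos])^beta *
    (alpha * p[!pos]^(alpha - 1) * log1p(-p[!pos]) -
       p[!pos]^alpha / (1 - p[!pos]))
  list(value = out, grad = g / n_norm)
}

#' Penalty-reduced focal loss for the center heatmap
#'
#' Positives (cells where the target `q` equals 1) contribute
#' `-(1-p)^alpha log p`; all other cells contribute
#' `-(1-q)^beta p^alpha log(1-p)`, so the Gaussian shoulder of each center
#' softens the negative penalty nearby. The sum is divided by the number of
#' object centers (minimum 1), the usual keypoint normalization. Zero exactly
#' when `p == q` on `{0,1}` targets (approached in the sigmoid limit).
#'
#' @param p predicted heatmap, all values strictly inside (0, 1).
#' @param q target heatmap in `[0, 1]`.
#' @param alpha,beta focal exponents (defaults 2 and 4).
#' @param n_norm normalizer; defaults to `max(1, sum(q == 1))`.
#' @return Non-negative scalar.
#' @export
heatmap_loss <- function(p, q, alpha = 2, beta = 4, n_norm = NULL) {
  if (any(p <= 0) || any(p >= 1))
    stop("heatmap_loss: predictions must lie strictly in (0,1); apply a sigmoid")
  if (is.null(n_norm)) n_norm <- max(1, sum(q == 1))
  focal_value_grad(as.vector(p), as.vector(q), alpha, beta, n_norm)
}

#' L1 regression losses at ground-truth centers
#'
#' Mean absolute difference between predictions gathered at the K annotated
#' center cells and their targets: over all `2K` components for offsets and
#' sizes, over the K instances for angles. With `wrap = TRUE` the angular
#' difference is taken modulo 180 degrees (`min(|d|, 180 - |d|)`); the
#' default `wrap = FALSE` is the plain absolute difference. `K = 0` returns
#' 0.
#'
#' @param pred,target numeric matrices `K x 2` (offset/size) or vectors of
#'   length K (angle).
#' @return Non-negative scalar.
#' @export
offset_loss <- function(pred, target) {
  if (length(pred) == 0) return(0)
  mean(abs(pred - target))
}

#' @rdname offset_loss
#' @export
size_loss <- function(pred, target) {
  if (length(pred) == 0) return(0)
  mean(abs(pred - target))
}

#' @rdname offset_loss
#' @param wrap treat angles as equivalent modulo 180 degrees.
#' @export
angle_loss <- function(pred, target, wrap = FALSE) {
  if (length(pred) == 0) return(0)
  d <- pred - target
  if (wrap) {
    e <- ((d %% 180) + 180) %% 180
    mean(pmin(e, 180 - e))
  } else {
    mean(abs(d))
  }
}

# dG/dSL and dG/dl of the conductance closed form, SL and l in micrometers.
gsmax_grad <- function(SL, l, SD, params = conductance_params()) {
  K0 <- params$d * SD * pi / (4 * params$v)
  D <- l + pi * SL / 4
  list(G = K0 * SL^2 / D,
       dSL = K0 * (2 * SL * D - SL^2 * pi / 4) / D^2,
       dl = -K0 * SL^2 / D^2)
}

#' Stomatal-conductance loss
#'
#' Mean absolute difference between the per-stoma maximum conductance implied
#' by the predicted sizes and by the true boxes. Both use the image's
#' ground-truth density, so the term isolates the trait-size error (a
#' predicted count is not differentiable). Non-positive predicted sizes are
#' clamped to a small epsilon (with a warning counter attribute).
#'
#' @param pred_size_grid K x 2 matrix of predicted (length, width) in
#'   output-grid units at the ground-truth center cells.
#' @param true_boxes list of K [rotated_box()]es (image pixels).
#' @param image_density ground-truth stomatal density, mm^-2.
#' @param pixel_scale micrometers per pixel.
#' @param stride output stride R.
#' @param params a [conductance_params()].
#' @return Non-negative scalar with attribute `n_clamped`.
#' @export
conductance_loss <- function(pred_size_grid, true_boxes, image_density,
                             pixel_scale = 0.625, stride = 4,
                             params = conductance_params()) {
  K <- length(true_boxes)
  if (K == 0) return(structure(0, n_clamped = 0L))
  eps <- 1e-3
  raw <- pred_size_grid * stride * pixel_scale
  n_clamped <- sum(raw < eps)
  um <- pmax(raw, eps)
  Ghat <- gsmax_grad(um[, 1], um[, 2], image_density, params)$G
  G <- vapply(true_boxes, function(b)
    gsmax(b$length * pixel_scale, b$width * pixel_scale, image_density,
          params), numeric(1))
  structure(mean(abs(Ghat - G)), n_clamped = as.integer(n_clamped))
}

#' Total training loss
#'
#' Weighted sum of the five components; unit weights reproduce the plain sum
#' `L = L_H + L_off + L_size + L_ang + L_con`.
#'
#' @param components named numeric vector or list with elements `heatmap`,
#'   `offset`, `size`, `angle`, `conductance`.
#' @param weights a [loss_weights()].
#' @return Scalar with attribute `breakdown` (the weighted components).
#' @export
total_loss <- function(components, weights = loss_weights()) {
  comp <- unlist(components)[names(weights$w)]
  comp[is.na(comp)] <- 0
  wc <- weights$w * comp
  structure(sum(wc), breakdown = wc)
}

## ---- tape forms used in training ----

focal_loss_fwd <- function(tape, p_node, q, alpha, beta) {
  pv <- pmin(pmax(as.vector(p_node$value), 1e-7), 1 - 1e-7)
  n_norm <- max(1, sum(q == 1))
  vg <- focal_value_grad(pv, as.vector(q), alpha, beta, n_norm, want_grad = TRUE)
  new_node(tape, vg$value, backward = function(nd) {
    g <- nd$grad * vg$grad
    dim(g) <- dim(p_node$value)
    acc_grad(p_node, g)
  })
}

l1_loss_fwd <- function(tape, pred_node, target) {
  n <- length(target)
  if (n == 0) return(new_node(tape, 0, backward = function(nd) NULL))
  d <- pred_node$value - target
  new_node(tape, mean(abs(d)), backward = function(nd) {
    acc_grad(pred_node, nd$grad * sign(d) / n)
  })
}

angle_loss_fwd <- function(tape, pred_node, target, wrap = FALSE) {
  n <- length(target)
  if (n == 0) return(new_node(tape, 0, backward = function(nd) NULL))
  d <- as.vector(pred_node$value) - target
  if (!wrap) {
    v <- mean(abs(d)); g <- sign(d) / n
  } else {
    e <- ((d %% 180) + 180) %% 180
    v <- mean(pmin(e, 180 - e))
    g <- ifelse(e < 90, 1, -1) * ifelse(e == 0, 0, 1) / n
  }
  new_node(tape, v, backward = function(nd) {
    gg <- nd$grad * g
    dim(gg) <- dim(pred_node$value)
    acc_grad(pred_node, gg)
  })
}

cond_loss_fwd <- function(tape, size_node, true_G, image_density, pixel_scale,
                          stride, params) {
  K <- length(true_G)
  if (K == 0) return(new_node(tape, 0, backward = function(nd) NULL))
  eps <- 1e-3
  scale <- stride * pixel_scale
  raw <- size_node$value * scale
  um <- pmax(raw, eps)
  gg <- gsmax_grad(um[, 1], um[, 2], image_density, params)
  d <- gg$G - true_G
  v <- mean(abs(d))
  new_node(tape, v, backward = function(nd) {
    s <- nd$grad * sign(d) / K
    dsz <- cbind(s * gg$dSL, s * gg$dl) * scale
    dsz[raw < eps] <- 0   # clamped: no gradient
    acc_grad(size_node, dsz)
  })
}
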