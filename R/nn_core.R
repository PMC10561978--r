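# Minimal reverse-mode autodiff on dense arrays.
#
# Feature maps are H x W x C arrays (rows = y, column-major). A "tape" records
# operation nodes in execution order; backward() walks it in reverse. Nodes
# and parameters are environments so gradients accumulate in place.
# Convolutions are im2col + BLAS gemm; the im2col index tables (and the
# matching scatter tables for the backward pass) are cached per shape.

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 128L)
  t$n <- 0L
  t
}

tape_push <- function(tape, nd) {
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

# A node: value plus a backward closure that routes the node's accumulated
# gradient to its parents. Leaves (inputs, parameters) have no backward.
new_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  if (!is.null(backward) && !is.null(tape)) tape_push(tape, nd)
  nd
}

new_leaf <- function(value, nograd = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$nograd <- nograd
  nd
}

acc_grad <- function(nd, g) {
  if (isTRUE(nd$nograd)) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Backpropagate from scalar node `root`; `seed` is d(loss_total)/d(root).
tape_backward <- function(tape, root, seed = 1) {
  root$grad <- seed
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad)) nd$backward(nd)
    tape$nodes[i] <- list(NULL)  # release caches as we go
  }
  tape$n <- 0L
  invisible(NULL)
}

## ---- parameters ----

new_param <- function(value, name = "") {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$name <- name
  p
}

# Collect all parameter environments of a (possibly nested) module list.
collect_params <- function(mod) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x)) { out[[length(out) + 1]] <<- x; return() }
    if (is.list(x)) for (el in x) walk(el)
  }
  walk(mod$params)
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- im2col cache ----

## ---- layers ----

he_init <- function(n_in, n_out, gain = 2) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(gain / n_in)), n_in, n_out)
}

make_conv <- function(c_in, c_out, k = 3, stride = 1L, pad = (k - 1L) %/% 2L,
                      name = "conv", bias_init = 0, zero_init = FALSE) {
  W <- if (zero_init) matrix(0, k * k * c_in, c_out) else he_init(k * k * c_in, c_out)
  list(type = "conv", k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), c_in = c_in, c_out = c_out,
       params = list(W = new_param(W, paste0(name, ".W")),
                     b = new_param(rep(bias_init, length.out = c_out),
                                   paste0(name, ".b"))))
}

conv_fwd <- function(tape, layer, x) {
  xv <- x$value
  d <- dim(xv)
  fw <- .conv_fwd_cpp(xv, layer$params$W$value, layer$params$b$value,
                      d[1], d[2], d[3], layer$k, layer$stride, layer$pad)
  new_node(tape, fw$y,
           backward = function(nd) {
             bw <- .conv_bwd_cpp(nd$grad, fw$xcol, layer$params$W$value,
                                 d[1], d[2], d[3], layer$k, layer$stride,
                                 layer$pad, !isTRUE(x$nograd))
             acc_grad(layer$params$W, bw$dW)
             acc_grad(layer$params$b, bw$db)
             if (!is.null(bw$dx)) acc_grad(x, bw$dx)
           })
}

# Per-channel spatial normalization with learned affine (instance
# normalization): statistics are taken over the H x W extent of the sample
# both in training and at inference, so the layer is batch-size-free and the
# network behaves identically however images are batched. Running statistics
# are still tracked during training for introspection.
make_norm <- function(c_out, name = "norm", momentum = 0.1, eps = 1e-5) {
  st <- new.env(parent = emptyenv())
  st$rm <- rep(0, c_out); st$rv <- rep(1, c_out)
  list(type = "norm", momentum = momentum, eps = eps, state = st,
       params = list(g = new_param(rep(1, c_out), paste0(name, ".g")),
                     b = new_param(rep(0, c_out), paste0(name, ".b"))))
}

norm_fwd <- function(tape, layer, x, training = TRUE) {
  xv <- x$value
  d <- dim(xv)
  HW <- d[1] * d[2]; C <- d[3]
  g <- layer$params$g$value
  fw <- .norm_fwd_cpp(xv, g, layer$params$b$value, HW, C, layer$eps)
  if (training) {
    st <- layer$state
    va <- 1 / fw$inv^2 - layer$eps
    st$rm <- (1 - layer$momentum) * st$rm + layer$momentum * fw$mu
    st$rv <- (1 - layer$momentum) * st$rv + layer$momentum * va
  }
  y <- fw$y; dim(y) <- d
  new_node(tape, y, backward = function(nd) {
    bw <- .norm_bwd_cpp(nd$grad, xv, fw$mu, fw$inv, g, HW, C,
                        !isTRUE(x$nograd))
    acc_grad(layer$params$g, bw$dg)
    acc_grad(layer$params$b, bw$db)
    if (!is.null(bw$dx)) { dx <- bw$dx; dim(dx) <- d; acc_grad(x, dx) }
  })
}

relu_fwd <- function(tape, x) {
  m <- x$value > 0
  new_node(tape, x$value * m, backward = function(nd) {
    acc_grad(x, nd$grad * m)
  })
}

sigmoid_fwd <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(tape, s, backward = function(nd) {
    acc_grad(x, nd$grad * s * (1 - s))
  })
}

softplus_fwd <- function(tape, x) {
  xv <- x$value
  y <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  s <- 1 / (1 + exp(-xv))
  new_node(tape, y, backward = function(nd) {
    acc_grad(x, nd$grad * s)
  })
}

add_fwd <- function(tape, a, b) {
  new_node(tape, a$value + b$value, backward = function(nd) {
    acc_grad(a, nd$grad)
    acc_grad(b, nd$grad)
  })
}

# Nearest-neighbor 2x upsampling.
upsample2_fwd <- function(tape, x) {
  d <- dim(x$value)
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  y <- x$value[ri, ci, , drop = FALSE]
  new_node(tape, y, backward = function(nd) {
    g <- nd$grad
    g1 <- g[seq(1, 2 * d[1], 2), , , drop = FALSE] +
      g[seq(2, 2 * d[1], 2), , , drop = FALSE]
    dx <- g1[, seq(1, 2 * d[2], 2), , drop = FALSE] +
      g1[, seq(2, 2 * d[2], 2), , drop = FALSE]
    acc_grad(x, dx)
  })
}

## ---- attention primitives ----

gap_fwd <- function(tape, x) {   # global average pool -> C vector
  d <- dim(x$value); HW <- d[1] * d[2]
  xm <- x$value; dim(xm) <- c(HW, d[3])
  new_node(tape, .colMeans(xm, HW, d[3]), backward = function(nd) {
    g <- rep(nd$grad / HW, each = HW)
    acc_grad(x, array(g, d))
  })
}

gmp_fwd <- function(tape, x) {   # global max pool -> C vector
  d <- dim(x$value); HW <- d[1] * d[2]
  xm <- x$value; dim(xm) <- c(HW, d[3])
  am <- max.col(t(xm), ties.method = "first")   # argmax per channel
  v <- xm[cbind(am, seq_len(d[3]))]
  new_node(tape, v, backward = function(nd) {
    dx <- array(0, d); dim(dx) <- c(HW, d[3])
    dx[cbind(am, seq_len(d[3]))] <- nd$grad
    dim(dx) <- d
    acc_grad(x, dx)
  })
}

make_dense <- function(n_in, n_out, name = "fc") {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = new_param(he_init(n_in, n_out), paste0(name, ".W")),
                     b = new_param(rep(0, n_out), paste0(name, ".b"))))
}

dense_fwd <- function(tape, layer, x) {
  xv <- x$value
  y <- drop(xv %*% layer$params$W$value) + layer$params$b$value
  new_node(tape, y, backward = function(nd) {
    acc_grad(layer$params$W, outer(xv, nd$grad))
    acc_grad(layer$params$b, nd$grad)
    if (!isTRUE(x$nograd))
      acc_grad(x, drop(layer$params$W$value %*% nd$grad))
  })
}

chan_gate_fwd <- function(tape, x, gate) {  # gate: C vector node in (0,1)
  d <- dim(x$value); HW <- d[1] * d[2]
  gv <- rep(gate$value, each = HW)
  new_node(tape, x$value * gv, backward = function(nd) {
    acc_grad(x, nd$grad * array(gv, d))
    dm <- nd$grad * x$value; dim(dm) <- c(HW, d[3])
    acc_grad(gate, .colMeans(dm, HW, d[3]) * HW)
  })
}

spat_gate_fwd <- function(tape, x, gate) {  # gate: (H, W, 1) node in (0,1)
  d <- dim(x$value); HW <- d[1] * d[2]
  gv <- as.vector(gate$value)               # length HW, recycled per channel
  new_node(tape, x$value * gv, backward = function(nd) {
    acc_grad(x, nd$grad * array(gv, d))
    dm <- nd$grad * x$value; dim(dm) <- c(HW, d[3])
    dg <- rowSums(dm)
    acc_grad(gate, array(dg, c(d[1], d[2], 1)))
  })
}

# Channel-wise mean and max, stacked into an (H, W, 2) descriptor map.
chan_pool_fwd <- function(tape, x) {
  d <- dim(x$value); HW <- d[1] * d[2]; C <- d[3]
  xm <- x$value; dim(xm) <- c(HW, C)
  mn <- rowMeans(xm)
  am <- max.col(xm, ties.method = "first")
  mx <- xm[cbind(seq_len(HW), am)]
  y <- array(c(mn, mx), c(d[1], d[2], 2))
  new_node(tape, y, backward = function(nd) {
    g <- nd$grad; dim(g) <- c(HW, 2)
    dx <- matrix(g[, 1] / C, HW, C)
    dx[cbind(seq_len(HW), am)] <- dx[cbind(seq_len(HW), am)] + g[, 2]
    acc_grad(x, array(dx, d))
  })
}

# Gather head values at K grid cells (1-based linear indices into H x W).
gather_cells_fwd <- function(tape, x, lin) {
  d <- dim(x$value); HW <- d[1] * d[2]; C <- d[3]
  xm <- x$value; dim(xm) <- c(HW, C)
  y <- xm[lin, , drop = FALSE]
  new_node(tape, y, backward = function(nd) {
    dx <- matrix(0, HW, C)
    for (i in seq_along(lin))
      dx[lin[i], ] <- dx[lin[i], ] + nd$grad[i, ]
    acc_grad(x, array(dx, d))
  })
}

# Affine rescaling y = a*x + c (used e.g. for the angle head's x180 scale).
affine_fwd <- function(tape, x, a, c = 0) {
  new_node(tape, a * x$value + c, backward = function(nd) {
    acc_grad(x, a * nd$grad)
  })
}

# Weighted sum of scalar loss nodes.
wsum_fwd <- function(tape, nodes, weights) {
  v <- sum(vapply(seq_along(nodes), function(i) weights[i] * nodes[[i]]$value,
                  numeric(1)))
  new_node(tape, v, backward = function(nd) {
    for (i in seq_along(nodes)) acc_grad(nodes[[i]], weights[i] * nd$grad)
  })
}

## ---- deformable 3x3 convolution ----

# Offsets come from a zero-initialized companion convolution (18 channels:
# (dy, dx) per kernel tap), so the layer starts as a plain 3x3 convolution
# and learns where to sample. Bilinear sampling with zero padding outside;
# gradients flow to the input, the weights and the offsets.
make_deform_conv <- function(c_in, c_out, name = "dconv") {
  list(type = "dconv", c_in = c_in, c_out = c_out,
       off = make_conv(c_in, 18, k = 3, name = paste0(name, ".off"),
                       zero_init = TRUE),
       params = list(W = new_param(he_init(9 * c_in, c_out), paste0(name, ".W")),
                     b = new_param(rep(0, c_out), paste0(name, ".b"))))
}

deform_conv_fwd <- function(tape, layer, x) {
  off <- conv_fwd(tape, layer$off, x)
  xv <- x$value
  d <- dim(xv); H <- d[1]; W <- d[2]; C <- d[3]; HW <- H * W
  xm <- xv; dim(xm) <- c(HW, C)
  ys <- rep(0:(H - 1), times = W)
  xs <- rep(0:(W - 1), each = H)
  taps <- expand.grid(ky = -1:1, kx = -1:1)
  Xcol <- matrix(0, HW, 9 * C)
  cache <- vector("list", 9)
  offv <- off$value
  for (t in 1:9) {
    py <- ys + taps$ky[t] + as.vector(offv[, , 2 * t - 1])
    px <- xs + taps$kx[t] + as.vector(offv[, , 2 * t])
    y0 <- floor(py); x0 <- floor(px)
    fy <- py - y0; fx <- px - x0
    corn <- function(xi, yi) {
      ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1)
      lin <- ifelse(ok, yi + xi * H + 1, 1L)
      v <- xm[lin, , drop = FALSE]
      v[!ok, ] <- 0
      list(v = v, lin = lin, ok = ok)
    }
    c00 <- corn(x0, y0); c10 <- corn(x0 + 1, y0)
    c01 <- corn(x0, y0 + 1); c11 <- corn(x0 + 1, y0 + 1)
    w00 <- (1 - fx) * (1 - fy); w10 <- fx * (1 - fy)
    w01 <- (1 - fx) * fy; w11 <- fx * fy
    Xcol[, ((t - 1) * C + 1):(t * C)] <-
      c00$v * w00 + c10$v * w10 + c01$v * w01 + c11$v * w11
    cache[[t]] <- list(c00 = c00, c10 = c10, c01 = c01, c11 = c11,
                       fx = fx, fy = fy)
  }
  Y <- Xcol %*% layer$params$W$value
  Y <- Y + rep(layer$params$b$value, each = HW)
  new_node(tape, array(Y, c(H, W, layer$c_out)), backward = function(nd) {
    dY <- nd$grad; dim(dY) <- c(HW, layer$c_out)
    acc_grad(layer$params$W, crossprod(Xcol, dY))
    acc_grad(layer$params$b, colSums(dY))
    dXcol <- tcrossprod(dY, layer$params$W$value)
    dxm <- matrix(0, HW, C)
    doff <- array(0, c(H, W, 18))
    for (t in 1:9) {
      blk <- dXcol[, ((t - 1) * C + 1):(t * C), drop = FALSE]
      ch <- cache[[t]]
      fx <- ch$fx; fy <- ch$fy
      w <- list(`00` = (1 - fx) * (1 - fy), `10` = fx * (1 - fy),
                `01` = (1 - fx) * fy, `11` = fx * fy)
      for (cn in c("00", "10", "01", "11")) {
        cc <- ch[[paste0("c", cn)]]
        contrib <- blk * w[[cn]]
        contrib[!cc$ok, ] <- 0
        r <- rowsum(contrib, cc$lin)
        rows <- as.integer(rownames(r))
        dxm[rows, ] <- dxm[rows, ] + r
      }
      dvdx <- (ch$c10$v - ch$c00$v) * (1 - fy) + (ch$c11$v - ch$c01$v) * fy
      dvdy <- (ch$c01$v - ch$c00$v) * (1 - fx) + (ch$c11$v - ch$c10$v) * fx
      doff[, , 2 * t - 1] <- matrix(rowSums(blk * dvdy), H, W)
      doff[, , 2 * t] <- matrix(rowSums(blk * dvdx), H, W)
    }
    if (!isTRUE(x$nograd)) acc_grad(x, array(dxm, d))
    acc_grad(off, doff)
  })
}

## ---- AdamW ----

adamw_state <- function(params) {
  lapply(params, function(p) list(m = 0 * p$value, v = 0 * p$value))
}

adamw_step <- function(params, state, lr, weight_decay = 5e-3,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 1,
                       clip_norm = 10) {
  gn2 <- 0
  for (p in params) if (!is.null(p$grad)) gn2 <- gn2 + sum(p$grad^2)
  scale <- if (gn2 > clip_norm^2) clip_norm / sqrt(gn2) else 1
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    state[[i]]$m <- beta1 * state[[i]]$m + (1 - beta1) * g
    state[[i]]$v <- beta2 * state[[i]]$v + (1 - beta2) * g * g
    mh <- state[[i]]$m / (1 - beta1^t)
    vh <- state[[i]]$v / (1 - beta2^t)
    p$value <- p$value - lr * (mh / (sqrt(vh) + eps) + weight_decay * p$value)
  }
  state
}
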