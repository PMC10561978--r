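#' Feature map container
#'
#' @param values H x W x C numeric array (channels last).
#' @param stride integer down-sampling factor relative to the network input;
#'   must be a power of two.
#' @return A list of class `feature_map`.
#' @export
feature_map <- function(values, stride = 1L) {
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3)
  s <- as.integer(stride)
  if (s < 1 || bitwAnd(s, s - 1L) != 0L)
    stop("feature_map: stride must be a power of 2")
  structure(list(values = values, stride = s), class = "feature_map")
}

#' Detection network configuration
#'
#' @param preset `"dla_lite"` (3 stages, base 16 channels, depths 1/1/1;
#'   sized for CPU work) or `"dla34"` (4 stages, depths 1/2/2/1 mirroring the
#'   published DLA-34 stage layout).
#' @param base_channels channels of the stem and first stage.
#' @param stage_depths integer vector, one hierarchical-aggregation tree depth
#'   per stage; each stage halves the resolution.
#' @param use_attention apply a channel+spatial attention block (CBAM) to the
#'   final aggregated feature (default `TRUE`).
#' @param use_deformable use deformable 3x3 convolutions in the up-sampling
#'   projections (default `FALSE`; a plain convolution is used otherwise, the
#'   two are interchangeable in shape).
#' @param head_channels hidden channels of each prediction head (default 16).
#' @param output_stride stride `R` of the head grid (fixed at 4 for this
#'   architecture family).
#' @param num_classes number of object classes (1: "stoma").
#' @return A list of class `net_config`.
#' @export
net_config <- function(preset = c("dla_lite", "dla34"),
                       base_channels = NULL, stage_depths = NULL,
                       use_attention = TRUE, use_deformable = FALSE,
                       head_channels = 16, output_stride = 4,
                       num_classes = 1) {
  preset <- match.arg(preset)
  if (is.null(base_channels))
    base_channels <- 16
  if (is.null(stage_depths))
    stage_depths <- if (preset == "dla_lite") c(1, 1, 1) else c(1, 2, 2, 1)
  if (output_stride != 4)
    stop("net_config: this architecture family emits heads at stride 4")
  structure(list(preset = preset, base_channels = base_channels,
                 stage_depths = as.integer(stage_depths),
                 use_attention = isTRUE(use_attention),
                 use_deformable = isTRUE(use_deformable),
                 head_channels = as.integer(head_channels),
                 output_stride = as.integer(output_stride),
                 num_classes = as.integer(num_classes)),
            class = "net_config")
}

## ---- building blocks ----

# Basic residual block: conv-norm-relu-conv-norm (+ projected skip) -> relu.
make_block <- function(c_in, c_out, stride = 1L, name = "blk") {
  list(type = "block",
       conv1 = make_conv(c_in, c_out, 3, stride = stride, name = paste0(name, ".c1")),
       n1 = make_norm(c_out, paste0(name, ".n1")),
       conv2 = make_conv(c_out, c_out, 3, name = paste0(name, ".c2")),
       n2 = make_norm(c_out, paste0(name, ".n2")),
       proj = if (stride != 1L || c_in != c_out)
         make_conv(c_in, c_out, 1, stride = stride, pad = 0L,
                   name = paste0(name, ".proj"))
       else NULL)
}

block_fwd <- function(tape, blk, x, training) {
  h <- relu_fwd(tape, norm_fwd(tape, blk$n1, conv_fwd(tape, blk$conv1, x), training))
  h <- norm_fwd(tape, blk$n2, conv_fwd(tape, blk$conv2, h), training)
  skip <- if (is.null(blk$proj)) x else conv_fwd(tape, blk$proj, x)
  relu_fwd(tape, add_fwd(tape, h, skip))
}

# Aggregation node: y = relu(norm(sum_i conv1x1_i(x_i) + b) + x_n), the
# residual path being the last input (which must already have c_out
# channels).
make_agg <- function(c_ins, c_out, name = "agg") {
  if (length(c_ins) < 2) stop("aggregation node needs >= 2 inputs")
  if (c_ins[length(c_ins)] != c_out)
    stop("aggregation node: residual (last) input must have ", c_out,
         " channels, got ", c_ins[length(c_ins)])
  list(type = "agg",
       convs = lapply(seq_along(c_ins), function(i)
         make_conv(c_ins[i], c_out, 1, pad = 0L,
                   name = sprintf("%s.w%d", name, i))),
       n = make_norm(c_out, paste0(name, ".n")))
}

agg_fwd <- function(tape, agg, xs, training) {
  s <- conv_fwd(tape, agg$convs[[1]], xs[[1]])
  for (i in 2:length(xs))
    s <- add_fwd(tape, s, conv_fwd(tape, agg$convs[[i]], xs[[i]]))
  relu_fwd(tape, add_fwd(tape, norm_fwd(tape, agg$n, s, training),
                         xs[[length(xs)]]))
}

# Hierarchical aggregation tree of depth n over residual blocks:
#   T_n(x) = N(R_{n-1}(x), ..., R_1(x), L_1(x), L_2(x))
#   L_2 = B(L_1), L_1 = B(R_1), R_m = T_m(x) if m = n-1 else T_m(R_{m+1}(x)),
# i.e. the sub-trees T_{n-1}..T_1 are chained and every root feeds the top
# aggregation. At depth 1 the tree degenerates to N(L_1, L_2) with
# L_1 = B(x). The very first residual block applied to the stage input
# carries the stage's stride-2 down-sampling.
make_hda <- function(depth, c_in, c_out, stride = 2L, name = "hda") {
  build <- function(n, c_in, first, nm) {
    if (n == 1) {
      b1 <- make_block(c_in, c_out, stride = if (first) stride else 1L,
                       name = paste0(nm, ".b1"))
      b2 <- make_block(c_out, c_out, name = paste0(nm, ".b2"))
      list(depth = 1, b1 = b1, b2 = b2,
           agg = make_agg(c(c_out, c_out), c_out, paste0(nm, ".agg")))
    } else {
      # chained sub-trees R_{n-1}, ..., R_1: the first sees the stage input
      subs <- vector("list", n - 1)
      for (m in (n - 1):1) {
        i <- n - m  # build order: deepest-index first
        subs[[i]] <- build(m, if (i == 1) c_in else c_out,
                           first && i == 1, sprintf("%s.t%d", nm, m))
      }
      b1 <- make_block(c_out, c_out, name = paste0(nm, ".b1"))
      b2 <- make_block(c_out, c_out, name = paste0(nm, ".b2"))
      list(depth = n, subs = subs, b1 = b1, b2 = b2,
           agg = make_agg(rep(c_out, n + 1), c_out, paste0(nm, ".agg")))
    }
  }
  tree <- build(depth, c_in, TRUE, name)
  list(type = "hda", depth = depth, tree = tree, stride = stride)
}

hda_tree_fwd <- function(tape, tr, x, training) {
  if (tr$depth == 1) {
    l1 <- block_fwd(tape, tr$b1, x, training)
    l2 <- block_fwd(tape, tr$b2, l1, training)
    return(agg_fwd(tape, tr$agg, list(l1, l2), training))
  }
  roots <- vector("list", length(tr$subs))
  cur <- x
  for (i in seq_along(tr$subs)) {   # R_{n-1} first, each feeding the next
    cur <- hda_tree_fwd(tape, tr$subs[[i]], cur, training)
    roots[[i]] <- cur
  }
  l1 <- block_fwd(tape, tr$b1, cur, training)
  l2 <- block_fwd(tape, tr$b2, l1, training)
  agg_fwd(tape, tr$agg, c(roots, list(l1, l2)), training)
}

# Up-sampling projection used by the iterative aggregation across stages:
# a 1x1 channel projection (or a deformable 3x3 convolution when enabled)
# followed by nearest-neighbor 2x steps.
make_up <- function(c_in, c_out, factor, deformable = FALSE, name = "up") {
  proj <- if (deformable) make_deform_conv(c_in, c_out, name = paste0(name, ".proj"))
  else make_conv(c_in, c_out, 1, pad = 0L, name = paste0(name, ".proj"))
  list(type = "up", proj = proj, factor = as.integer(factor),
       deformable = deformable, n = make_norm(c_out, paste0(name, ".n")))
}

up_fwd <- function(tape, up, x, training) {
  h <- if (up$deformable) deform_conv_fwd(tape, up$proj, x)
  else conv_fwd(tape, up$proj, x)
  h <- relu_fwd(tape, norm_fwd(tape, up$n, h, training))
  f <- up$factor
  while (f > 1) { h <- upsample2_fwd(tape, h); f <- f %/% 2L }
  h
}

# CBAM: channel attention (shared two-layer MLP over average- and max-pooled
# channel statistics, sigmoid gate) then spatial attention (channel mean/max
# descriptor through a 7x7 convolution, sigmoid gate).
make_cbam <- function(c_in, reduction = 4, name = "cbam") {
  hidden <- max(2L, c_in %/% reduction)
  list(type = "cbam",
       fc1 = make_dense(c_in, hidden, paste0(name, ".fc1")),
       fc2 = make_dense(hidden, c_in, paste0(name, ".fc2")),
       sconv = make_conv(2, 1, 7, pad = 3L, name = paste0(name, ".sconv")))
}

cbam_fwd <- function(tape, cb, x, training) {
  mlp <- function(v) dense_fwd(tape, cb$fc2, relu_fwd(tape, dense_fwd(tape, cb$fc1, v)))
  ca <- sigmoid_fwd(tape, add_fwd(tape, mlp(gap_fwd(tape, x)),
                                  mlp(gmp_fwd(tape, x))))
  xc <- chan_gate_fwd(tape, x, ca)
  sa <- sigmoid_fwd(tape, conv_fwd(tape, cb$sconv, chan_pool_fwd(tape, xc)))
  spat_gate_fwd(tape, xc, sa)
}

make_head <- function(c_in, c_hidden, c_out, name, bias_init = 0) {
  list(conv1 = make_conv(c_in, c_hidden, 3, name = paste0(name, ".c1")),
       conv2 = make_conv(c_hidden, c_out, 1, pad = 0L,
                         name = paste0(name, ".c2"), bias_init = bias_init))
}

head_fwd <- function(tape, hd, x) {
  conv_fwd(tape, hd$conv2, relu_fwd(tape, conv_fwd(tape, hd$conv1, x)))
}

## ---- whole network ----

#' Build a detection network
#'
#' Assembles the stem, the hierarchical-aggregation stages, the iterative
#' cross-stage aggregation back up to stride 4, the optional attention block,
#' and the four prediction heads (center heatmap, size, sub-pixel offset,
#' long-axis angle). Weight initialization draws from the current RNG; seed
#' beforehand for reproducibility.
#'
#' @param config a [net_config()].
#' @param in_channels input image channels (1 = grayscale).
#' @return A list of class `rsd_network`.
#' @export
build_network <- function(config = net_config(), in_channels = 1) {
  nb <- config$base_channels
  ns <- length(config$stage_depths)
  stage_ch <- nb * 2^(0:(ns - 1))
  # stride-2 stem: the earliest layers carry little semantic content for
  # blob-like objects, so the full-resolution convolution is folded into the
  # down-sampling step; with each stage halving the resolution once more,
  # the first stage lands on the stride-4 head grid.
  stem <- list(conv = make_conv(in_channels, nb, 3, stride = 2L,
                                name = "stem.c"),
               n = make_norm(nb, "stem.n"))
  stages <- lapply(seq_len(ns), function(i) {
    make_hda(config$stage_depths[i],
             if (i == 1) nb else stage_ch[i - 1], stage_ch[i],
             name = sprintf("stage%d", i))
  })
  cf <- stage_ch[1]  # channels of the fused stride-4 feature
  ups <- lapply(seq_len(ns - 1), function(j)
    make_up(stage_ch[j + 1], cf, 2^j, config$use_deformable,
            name = sprintf("up%d", j)))
  aggs <- lapply(seq_len(ns - 1), function(j)
    make_agg(c(cf, cf), cf, sprintf("ida%d", j)))
  cbam <- if (config$use_attention) make_cbam(cf) else NULL
  heads <- list(
    heatmap = make_head(cf, config$head_channels, config$num_classes,
                        "hm", bias_init = -2.19),
    size = make_head(cf, config$head_channels, 2, "size", bias_init = 14),
    offset = make_head(cf, config$head_channels, 2, "off"),
    angle = make_head(cf, config$head_channels, 1, "ang"))
  structure(list(config = config, in_channels = in_channels,
                 stem = stem, stages = stages,
                 ups = ups, aggs = aggs, cbam = cbam, heads = heads),
            class = "rsd_network")
}

#' @export
print.rsd_network <- function(x, ...) {
  np <- sum(vapply(network_params(x), function(p) length(p$value), numeric(1)))
  cat(sprintf("<rsd_network> preset %s, %d stages, %s parameters (stride %d heads)\n",
              x$config$preset, length(x$stages), format(np, big.mark = ","),
              x$config$output_stride))
  invisible(x)
}

# All trainable parameter environments of the network, in a stable order.
network_params <- function(net) {
  mods <- list(net$stem$conv, net$stem$n)
  walk_tree <- function(tr) {
    out <- list(tr$b1$conv1, tr$b1$n1, tr$b1$conv2, tr$b1$n2)
    if (!is.null(tr$b1$proj)) out <- c(out, list(tr$b1$proj))
    out <- c(out, list(tr$b2$conv1, tr$b2$n1, tr$b2$conv2, tr$b2$n2))
    if (!is.null(tr$b2$proj)) out <- c(out, list(tr$b2$proj))
    out <- c(out, tr$agg$convs, list(tr$agg$n))
    if (!is.null(tr$subs)) for (s in tr$subs) out <- c(out, walk_tree(s))
    out
  }
  for (st in net$stages) mods <- c(mods, walk_tree(st$tree))
  for (u in net$ups) {
    mods <- c(mods, list(u$proj, u$n))
    if (identical(u$proj$type, "dconv")) mods <- c(mods, list(u$proj$off))
  }
  for (a in net$aggs) mods <- c(mods, a$convs, list(a$n))
  if (!is.null(net$cbam))
    mods <- c(mods, list(net$cbam$fc1, net$cbam$fc2, net$cbam$sconv))
  for (h in net$heads) mods <- c(mods, list(h$conv1, h$conv2))
  out <- list()
  for (m in mods) out <- c(out, collect_params(m))
  out
}

# Forward pass on the tape; returns nodes for each head plus the fused
# feature. `x` is an H x W x C array node.
net_fwd_nodes <- function(tape, net, x, training = TRUE) {
  h <- relu_fwd(tape, norm_fwd(tape, net$stem$n,
                               conv_fwd(tape, net$stem$conv, x), training))
  feats <- list()
  for (i in seq_along(net$stages)) {
    h <- hda_tree_fwd(tape, net$stages[[i]]$tree, h, training)
    feats[[i]] <- h
  }
  # iterative aggregation: fold deeper stages into the stride-4 feature
  f <- feats[[1]]
  for (j in seq_len(length(feats) - 1)) {
    up <- up_fwd(tape, net$ups[[j]], feats[[j + 1]], training)
    f <- agg_fwd(tape, net$aggs[[j]], list(f, up), training)
  }
  if (!is.null(net$cbam)) f <- cbam_fwd(tape, net$cbam, f, training)
  list(feature = f,
       heatmap = sigmoid_fwd(tape, head_fwd(tape, net$heads$heatmap, f)),
       size = softplus_fwd(tape, head_fwd(tape, net$heads$size, f)),
       offset = sigmoid_fwd(tape, head_fwd(tape, net$heads$offset, f)),
       angle = affine_fwd(tape, sigmoid_fwd(tape, head_fwd(tape, net$heads$angle, f)),
                          180))
}

#' Run the network on an image
#'
#' Images are padded on the right/bottom to a multiple of the maximum stage
#' stride if necessary (padding recorded in the result), intensities are
#' scaled to `[-1, 1]`, and the four heads are produced at output stride 4:
#' sigmoid heatmap in (0,1), softplus sizes (output-grid units), sigmoid
#' offsets in (0,1) and sigmoid-scaled angles in (0,180).
#'
#' @param net an [build_network()] result.
#' @param image H x W gray matrix in 0-255 (or H x W x C array).
#' @param training use per-sample statistics in the normalization layers and
#'   keep the forward recorded on a tape (internal use); default `FALSE`.
#' @return A list of class `head_outputs`: `heatmap`, `size`, `offset`,
#'   `angle`, `stride`, `pad_right`, `pad_bottom`.
#' @export
network_forward <- function(net, image, training = FALSE) {
  if (length(dim(image)) == 2) dim(image) <- c(dim(image), 1L)
  max_stride <- 2L * 2L^length(net$stages)
  h <- dim(image)[1]; w <- dim(image)[2]
  hp <- as.integer(ceiling(h / max_stride) * max_stride)
  wp <- as.integer(ceiling(w / max_stride) * max_stride)
  if (hp != h || wp != w) {
    im2 <- array(0, c(hp, wp, dim(image)[3]))
    im2[1:h, 1:w, ] <- image
    image <- im2
  }
  x <- new_leaf(image / 127.5 - 1, nograd = TRUE)
  tape <- new_tape()
  nodes <- net_fwd_nodes(tape, net, x, training = training)
  hm <- nodes$heatmap$value
  if (any(!is.finite(hm)) || any(!is.finite(nodes$size$value)) ||
      any(!is.finite(nodes$offset$value)) || any(!is.finite(nodes$angle$value)))
    stop("network_forward: non-finite head output (training diverged?)")
  structure(list(heatmap = hm[, , 1],
                 size = nodes$size$value,
                 offset = nodes$offset$value,
                 angle = nodes$angle$value[, , 1],
                 stride = net$config$output_stride,
                 pad_right = wp - w, pad_bottom = hp - h),
            class = "head_outputs")
}

## ---- spec-level functional wrappers on feature_map objects ----

#' Aggregation node on feature maps
#'
#' Functional form of the aggregation used throughout the backbone:
#' `y = relu(norm(sum_i W_i x_i + b) + x_n)` where the `W_i` are 1x1
#' convolutions and the residual path is the last input. All inputs must
#' share a spatial size and the last must have `c_out` channels.
#'
#' @param inputs list of [feature_map()]s (at least 2).
#' @param weights optional list of 1x1 kernel matrices (`c_in_i` x `c_out`);
#'   random if omitted.
#' @param bias optional bias vector of length `c_out`.
#' @param c_out output channels; defaults to the channels of the last input.
#' @return A [feature_map()] at the common spatial size.
#' @export
aggregation_node <- function(inputs, weights = NULL, bias = NULL,
                             c_out = NULL) {
  if (length(inputs) < 2) stop("aggregation_node: need >= 2 inputs")
  dims <- lapply(inputs, function(f) dim(f$values))
  sp <- vapply(dims, function(d) paste(d[1], d[2]), character(1))
  if (length(unique(sp)) != 1)
    stop("aggregation_node: inputs must share a spatial size")
  c_ins <- vapply(dims, function(d) d[3], numeric(1))
  if (is.null(c_out)) c_out <- c_ins[length(c_ins)]
  agg <- make_agg(c_ins, c_out, "agg")
  if (!is.null(weights)) {
    for (i in seq_along(weights)) {
      wm <- weights[[i]]
      if (!all(dim(wm) == c(c_ins[i], c_out)))
        stop("aggregation_node: weights[[", i, "]] must be ", c_ins[i], " x ", c_out)
      agg$convs[[i]]$params$W$value <- wm
      agg$convs[[i]]$params$b$value <- rep(0, c_out)
    }
  }
  if (!is.null(bias)) agg$convs[[1]]$params$b$value <- bias
  tape <- new_tape()
  xs <- lapply(inputs, function(f) new_leaf(f$values, nograd = TRUE))
  out <- agg_fwd(tape, agg, xs, training = TRUE)
  feature_map(out$value, inputs[[1]]$stride)
}

#' Iterative deep aggregation across stages
#'
#' Folds an ordered (shallow to deep) list of feature maps into one map at
#' the shallowest resolution: a single input is returned unchanged (the
#' recursion's base case); otherwise each deeper map is channel-projected,
#' up-sampled to the running resolution and merged through an
#' [aggregation_node()], left to right.
#'
#' @param features list of [feature_map()]s ordered shallow to deep.
#' @return A [feature_map()] at the first input's stride and channels.
#' @export
ida_combine <- function(features) {
  if (length(features) == 0) stop("ida_combine: empty feature list")
  if (length(features) == 1) return(features[[1]])
  acc <- features[[1]]
  c_out <- dim(acc$values)[3]
  for (j in 2:length(features)) {
    deep <- features[[j]]
    fac <- deep$stride / acc$stride
    if (fac < 1 || fac != round(fac))
      stop("ida_combine: features must be ordered shallow to deep")
    up <- make_up(dim(deep$values)[3], c_out, fac)
    tape <- new_tape()
    un <- up_fwd(tape, up, new_leaf(deep$values, nograd = TRUE), training = TRUE)
    acc <- aggregation_node(list(acc, feature_map(un$value, acc$stride)),
                            c_out = c_out)
  }
  acc
}

#' Hierarchical deep aggregation stage
#'
#' Applies a freshly initialized hierarchical aggregation tree of the given
#' depth to a feature map, halving the resolution (the stage's stride-2
#' down-sampling is carried by the first residual block).
#'
#' @param input a [feature_map()].
#' @param depth tree depth (>= 1).
#' @param c_out output channels (default: doubles the input channels).
#' @return A [feature_map()] at `stride * 2`.
#' @export
hda_stage <- function(input, depth = 1, c_out = 2 * dim(input$values)[3]) {
  if (depth < 1) stop("hda_stage: depth must be >= 1")
  st <- make_hda(depth, dim(input$values)[3], c_out)
  tape <- new_tape()
  out <- hda_tree_fwd(tape, st$tree, new_leaf(input$values, nograd = TRUE), TRUE)
  feature_map(out$value, input$stride * 2L)
}

#' Channel-then-spatial attention block
#'
#' Gates a feature map by learned channel weights (pooled-statistics MLP,
#' sigmoid) followed by spatial weights (channel-pooled 7x7 convolution,
#' sigmoid); every gate value lies strictly in (0, 1) and the output shape
#' equals the input shape.
#'
#' @param feature a [feature_map()].
#' @return A [feature_map()] of identical shape and stride.
#' @export
attention_block <- function(feature) {
  cb <- make_cbam(dim(feature$values)[3])
  tape <- new_tape()
  out <- cbam_fwd(tape, cb, new_leaf(feature$values, nograd = TRUE), TRUE)
  feature_map(out$value, feature$stride)
}

#' Read / write a network configuration file
#'
#' Flat YAML key-value files mirroring the [net_config()] fields, e.g.
#' `preset: dla_lite`, `use_attention: yes`, `head_channels: 16`.
#'
#' @param path file path.
#' @return `read_net_config`: a [net_config()]; `write_net_config`: `path`,
#'   invisibly.
#' @export
read_net_config <- function(path) {
  if (!file.exists(path)) stop("read_net_config: no such file: ", path)
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(net_config)), "...")
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("read_net_config: unknown field(s): ", paste(unknown, collapse = ", "))
  do.call(net_config, vals)
}

#' @rdname read_net_config
#' @param config a [net_config()].
#' @export
write_net_config <- function(config, path) {
  stopifnot(inherits(config, "net_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## ---- checkpoint I/O ----

#' Save / load network weights
#'
#' Weights (and normalization running statistics) are serialized with the
#' network configuration so a checkpoint restores an identical model.
#'
#' @param net an `rsd_network`.
#' @param path checkpoint file path (RDS container).
#' @return `save_network`: `path` invisibly; `load_network`: an
#'   `rsd_network`.
#' @export
save_network <- function(net, path) {
  ps <- network_params(net)
  vals <- lapply(ps, function(p) p$value)
  names(vals) <- vapply(ps, function(p) p$name, character(1))
  stats <- network_norm_stats(net)
  saveRDS(list(config = net$config, in_channels = net$in_channels,
               values = vals, norm_stats = stats), path)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  ck <- readRDS(path)
  net <- with_seed(0, build_network(ck$config, ck$in_channels))
  set_network_weights(net, ck$values, ck$norm_stats)
  net
}

# Snapshot / restore helpers (used for best-checkpoint tracking in memory).
walk_norms <- function(net, fn) {
  walk <- function(m, path) {
    if (!is.list(m)) return(invisible(NULL))
    if (identical(m$type, "norm")) { fn(m, path); return(invisible(NULL)) }
    nms <- names(m)
    for (i in seq_along(m)) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      if (is.list(m[[i]])) walk(m[[i]], paste0(path, ".", nm))
    }
  }
  walk(unclass(net), "net")
  invisible(NULL)
}

network_norm_stats <- function(net) {
  out <- new.env(parent = emptyenv())
  walk_norms(net, function(m, path)
    assign(path, list(rm = m$state$rm, rv = m$state$rv), envir = out))
  as.list(out)
}

set_network_weights <- function(net, vals, norm_stats = NULL) {
  ps <- network_params(net)
  nms <- vapply(ps, function(p) p$name, character(1))
  if (!setequal(nms, names(vals)))
    stop("set_network_weights: parameter names do not match checkpoint")
  for (p in ps) p$value <- vals[[p$name]]
  if (!is.null(norm_stats)) {
    walk_norms(net, function(m, path) {
      s <- norm_stats[[path]]
      if (!is.null(s)) { m$state$rm <- s$rm; m$state$rv <- s$rv }
    })
  }
  invisible(net)
}

snapshot_weights <- function(net) {
  ps <- network_params(net)
  vals <- lapply(ps, function(p) p$value)
  names(vals) <- vapply(ps, function(p) p$name, character(1))
  list(values = vals, norm_stats = network_norm_stats(net))
}
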