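test_that("aggregation node follows its closed form", {
  set.seed(71)
  x1 <- feature_map(array(rnorm(6 * 6 * 4), c(6, 6, 4)), 4)
  x2 <- feature_map(array(rnorm(6 * 6 * 4), c(6, 6, 4)), 4)
  out <- aggregation_node(list(x1, x2))
  expect_equal(dim(out$values), c(6, 6, 4))
  expect_equal(out$stride, 4)

  # zero weights and bias with identity normalization: y = relu(x_n)
  zw <- list(matrix(0, 4, 4), matrix(0, 4, 4))
  out0 <- aggregation_node(list(x1, x2), weights = zw, bias = rep(0, 4))
  expect_equal(out0$values, pmax(x2$values, 0), tolerance = 1e-12)

  # three inputs (hierarchical aggregation case) are accepted
  x3 <- feature_map(array(rnorm(6 * 6 * 4), c(6, 6, 4)), 4)
  out3 <- aggregation_node(list(x1, x2, x3))
  expect_equal(dim(out3$values), c(6, 6, 4))

  expect_error(aggregation_node(list(x1)), ">= 2")
  xs <- feature_map(array(rnorm(3 * 3 * 4), c(3, 3, 4)), 4)
  expect_error(aggregation_node(list(x1, xs)), "spatial")
})

test_that("iterative aggregation folds shallow to deep", {
  set.seed(72)
  f1 <- feature_map(array(rnorm(8 * 8 * 4), c(8, 8, 4)), 8)
  # single feature: bit-exact identity (the recursion's base case)
  expect_identical(ida_combine(list(f1)), f1)

  f2 <- feature_map(array(rnorm(4 * 4 * 8), c(4, 4, 8)), 16)
  out <- ida_combine(list(f1, f2))
  expect_equal(dim(out$values), c(8, 8, 4))
  expect_equal(out$stride, 8)

  f3 <- feature_map(array(rnorm(2 * 2 * 16), c(2, 2, 16)), 32)
  out3 <- ida_combine(list(f1, f2, f3))
  expect_equal(dim(out3$values), c(8, 8, 4))

  # left-fold order: the same module sequence applied by hand matches
  set.seed(99)
  auto <- ida_combine(list(f1, f2, f3))
  set.seed(99)
  acc <- ida_combine(list(f1, f2))
  manual <- ida_combine(list(acc, f3))
  expect_equal(manual$values, auto$values, tolerance = 1e-12)

  expect_error(ida_combine(list()), "empty")
  expect_error(ida_combine(list(f2, f1)), "shallow to deep")
})

test_that("hierarchical stages halve resolution and stay finite", {
  set.seed(73)
  x <- feature_map(array(rnorm(16 * 16 * 8), c(16, 16, 8)), 2)
  out <- hda_stage(x, depth = 1)
  expect_equal(dim(out$values), c(8, 8, 16))
  expect_equal(out$stride, 4)
  out2 <- hda_stage(x, depth = 2, c_out = 12)
  expect_equal(dim(out2$values), c(8, 8, 12))
  for (i in 1:20) {
    xi <- feature_map(array(rnorm(8 * 8 * 4, sd = 10), c(8, 8, 4)), 2)
    expect_true(all(is.finite(hda_stage(xi, 1)$values)))
  }
  expect_error(hda_stage(x, depth = 0), "depth")
})

test_that("attention gates shrink magnitudes and preserve shape", {
  set.seed(74)
  x <- feature_map(array(rnorm(10 * 12 * 8), c(10, 12, 8)), 4)
  out <- attention_block(x)
  expect_equal(dim(out$values), dim(x$values))
  expect_equal(out$stride, x$stride)
  # both gates lie strictly in (0,1): |y| < |x| wherever x != 0
  nz <- x$values != 0
  expect_true(all(abs(out$values[nz]) < abs(x$values[nz])))
  # all-zero input stays zero
  z <- feature_map(array(0, c(6, 6, 8)), 4)
  expect_true(all(attention_block(z)$values == 0))
})

test_that("the full forward pass honors the head contracts", {
  set.seed(75)
  net <- build_network(net_config())
  img <- matrix(runif(128 * 128, 0, 255), 128, 128)
  h <- network_forward(net, img)
  expect_equal(dim(h$heatmap), c(32, 32))
  expect_equal(dim(h$size), c(32, 32, 2))
  expect_equal(dim(h$offset), c(32, 32, 2))
  expect_equal(dim(h$angle), c(32, 32))
  expect_true(all(h$heatmap > 0 & h$heatmap < 1))
  expect_true(all(h$offset > 0 & h$offset < 1))
  expect_true(all(h$size >= 0))
  expect_true(all(h$angle >= 0 & h$angle <= 180))

  # non-multiple-of-stride input is padded and recorded
  h2 <- network_forward(net, matrix(runif(100 * 90, 0, 255), 90, 100))
  expect_equal(dim(h2$heatmap), c(24, 28))
  expect_equal(h2$pad_right, 12)
  expect_equal(h2$pad_bottom, 6)

  # deformable and plain up-sampling give identical shapes
  set.seed(75)
  netd <- build_network(net_config(use_deformable = TRUE))
  hd <- network_forward(netd, img)
  expect_equal(dim(hd$heatmap), dim(h$heatmap))
  expect_equal(dim(hd$size), dim(h$size))
})

test_that("gradient flows from the total loss into every head and the stem", {
  set.seed(76)
  net <- build_network(net_config())
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  ann <- annotation_set("g", 64, 64, 0.625,
                        list(rotated_box(30, 30, 40, 16, 25)))
  tg <- encode_targets(ann, 4, 16, 16)
  cfg <- train_config()
  params <- stomakit:::network_params(net)
  stomakit:::zero_grads(params)
  tape <- stomakit:::new_tape()
  il <- stomakit:::image_losses(tape, net, list(image = img), tg, cfg)
  stomakit:::tape_backward(tape, il$total)
  by_head <- function(prefix) {
    sel <- params[grepl(prefix, vapply(params, function(p) p$name,
                                       character(1)))]
    sum(vapply(sel, function(p)
      if (is.null(p$grad)) 0 else sum(p$grad^2), numeric(1)))
  }
  expect_gt(by_head("^hm\\."), 0)
  expect_gt(by_head("^size\\."), 0)
  expect_gt(by_head("^off\\."), 0)
  expect_gt(by_head("^ang\\."), 0)
  expect_gt(by_head("^stem\\."), 0)
  expect_gt(by_head("^cbam\\."), 0)
})

test_that("forward is deterministic and fast at test scale", {
  set.seed(77)
  net <- build_network(net_config())
  img <- matrix(runif(256 * 256, 0, 255), 256, 256)
  h1 <- network_forward(net, img)
  h2 <- network_forward(net, img)
  expect_identical(h1$heatmap, h2$heatmap)
  t0 <- Sys.time()
  invisible(network_forward(net, img))
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
})

test_that("checkpoints restore an identical network", {
  set.seed(78)
  net <- build_network(net_config())
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  expect_identical(network_forward(net, img)$heatmap,
                   network_forward(net2, img)$heatmap)
})

test_that("network configurations round-trip through YAML files", {
  f <- withr::local_tempfile(fileext = ".yaml")
  cfg <- net_config(head_channels = 24, use_deformable = TRUE)
  write_net_config(cfg, f)
  got <- read_net_config(f)
  expect_equal(got, cfg)
  writeLines(c("preset: dla_lite", "head_channels: 8"), f)
  expect_equal(read_net_config(f)$head_channels, 8L)
  writeLines(c("nonsense_field: 3"), f)
  expect_error(read_net_config(f), "unknown field")
})
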