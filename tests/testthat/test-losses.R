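test_that("heatmap focal loss matches hand-evaluated values", {
  # single positive cell at p = 0.5: (1-p)^2 * (-log p) = 0.25 ln 2
  expect_equal(heatmap_loss(matrix(0.5), matrix(1), 2, 4), 0.25 * log(2),
               tolerance = 1e-9)
  # single pure negative at p = 0.5: p^2 * (-log(1-p)) = 0.25 ln 2
  expect_equal(heatmap_loss(matrix(0.5), matrix(0), 2, 4), 0.25 * log(2),
               tolerance = 1e-9)
  # near-perfect prediction is near zero
  q <- matrix(0, 4, 4); q[2, 2] <- 1
  p <- matrix(1e-7, 4, 4); p[2, 2] <- 1 - 1e-7
  expect_lt(heatmap_loss(p, q), 1e-5)
  expect_error(heatmap_loss(matrix(1.2), matrix(1)), "strictly")
})

test_that("heatmap loss decreases monotonically toward the target", {
  set.seed(41)
  q <- matrix(0, 8, 8)
  q[3, 4] <- 1; q[6, 2] <- 1
  q[3, 5] <- 0.6; q[4, 4] <- 0.6   # Gaussian shoulder
  p0 <- matrix(runif(64, 0.05, 0.95), 8, 8)
  p1 <- pmin(pmax(q, 1e-6), 1 - 1e-6)
  ts <- seq(0, 1, length.out = 11)
  ls <- vapply(ts, function(t) heatmap_loss((1 - t) * p0 + t * p1, q),
               numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("L1 losses follow the stated instance averaging", {
  expect_equal(size_loss(matrix(c(3, 4), 1), matrix(c(3, 4), 1)), 0)
  expect_equal(angle_loss(30, 50), 20)
  expect_equal(angle_loss(30, 50, wrap = TRUE), 20)
  expect_equal(angle_loss(179, 1), 178)
  expect_equal(angle_loss(179, 1, wrap = TRUE), 2)
  expect_equal(offset_loss(matrix(0, 0, 2), matrix(0, 0, 2)), 0)  # K = 0
  expect_equal(offset_loss(matrix(c(0.1, 0.2, 0.5, 0.9), 2),
                           matrix(c(0.2, 0.2, 0.5, 0.5), 2)),
               mean(c(0.1, 0, 0, 0.4)))
})

test_that("conductance loss isolates trait-size error", {
  truth <- list(rotated_box(100, 100, 42.09 / 0.625, 14.35 / 0.625, 30))
  exact <- matrix(c(42.09, 14.35) / 0.625 / 4, 1)
  expect_equal(as.numeric(conductance_loss(exact, truth, 53.74)), 0,
               tolerance = 1e-9)
  # zero predicted length: the loss equals the true conductance
  zero_len <- matrix(c(0, 14.35 / 0.625 / 4), 1)
  expect_equal(as.numeric(conductance_loss(zero_len, truth, 53.74)),
               gsmax(42.09, 14.35, 53.74), tolerance = 1e-3)
  # doubling the predicted length strictly increases the implied conductance
  l1 <- conductance_loss(matrix(c(20, 5), 1), truth, 53.74)
  bigger <- stomakit:::gsmax_grad(2 * 20 * 4 * 0.625, 5 * 4 * 0.625, 53.74)$G
  smaller <- stomakit:::gsmax_grad(20 * 4 * 0.625, 5 * 4 * 0.625, 53.74)$G
  expect_gt(bigger, smaller)
})

test_that("total loss is the weighted component sum with breakdown", {
  comp <- c(heatmap = 1, offset = 2, size = 3, angle = 4, conductance = 5)
  expect_equal(as.numeric(total_loss(comp)), 15)
  expect_equal(as.numeric(total_loss(c(heatmap = 0, offset = 0, size = 0,
                                       angle = 0, conductance = 0))), 0)
  w <- loss_weights(conductance = 0)
  t0 <- total_loss(comp, w)
  expect_equal(as.numeric(t0), 10)
  expect_equal(unname(attr(t0, "breakdown")["conductance"]), 0)
})

test_that("a zero conductance weight removes its gradient (ablation mode)", {
  set.seed(43)
  sz <- matrix(runif(4, 3, 8), 2)
  truth <- list(rotated_box(50, 50, 60, 20, 10),
                rotated_box(100, 100, 55, 25, 100))
  G <- vapply(truth, function(b) gsmax(b$length * 0.625, b$width * 0.625, 50),
              numeric(1))
  run <- function(wcon) {
    tape <- stomakit:::new_tape()
    szn <- stomakit:::new_leaf(sz)
    lcon <- stomakit:::cond_loss_fwd(tape, szn, G, 50, 0.625, 4,
                                     conductance_params())
    lsz <- stomakit:::l1_loss_fwd(tape, szn, matrix(5, 2, 2))
    tot <- stomakit:::wsum_fwd(tape, list(lsz, lcon), c(1, wcon))
    stomakit:::tape_backward(tape, tot)
    szn$grad
  }
  g_on <- run(1); g_off <- run(0)
  g_sz_only <- sign(sz - 5) / 4
  expect_equal(g_off, g_sz_only, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(g_on, g_off)))
})

test_that("losses are zero exactly at matching prediction and target", {
  set.seed(44)
  ann <- tiny_annotations()
  tg <- encode_targets(ann, 4)
  expect_equal(size_loss(tg$size_S, tg$size_S), 0)
  expect_equal(offset_loss(tg$offset_O, tg$offset_O), 0)
  expect_equal(angle_loss(tg$angle_theta, tg$angle_theta), 0)
  p <- ifelse(tg$heatmap_q == 1, 1 - 1e-7, 1e-7)
  expect_lt(heatmap_loss(p, tg$heatmap_q), 1e-5)
})
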