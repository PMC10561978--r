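test_that("target encoding places centers, offsets and peak values", {
  ann <- annotation_set("a", 256, 256, 0.625,
                        list(rotated_box(40, 28, 48, 20, 15)))
  tg <- encode_targets(ann, 4)
  expect_equal(tg$center_cells[1, ], c(10, 7))
  expect_equal(tg$offset_O[1, ], c(0, 0))
  expect_equal(tg$heatmap_q[8, 11], 1)   # 1-based (y+1, x+1)
  expect_lt(max(tg$heatmap_q[-tg$center_lin]), 1)

  ann2 <- annotation_set("b", 256, 256, 0.625,
                         list(rotated_box(41.2, 29.6, 48, 20, 15)))
  tg2 <- encode_targets(ann2, 4)
  expect_equal(tg2$center_cells[1, ], c(10, 7))
  expect_equal(tg2$offset_O[1, ], c(0.3, 0.4), tolerance = 1e-9)
  expect_equal(tg2$size_S[1, ], c(12, 5))

  bad <- annotation_set("c", 100, 100, 0.625,
                        list(rotated_box(150, 50, 20, 8, 0)))
  expect_error(encode_targets(bad, 4), "outside")
})

test_that("peak extraction matches the literal neighborhood rule", {
  # smooth single Gaussian: exactly one peak at its center
  g <- outer(exp(-((1:21) - 11)^2 / 18), exp(-((1:21) - 7)^2 / 18))
  pk <- extract_peaks(g * 0.9 + 1e-4, top_k = 100, score_threshold = 0.1)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$x, pk$y), c(6, 10))  # 0-based

  # uniform plateau: every cell ties; the top_k cap applies
  u <- matrix(0.4, 9, 9)
  pk <- extract_peaks(u, top_k = 10)
  expect_equal(nrow(pk), 10)

  # two Gaussians 10 cells apart: exactly two peaks above 0.3
  g2 <- pmax(outer(exp(-((1:30) - 8)^2 / 8), exp(-((1:30) - 10)^2 / 8)),
             outer(exp(-((1:30) - 18)^2 / 8), exp(-((1:30) - 20)^2 / 8)))
  pk <- extract_peaks(g2 * 0.95 + 1e-4, score_threshold = 0.3)
  expect_equal(nrow(pk), 2)
})

test_that("peak extraction equals a brute-force scan on random heatmaps", {
  set.seed(51)
  for (i in 1:200) {
    hm <- matrix(runif(18 * 14, 1e-4, 1 - 1e-4), 18, 14)
    keep <- brute_force_peaks(hm)
    pk <- extract_peaks(hm, top_k = 10000, score_threshold = 0)
    got <- sort(pk$y + 1 + pk$x * 18)
    expect_equal(got, sort(which(keep)))
  }
})

test_that("decoding inverts the center arithmetic", {
  hm <- matrix(1e-4, 16, 16); hm[8, 11] <- 0.9   # cell x=10, y=7
  size <- array(0.1, c(16, 16, 2)); size[8, 11, ] <- c(12, 5)
  off <- array(0, c(16, 16, 2)); off[8, 11, ] <- c(0.3, 0.4)
  angle <- matrix(45, 16, 16)
  heads <- list(heatmap = hm, size = size, offset = off, angle = angle,
                stride = 4)
  dets <- decode_detections(heads, top_k = 100, score_threshold = 0.3)
  expect_length(dets, 1)
  b <- dets[[1]]$box
  expect_equal(c(b$cx, b$cy), c(41.2, 29.6), tolerance = 1e-9)
  expect_equal(c(b$length, b$width), c(48, 20), tolerance = 1e-9)
  expect_equal(b$angle_deg, 45)
  expect_equal(dets[[1]]$score, 0.9)

  off[8, 11, ] <- 0
  heads$offset <- off
  b0 <- decode_detections(heads, score_threshold = 0.3)[[1]]$box
  expect_equal(c(b0$cx, b0$cy), c(40, 28))
})

test_that("encode then decode recovers annotations exactly on clean targets", {
  set.seed(52)
  cfg <- synth_config(angle_range_deg = c(3, 177))
  for (seed in 1:10) {
    s <- generate_sample(cfg, 300 + seed)
    ann <- s$annotations
    tg <- encode_targets(ann, 4)
    heads <- stomakit:::targets_as_heads(tg)
    dets <- decode_detections(heads, top_k = 100, score_threshold = 0.5)
    expect_length(dets, length(ann$boxes))
    # match by nearest center
    for (b in ann$boxes) {
      d2 <- vapply(dets, function(d) (d$box$cx - b$cx)^2 + (d$box$cy - b$cy)^2,
                   numeric(1))
      db <- dets[[which.min(d2)]]$box
      expect_lt(abs(db$cx - b$cx), 0.5)
      expect_lt(abs(db$cy - b$cy), 0.5)
      expect_lt(abs(db$length - b$length), 0.5)
      expect_lt(abs(db$width - b$width), 0.5)
      expect_lt(angle_diff(db$angle_deg, b$angle_deg), 0.5)
    }
  }
})
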