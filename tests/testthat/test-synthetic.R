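test_that("generated samples honor the configured count and are deterministic", {
  cfg <- synth_config(n_stomata_range = c(5, 5))
  s1 <- generate_sample(cfg, 1)
  expect_length(s1$annotations$boxes, 5)
  s2 <- generate_sample(cfg, 1)
  expect_identical(s1$image, s2$image)
  expect_equal(s1$annotations, s2$annotations)
  s3 <- generate_sample(cfg, 2)
  expect_false(identical(s1$image, s3$image))
})

test_that("fixed trait draws give exact pixel-space annotations", {
  cfg <- synth_config(length_range_um = c(40, 40), width_range_um = c(14, 14),
                      n_stomata_range = c(3, 3), pixel_scale = 0.625)
  s <- generate_sample(cfg, 7)
  for (b in s$annotations$boxes) {
    expect_equal(b$length, 64, tolerance = 1e-9)
    expect_equal(b$width, 22.4, tolerance = 1e-9)
  }
})

test_that("annotations satisfy the geometric invariants", {
  cfg <- synth_config()
  for (seed in 1:15) {
    s <- generate_sample(cfg, seed)
    n <- length(s$annotations$boxes)
    expect_gte(n, cfg$n_stomata_range[1])
    expect_lte(n, cfg$n_stomata_range[2])
    for (b in s$annotations$boxes) {
      expect_gte(b$length, b$width)
      expect_gte(b$angle_deg, 0)
      expect_lt(b$angle_deg, 180)
      expect_gte(b$cx, 0); expect_lte(b$cx, 255)
      expect_gte(b$cy, 0); expect_lte(b$cy, 255)
      expect_gt(visibility_fraction(b, 256, 256), 2 / 3)
    }
    # achieved density lies in the band implied by the count range
    dens <- stomatal_density(n, 256, 256, 0.625)
    expect_gte(dens, cfg$n_stomata_range[1] / cfg$area_mm2 - 1e-9)
    expect_lte(dens, cfg$n_stomata_range[2] / cfg$area_mm2 + 1e-9)
  }
})

test_that("re-measuring rendered ellipses recovers the annotations", {
  # noise- and distractor-free, single isolated stoma: the connected
  # component fit must match the label within 2 px and 5 degrees
  cfg <- synth_config(noise_sd = 0, distractor_rate = 0,
                      background_texture = "flat", n_stomata_range = c(1, 1),
                      angle_range_deg = c(10, 170))
  for (seed in 101:112) {
    s <- generate_sample(cfg, seed)
    b <- s$annotations$boxes[[1]]
    if (visibility_fraction(b, 256, 256) < 0.999) next  # clipped at the edge
    fit <- refit_ellipse(s$image, b)
    expect_false(is.null(fit))
    expect_lt(abs(fit$cx - b$cx), 1.5)
    expect_lt(abs(fit$cy - b$cy), 1.5)
    expect_lt(abs(fit$length - b$length), 2)
    expect_lt(abs(fit$width - b$width), 2)
    expect_lt(angle_diff(fit$angle_deg, b$angle_deg), 5)
  }
})

test_that("impossible placements fail after bounded retries", {
  cfg <- synth_config(image_width_px = 64, image_height_px = 64,
                      n_stomata_range = c(30, 30), max_overlap = 0,
                      max_retries = 20)
  expect_error(generate_sample(cfg, 1), "retries")
})

test_that("datasets on disk carry a 3:1 split and reproduce bit-identically", {
  cfg <- synth_config(image_width_px = 96, image_height_px = 96,
                      n_stomata_range = c(1, 2))
  d1 <- withr::local_tempdir()
  man <- generate_dataset(cfg, 8, d1, seed = 5)
  expect_equal(sum(vapply(man$images, function(e) e$split == "train",
                          logical(1))), 6)
  expect_equal(sum(vapply(man$images, function(e) e$split == "val",
                          logical(1))), 2)
  expect_length(list.files(d1, pattern = "\\.png$"), 8)

  d2 <- withr::local_tempdir()
  generate_dataset(cfg, 8, d2, seed = 5)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }

  ds <- read_dataset(d1)
  expect_length(ds$samples, 8)
  expect_equal(dim(ds$samples[[1]]$image), c(96, 96))

  d3 <- withr::local_tempdir()
  man0 <- generate_dataset(cfg, 0, d3, seed = 1)
  expect_equal(man0$n_images, 0)
  expect_length(list.files(d3, pattern = "\\.png$"), 0)
})
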