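test_that("border padding shifts labels and grows the canvas", {
  img <- matrix(100, 667, 1000)
  ann <- annotation_set("a", 1000, 667, 0.625,
                        list(rotated_box(10, 20, 40, 15, 70)))
  out <- pad_border(img, ann, 30)
  expect_equal(dim(out$image), c(727, 1060))
  expect_true(all(out$image[1:30, ] == 0))
  b <- out$annotations$boxes[[1]]
  expect_equal(c(b$cx, b$cy), c(40, 50))
  expect_equal(c(b$length, b$width, b$angle_deg), c(40, 15, 70))

  id <- pad_border(img, ann, 0)
  expect_identical(id$image, img)
  expect_equal(id$annotations$boxes[[1]]$cx, 10)
})

test_that("padding makes every previously valid box fully visible", {
  set.seed(31)
  for (i in 1:20) {
    b <- random_box(120, 90)
    if (visibility_fraction(b, 120, 90) <= 2 / 3) next
    b2 <- rotated_box(b$cx + 30, b$cy + 30, b$length, b$width, b$angle_deg)
    expect_gte(visibility_fraction(b2, 180, 150) + 1e-9,
               visibility_fraction(b, 120, 90))
  }
  # a box that already fits is fully visible after padding
  b <- rotated_box(60, 45, 30, 12, 25)
  expect_equal(visibility_fraction(rotated_box(90, 75, 30, 12, 25), 180, 150), 1)
})

test_that("grayscale stretch maps the band onto the full range", {
  p <- stretch_params(210, 255)
  expect_equal(gray_stretch(matrix(210), p), matrix(0))
  expect_equal(gray_stretch(matrix(255), p), matrix(255))
  expect_equal(gray_stretch(matrix(100), p), matrix(0))
  expect_equal(gray_stretch(matrix(232), p), matrix(125))
  # monotone non-decreasing
  g <- 0:255
  out <- gray_stretch(matrix(g, 1), p)
  expect_true(all(diff(as.vector(out)) >= 0))
  # identity parameters are idempotent
  img <- matrix(sample(0:255, 100, replace = TRUE), 10)
  expect_equal(gray_stretch(img, stretch_params(0, 255)), img)
  expect_error(stretch_params(200, 100), "lo < hi")
})

test_that("right-angle rotation transposes the frame and adds to angles", {
  img <- matrix(runif(80 * 60, 0, 255), 60, 80)
  ann <- annotation_set("a", 80, 60, 0.625,
                        list(rotated_box(39.5, 29.5, 20, 8, 30)))
  out <- rotate_augment(img, ann, 90)
  expect_equal(dim(out$image), c(80, 60))
  b <- out$annotations$boxes[[1]]
  expect_equal(b$angle_deg, 120)
  # center of image is a fixed point
  expect_equal(c(b$cx, b$cy), c((60 - 1) / 2, (80 - 1) / 2), tolerance = 1e-9)
})

test_that("rotation preserves box size, drops invisible boxes, and inverts", {
  img <- matrix(runif(100 * 100, 0, 255), 100, 100)
  boxes <- list(rotated_box(50, 50, 30, 10, 15),
                rotated_box(90, 10, 30, 10, 100))
  ann <- annotation_set("a", 100, 100, 0.625, boxes)
  out <- rotate_augment(img, ann, 30)
  for (b in out$annotations$boxes) {
    expect_equal(b$length, 30)
    expect_equal(b$width, 10)
  }
  expect_lte(length(out$annotations$boxes), length(boxes))
  # rotating back returns the center box to its original position
  back <- rotate_augment(out$image, out$annotations, -30)
  ctr <- back$annotations$boxes[[1]]
  # the double canvas expansion shifts the origin; compare relative to the
  # canvas centers, which the composition maps onto each other exactly
  est_x <- ctr$cx - (ncol(back$image) - 1) / 2 + (100 - 1) / 2
  est_y <- ctr$cy - (nrow(back$image) - 1) / 2 + (100 - 1) / 2
  expect_equal(c(est_x, est_y), c(50, 50), tolerance = 1e-6)
  expect_lt(angle_diff(ctr$angle_deg, 15), 1e-9)
})
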