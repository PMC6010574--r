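test_that("measure_points reads intensities in marker order", {
  img <- gray8(matrix(7L, 64, 64))
  mk <- marker_points(cbind(c(1, 10, 64), c(1, 20, 64)))
  expect_equal(measure_points(img, mk), c(7L, 7L, 7L))
  m <- matrix(7L, 64, 64); m[10, 20] <- 200L
  expect_equal(measure_points(gray8(m), mk), c(7L, 200L, 7L))
  out_of_bounds <- marker_points(cbind(65, 1))
  expect_error(measure_points(img, out_of_bounds), "bounds")
})

test_that("already-compliant markers leave the image untouched", {
  img <- rand_gray8(1)
  img[img > 200] <- 200L  # avoid saturation but keep structure
  img <- gray8(pmin(as.matrix(img), 15L))
  mk <- marker_points(cbind(c(2, 30), c(2, 30)))
  out <- dark_point_adjust(img, mk, target = 15)
  expect_length(out$adjustment$dark_points, 0)
  expect_identical(as.matrix(out$image), as.matrix(img))
})

test_that("uniform background 25 is suppressed below 15 within three passes", {
  img <- gray8(matrix(25L, 64, 64))
  mk <- marker_points(cbind(c(5, 40), c(5, 40)))
  out <- dark_point_adjust(img, mk, target = 15)
  expect_lte(out$adjustment$residual_max, 15L)
  expect_lte(length(out$adjustment$dark_points), 3L)
})

test_that("dark-point remap never raises a pixel and fixes 0 and 255", {
  img <- rand_gray8(2)
  img[1, 1] <- 0L; img[1, 2] <- 255L
  mk <- marker_points(which(as.matrix(img) < 60, arr.ind = TRUE)[1:10, ])
  out <- dark_point_adjust(img, mk, target = 15)
  expect_true(all(as.matrix(out$image) <= as.matrix(img)))
  expect_equal(out$image[1, 1], 0L)
  expect_equal(out$image[1, 2], 255L)
})

test_that("adjustment preserves intensity ordering on phantom backgrounds", {
  spec <- test_spec(seed = 3, background_level = 25, background_noise_sd = 3)
  ph <- generate_phantom(spec)
  mk <- negative_marker_points(ph, n = 40)
  # marker readings sit near the configured background level
  vals <- measure_points(ph$channels$green, mk)
  expect_true(all(abs(vals - 25) <= 4 * 3 + 1))
  out <- dark_point_adjust(ph$channels$green, mk, target = 15)
  expect_lte(out$adjustment$residual_max, 15L)
  before <- as.matrix(ph$channels$green)[1:32, 1:32]
  after <- as.matrix(out$image)[1:32, 1:32]
  ord <- order(as.vector(before))
  expect_true(all(diff(as.vector(after)[ord]) >= 0))
})

test_that("saturated or empty marker sets are rejected", {
  img <- gray8(matrix(255L, 64, 64))
  mk <- marker_points(cbind(1, 1))
  expect_error(dark_point_adjust(img, mk), "saturated")
  expect_error(marker_points(matrix(numeric(0), 0, 2)), "points")
})

test_that("leakage subtraction cancels identical channels and passes pure ones", {
  g <- rand_gray8(4, channel_tag = "green")
  r <- gray8(as.matrix(g), channel_tag = "red")
  out <- leakage_subtract(g, r)
  expect_equal(sum(as.matrix(out$green)), 0)
  expect_equal(sum(as.matrix(out$red)), 0)
  zero <- gray8(matrix(0L, 64, 64), channel_tag = "red")
  out2 <- leakage_subtract(g, zero, median_radius = 1)
  expect_equal(as.matrix(out2$red), matrix(0L, 64, 64))
  expect_identical(as.matrix(out2$green),
                   toothmap:::median_filter8(as.matrix(g), 1L))
})

test_that("leakage subtraction is antisymmetric and separates supports", {
  a <- rand_gray8(5)
  b <- rand_gray8(6)
  out <- leakage_subtract(a, b)
  swapped <- leakage_subtract(b, a)
  expect_identical(as.matrix(out$green), as.matrix(swapped$red))
  expect_identical(as.matrix(out$red), as.matrix(swapped$green))
  # before filtering at most one output is nonzero per pixel
  raw <- leakage_subtract(a, b, median_radius = 0)
  expect_true(all(as.matrix(raw$green) == 0 | as.matrix(raw$red) == 0))
})

test_that("a second leakage pass is a no-op once channels are separated", {
  a <- rand_gray8(7)
  b <- rand_gray8(8)
  first <- leakage_subtract(a, b, median_radius = 0)
  second <- leakage_subtract(first$green, first$red, median_radius = 0)
  expect_identical(as.matrix(second$green), as.matrix(first$green))
  expect_identical(as.matrix(second$red), as.matrix(first$red))
})

test_that("bleed-through from a pure source is removed to within rounding", {
  spec <- test_spec(seed = 9, background_level = 0, background_noise_sd = 0,
                    leakage_green_to_red = 0.2, leakage_red_to_green = 0,
                    nucleus_density = 0,
                    compartment_expression = single_expression("green",
                      "epithelium", mean = 150, span = 40))
  ph <- generate_phantom(spec)
  out <- leakage_subtract(ph$channels$green, ph$channels$red,
                          median_radius = 0)
  expect_equal(sum(as.matrix(out$red)), 0)
  g <- as.matrix(out$green)
  clean <- ph$clean$green
  # pixel loop against the closed-form leakage model
  ok <- TRUE
  for (idx in which(clean > 0)) {
    ok <- ok && (g[idx] >= 0.8 * clean[idx] - 1)
  }
  expect_true(ok)
})

test_that("shape mismatches are rejected", {
  expect_error(leakage_subtract(rand_gray8(1, 32, 32), rand_gray8(1, 16, 16)),
               "shape")
})
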