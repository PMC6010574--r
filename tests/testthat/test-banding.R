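test_that("thresholding is inclusive at the level", {
  expect_true(all(threshold_image(gray8(matrix(15L, 8, 8)), 15)))
  expect_false(any(threshold_image(gray8(matrix(14L, 8, 8)), 15)))
  img <- rand_gray8(1)
  expect_equal(sum(threshold_image(img, 95)), sum(as.matrix(img) >= 95))
})

test_that("default thresholds yield six subtraction products plus a top band", {
  bands <- band_images(rand_gray8(2), threshold_set())
  expect_length(bands, 7)
  products <- bands[1:6]
  expect_true(all(vapply(products, function(b) b$high <= 256L, logical(1))))
  expect_equal(bands[[7]]$low, 95L)
  expect_equal(bands[[7]]$high, 256L)
  expect_equal(bands[[7]]$color_label, "yellow")
  expect_equal(vapply(bands, `[[`, "", "color_label"),
               c("dark blue", "bright blue", "dark green", "bright green",
                 "dark red", "bright red", "yellow"))
})

test_that("a constant mid-intensity image fills exactly one band", {
  bands <- band_images(gray8(matrix(50L, 32, 32)), threshold_set())
  areas <- vapply(bands, function(b) sum(b$mask), integer(1))
  expect_equal(areas, c(0L, 0L, 32L * 32L, 0L, 0L, 0L, 0L))
  expect_equal(bands[[3]]$color_label, "dark green")
})

test_that("band masks equal brute-force half-open interval masks", {
  ts <- threshold_set()
  for (seed in 1:25) {
    img <- rand_gray8(seed)
    bands <- band_images(img, ts)
    for (b in bands) {
      expect_identical(b$mask, bf_interval_mask(img, b$low, b$high))
    }
  }
})

test_that("bands partition the above-baseline mask and conserve area", {
  for (seed in c(3, 4)) {
    img <- rand_gray8(seed)
    ts <- threshold_set()
    bands <- band_images(img, ts)
    total <- Reduce(`+`, lapply(bands, function(b) b$mask * 1L))
    expect_true(all(total <= 1L))
    expect_identical(total == 1L, threshold_image(img, ts$baseline))
    roi <- roi_mask(matrix(TRUE, nrow(img), ncol(img)))
    m <- domain_size(img, roi, ts)
    expect_equal(sum(m$band_histogram), m$domain_area)
  }
})

test_that("domain fraction is non-increasing in the baseline threshold", {
  img <- rand_gray8(5)
  roi <- roi_mask(matrix(TRUE, 64, 64))
  fr <- vapply(c(5, 15, 40, 80, 120), function(b) {
    domain_size(img, roi, threshold_set(c(b, 255)))$fraction
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("hotmaps label every above-baseline pixel exactly once", {
  img <- rand_gray8(6)
  ts <- threshold_set()
  bands <- band_images(img, ts)
  hm <- compose_hotmap(bands)
  expect_identical(hm$labels > 0L, threshold_image(img, ts$baseline))
  counts <- vapply(seq_along(bands), function(i) sum(hm$labels == i),
                   integer(1))
  expect_equal(counts, vapply(bands, function(b) sum(b$mask), integer(1)))
  # empty input image -> empty hotmap
  empty <- compose_hotmap(band_images(gray8(matrix(0L, 16, 16)), ts))
  expect_equal(sum(empty$labels), 0L)
})

test_that("overlapping bands are rejected as an integrity error", {
  img <- rand_gray8(7)
  bands <- band_images(img, threshold_set())
  bands[[2]]$mask <- bands[[1]]$mask  # corrupt: duplicate coverage
  expect_error(compose_hotmap(bands), "overlap")
})

test_that("hotmap label counts agree with the domain band histogram", {
  ph <- generate_phantom(test_spec(seed = 8))
  img <- ph$channels$green
  ts <- threshold_set()
  hm <- compose_hotmap(band_images(img, ts))
  m <- domain_size(img, roi_mask(matrix(TRUE, nrow(img), ncol(img))), ts)
  counts <- vapply(seq_along(m$band_histogram),
                   function(i) sum(hm$labels == i), integer(1))
  expect_equal(unname(m$band_histogram), counts)
})

test_that("domain fraction hits 0 and 100 at the extremes", {
  roi <- roi_mask(matrix(TRUE, 16, 16))
  expect_equal(domain_size(gray8(matrix(0L, 16, 16)), roi)$fraction, 0)
  expect_equal(domain_size(gray8(matrix(255L, 16, 16)), roi)$fraction, 100)
})

test_that("noiseless phantom fractions match generator truth within 0.5 points", {
  spec <- test_spec(seed = 10, background_level = 0, background_noise_sd = 0,
                    leakage_green_to_red = 0, leakage_red_to_green = 0,
                    nucleus_density = 0)
  ph <- generate_phantom(spec)
  roi <- roi_mask(matrix(TRUE, spec$height, spec$width))
  for (ch in c("green", "red")) {
    m <- domain_size(ph$channels[[ch]], roi)
    expect_lt(abs(m$fraction - true_fraction(ph, ch)), 0.5)
  }
})

test_that("sample-unit bands cover the range at five-pixel increments", {
  img <- rand_gray8(9)
  units <- sample_unit_bands(img, 15, 95, 5)
  expect_length(units, 16)
  expect_equal(units[[1]]$low, 15L); expect_equal(units[[1]]$high, 20L)
  expect_equal(units[[16]]$low, 90L); expect_equal(units[[16]]$high, 95L)
  union <- Reduce(`|`, lapply(units, `[[`, "mask"))
  expect_identical(union, bf_interval_mask(img, 15, 95))
  single <- sample_unit_bands(img, 15, 30, 15)
  expect_length(single, 1)
  expect_equal(c(single[[1]]$low, single[[1]]$high), c(15L, 30L))
  expect_error(sample_unit_bands(img, 15, 95, 7), "step")
})

test_that("ROI and threshold-set validation catches bad inputs", {
  expect_error(roi_mask(matrix(FALSE, 4, 4)), "non-empty")
  expect_error(threshold_set(c(15)), "levels")
  expect_error(threshold_set(c(30, 15)), "increasing")
  expect_error(threshold_set(c(0, 15)), "levels")
  img <- rand_gray8(1, 16, 16)
  expect_error(domain_size(img, roi_mask(matrix(TRUE, 8, 8))), "shape")
})
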