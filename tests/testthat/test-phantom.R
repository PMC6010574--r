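test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generate_phantom(test_spec(seed = 11))
  b <- generate_phantom(test_spec(seed = 11))
  for (ch in names(a$channels)) {
    expect_identical(as.matrix(a$channels[[ch]]), as.matrix(b$channels[[ch]]))
  }
  expect_identical(a$true_domain_fraction, b$true_domain_fraction)
  c <- generate_phantom(test_spec(seed = 12))
  expect_false(identical(as.matrix(a$channels$green),
                         as.matrix(c$channels$green)))
})

test_that("compartment masks are pairwise disjoint and tile the frame", {
  ph <- generate_phantom(test_spec(seed = 2))
  total <- Reduce(`+`, lapply(ph$compartment_masks, function(m) m * 1L))
  expect_true(all(total == 1L))
  for (stage in c("bud", "cap", "bell_cl", "bell_iee")) {
    ph2 <- generate_phantom(test_spec(seed = 3, stage_label = stage))
    total2 <- Reduce(`+`, lapply(ph2$compartment_masks, function(m) m * 1L))
    expect_true(all(total2 == 1L))
    expect_true(all(vapply(ph2$compartment_masks[
      c("epithelium", "mesenchyme", "cervical_loop", "iee")], any,
      logical(1))))
  }
})

test_that("stored ground truth matches brute-force counting on clean rasters", {
  ph <- generate_phantom(test_spec(seed = 5))
  for (ch in c("green", "red", "nuclear")) {
    clean <- ph$clean[[ch]]
    for (comp in names(ph$compartment_masks)) {
      m <- ph$compartment_masks[[comp]]
      expected <- if (sum(m) == 0) 0 else 100 * sum(clean[m] >= 15) / sum(m)
      expect_equal(true_fraction(ph, ch, comp), expected)
    }
    expect_equal(true_fraction(ph, ch, "whole_frame"),
                 100 * sum(clean >= 15) / length(clean))
  }
})

test_that("zero expression and zero background give all-zero factor ground truth", {
  spec <- test_spec(seed = 4, background_level = 0, background_noise_sd = 0,
                    compartment_expression = list())
  ph <- generate_phantom(spec)
  tdf <- ph$true_domain_fraction
  expect_true(all(tdf$fraction[tdf$channel %in% c("green", "red")] == 0))
  expect_equal(sum(as.matrix(ph$channels$green)), 0)
  expect_equal(sum(as.matrix(ph$channels$red)), 0)
})

test_that("single-compartment coverage is recovered in whole-frame ground truth", {
  spec <- test_spec(seed = 6, background_level = 0, background_noise_sd = 0,
                    leakage_green_to_red = 0, leakage_red_to_green = 0,
                    compartment_expression = single_expression("green",
                      "epithelium", mean = 200))
  ph <- generate_phantom(spec)
  coverage <- 100 * sum(ph$compartment_masks$epithelium) /
    (spec$width * spec$height)
  expect_equal(true_fraction(ph, "green", "whole_frame"), coverage)
  expect_equal(true_fraction(ph, "red", "whole_frame"), 0)
})

test_that("leakage is linear in the counter-channel's clean signal", {
  spec <- test_spec(seed = 7, background_level = 0, background_noise_sd = 0,
                    leakage_green_to_red = 0.2, leakage_red_to_green = 0,
                    compartment_expression = single_expression("green",
                      "epithelium", mean = 150, span = 40))
  ph <- generate_phantom(spec)
  obs_red <- as.matrix(ph$channels$red)
  pred <- pmin(255L, pmax(0L, as.integer(floor(
    ph$clean$red + 0.2 * ph$clean$green + 0.5))))
  nuc_free <- ph$clean$nuclear == 0
  expect_true(all(obs_red[nuc_free] == pred[nuc_free]))
})

test_that("negative control carries no factor signal and keeps nuclei", {
  spec <- test_spec(seed = 8, background_level = 25, background_noise_sd = 3)
  ph <- negative_control_phantom(spec)
  tdf <- ph$true_domain_fraction
  expect_true(all(tdf$fraction[tdf$channel %in% c("green", "red")] == 0))
  # normal tail bound: >= 99% of factor-channel pixels at or below 40
  for (ch in c("green", "red")) {
    frac_low <- mean(as.matrix(ph$channels[[ch]]) <= 40)
    expect_gte(frac_low, 0.99)
  }
  expect_gt(sum(ph$clean$nuclear > 0), 0)
  expect_gt(max(as.matrix(ph$channels$nuclear)), 100)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(phantom_spec(width = 32), "width")
  expect_error(phantom_spec(background_level = 80), "background_level")
  expect_error(phantom_spec(leakage_green_to_red = 1), "leakage_green_to_red")
  expect_error(phantom_spec(background_noise_sd = -1), "background_noise_sd")
  expect_error(phantom_spec(nucleus_density = -2), "nucleus_density")
})

test_that("phantoms round-trip to disk with an RLE mask sidecar", {
  ph <- generate_phantom(test_spec(seed = 9))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir)
  expect_true(file.exists(file.path(dir, "green.tif")))
  back <- read_gray8(file.path(dir, "green.tif"))
  expect_identical(as.matrix(back), as.matrix(ph$channels$green))
  sidecar <- jsonlite::read_json(file.path(dir, "phantom.json"),
                                 simplifyVector = TRUE)
  dec <- toothmap:::rle_decode_mask(sidecar$masks$epithelium)
  expect_identical(dec, ph$compartment_masks$epithelium)
})
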