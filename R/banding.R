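#' Intensity threshold set
#'
#' The strictly increasing 8-bit threshold levels used for intensity banding.
#' The default seven levels (15, 30, 45, 55, 70, 85, 95) define six
#' subtraction-product bands plus the open top band; the first level is the
#' baseline that separates expression domain from background.
#'
#' @param levels strictly increasing integer vector, each in \[1, 255\],
#'   length at least 2.
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(levels = c(15L, 30L, 45L, 55L, 70L, 85L, 95L)) {
  levels <- as.integer(levels)
  if (length(levels) < 2L) stop_field("levels", "need at least 2 levels")
  if (any(levels < 1L | levels > 255L)) {
    stop_field("levels", "levels must lie in [1, 255]")
  }
  if (any(diff(levels) <= 0L)) {
    stop_field("levels", "levels must be strictly increasing")
  }
  structure(list(levels = levels, baseline = levels[1L]),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("<threshold_set> levels %s (baseline %d)\n",
              paste(x$levels, collapse = ", "), x$baseline))
  invisible(x)
}

# Canonical hotmap colors for the default 7-band set (6 subtraction products
# plus the open yellow top band).
band_color_labels <- c("dark blue", "bright blue", "dark green",
                       "bright green", "dark red", "bright red", "yellow")
band_palette <- c(
  "dark blue" = "#00008B", "bright blue" = "#1E90FF",
  "dark green" = "#006400", "bright green" = "#00FF00",
  "dark red" = "#8B0000", "bright red" = "#FF4500",
  "yellow" = "#FFFF00")

#' Binary threshold image
#'
#' @param img a [gray8] image.
#' @param t threshold level in \[1, 255\]; the mask is inclusive at `t`
#'   (`pixel >= t`).
#' @return logical matrix.
#' @export
threshold_image <- function(img, t) {
  stopifnot(is_gray8(img))
  if (t < 1 || t > 255) stop_field("t", "must lie in [1, 255]")
  as_pixel_matrix(img) >= t
}

new_band_image <- function(mask, low, high, color_label) {
  structure(list(mask = mask, low = as.integer(low), high = as.integer(high),
                 color_label = color_label),
            class = "band_image")
}

#' @export
print.band_image <- function(x, ...) {
  cat(sprintf("<band_image> [%d, %s) '%s', %d px\n", x$low,
              if (x$high >= 256L) "256" else x$high, x$color_label,
              sum(x$mask)))
  invisible(x)
}

#' Threshold-band images by colorize, merge and subtract
#'
#' For each consecutive threshold pair the two binary threshold images are
#' merged and their overlap subtracted, leaving the pixels in the half-open
#' intensity interval \[t_i, t_{i+1}) — six subtraction products under the
#' default seven levels. The open top band (pixels at or above the last
#' level) is emitted additionally as the raw top threshold image, labeled
#' yellow. Together the bands partition the above-baseline domain.
#'
#' @param img a [gray8] image.
#' @param ts a [threshold_set()].
#' @return list of `band_image` objects, length `length(levels)`; all but the
#'   last are subtraction products, the last is the open top band.
#' @examples
#' img <- gray8(matrix(sample(0:255, 64^2, TRUE), 64, 64))
#' bands <- band_images(img, threshold_set())
#' length(bands)  # 6 subtraction products + 1 top band
#' @export
band_images <- function(img, ts = threshold_set()) {
  stopifnot(inherits(ts, "threshold_set"))
  lv <- ts$levels
  k <- length(lv)
  masks <- lapply(lv, function(t) threshold_image(img, t))
  labels <- if (k == 7L) band_color_labels else
    c(paste0("band_", seq_len(k - 1L)), "yellow")
  bands <- vector("list", k)
  for (i in seq_len(k - 1L)) {
    # merge of masks i and i+1; overlap (the "yellow" area) subtracted
    bands[[i]] <- new_band_image(masks[[i]] & !masks[[i + 1L]],
                                 lv[i], lv[i + 1L], labels[i])
  }
  bands[[k]] <- new_band_image(masks[[k]], lv[k], 256L, labels[k])
  bands
}

#' Composite intensity hotmap
#'
#' Merges disjoint band images into one pseudo-color label raster assigning
#' every above-baseline pixel to its intensity band.
#'
#' @param bands list of `band_image`s with pairwise disjoint masks.
#' @param palette named vector mapping color labels to hex colors; defaults
#'   to the canonical seven-band palette, with unknown labels assigned
#'   rainbow colors.
#' @return an object of class `hotmap`: a list with `labels` (integer matrix,
#'   0 = below baseline), `color_labels`, `palette` and `intervals`.
#' @export
compose_hotmap <- function(bands, palette = band_palette) {
  if (length(bands) == 0L) stop_field("bands", "must be non-empty")
  total <- Reduce(`+`, lapply(bands, function(b) b$mask * 1L))
  if (any(total > 1L)) stop("overlapping bands: masks must be disjoint",
                            call. = FALSE)
  labels <- matrix(0L, nrow(bands[[1]]$mask), ncol(bands[[1]]$mask))
  for (i in seq_along(bands)) labels[bands[[i]]$mask] <- i
  color_labels <- vapply(bands, `[[`, "", "color_label")
  pal <- palette[color_labels]
  if (anyNA(pal)) {
    extra <- grDevices::rainbow(sum(is.na(pal)))
    pal[is.na(pal)] <- extra
    names(pal) <- color_labels
  }
  structure(list(labels = labels, color_labels = color_labels,
                 palette = pal,
                 intervals = lapply(bands, function(b) c(b$low, b$high))),
            class = "hotmap")
}

#' @export
print.hotmap <- function(x, ...) {
  cat(sprintf("<hotmap> %d x %d, %d bands, %d labeled px\n",
              nrow(x$labels), ncol(x$labels), length(x$color_labels),
              sum(x$labels > 0L)))
  invisible(x)
}

#' Hotmap as an RGB array
#'
#' @param hotmap a `hotmap`.
#' @return numeric array (rows x cols x 3) in \[0, 1\]; unlabeled pixels are
#'   black.
#' @export
hotmap_rgb <- function(hotmap) {
  rgb <- grDevices::col2rgb(hotmap$palette) / 255
  arr <- array(0, c(dim(hotmap$labels), 3L))
  for (i in seq_along(hotmap$color_labels)) {
    sel <- hotmap$labels == i
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[sel] <- rgb[ch, i]
      arr[, , ch] <- plane
    }
  }
  arr
}

#' Write a hotmap to a PNG file
#'
#' @param hotmap a `hotmap`.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_hotmap_png <- function(hotmap, path) {
  png::writePNG(hotmap_rgb(hotmap), path)
  invisible(path)
}

#' Region-of-interest mask
#'
#' @param mask logical matrix (non-empty).
#' @param id ROI identifier, e.g. `"whole_tooth_germ"`, `"cervical_loop"`,
#'   `"iee"`.
#' @return an object of class `roi_mask` with `mask`, `id` and `area`.
#' @export
roi_mask <- function(mask, id = "whole_tooth_germ") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_field("mask", "must be a logical matrix")
  }
  if (!any(mask)) stop_field("mask", "ROI must be non-empty")
  structure(list(mask = mask, id = id, area = sum(mask)),
            class = "roi_mask")
}

#' Expression-domain size within a region of interest
#'
#' The expression domain is the set of ROI pixels at or above the baseline
#' threshold; its size is expressed as a percentage of total ROI area,
#' together with the per-band pixel histogram (the band areas sum exactly to
#' the domain area).
#'
#' @param img a [gray8] image.
#' @param roi a [roi_mask()] of the same shape.
#' @param ts a [threshold_set()].
#' @param factor,stage optional annotation carried into the measurement.
#' @return an object of class `domain_measurement` with fields `factor`,
#'   `stage`, `roi_id`, `roi_area`, `domain_area`, `fraction` (percent) and
#'   `band_histogram` (named pixel counts).
#' @export
domain_size <- function(img, roi, ts = threshold_set(),
                        factor = NA_character_, stage = NA_character_) {
  stopifnot(is_gray8(img), inherits(roi, "roi_mask"))
  assert_same_shape(img, roi$mask, "image and ROI")
  bands <- band_images(img, ts)
  hist <- vapply(bands, function(b) sum(b$mask & roi$mask), integer(1))
  names(hist) <- vapply(bands, `[[`, "", "color_label")
  domain_area <- sum(as_pixel_matrix(img)[roi$mask] >= ts$baseline)
  structure(list(factor = factor, stage = stage, roi_id = roi$id,
                 roi_area = roi$area, domain_area = domain_area,
                 fraction = 100 * domain_area / roi$area,
                 band_histogram = hist),
            class = "domain_measurement")
}

#' @export
print.domain_measurement <- function(x, ...) {
  cat(sprintf("<domain_measurement> %s/%s roi '%s': %.2f%% (%d / %d px)\n",
              x$factor, x$stage, x$roi_id, x$fraction, x$domain_area,
              x$roi_area))
  invisible(x)
}

#' Collect domain measurements into a tidy table
#'
#' @param measurements list of `domain_measurement`s.
#' @return data.frame with one row per measurement and per-band count columns.
#' @export
domain_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m) {
    row <- data.frame(factor = m$factor, stage = m$stage, roi = m$roi_id,
                      roi_area = m$roi_area, domain_area = m$domain_area,
                      fraction = m$fraction, stringsAsFactors = FALSE)
    counts <- as.data.frame(as.list(m$band_histogram), optional = TRUE)
    names(counts) <- gsub(" ", "_", names(m$band_histogram))
    cbind(row, counts)
  }))
}

#' Sample-unit band images at fixed pixel increments
#'
#' Builds the statistical sampling units of the intensity-distribution
#' analysis: contiguous half-open bands covering \[`low`, `high`) at
#' `step`-pixel increments (default 15--95 by 5, giving 16 bands: 15--20,
#' 20--25, ..., 90--95). Each band is the subtraction product of the two
#' bracketing threshold images; no open top band is emitted.
#'
#' @param img a [gray8] image.
#' @param low,high band range bounds, 8-bit values with `low < high`.
#' @param step band width in pixels; must divide `high - low`.
#' @return list of `band_image`s of length `(high - low) / step`.
#' @export
sample_unit_bands <- function(img, low = 15L, high = 95L, step = 5L) {
  stopifnot(is_gray8(img))
  if (low >= high) stop_field("low", "must satisfy low < high")
  if (step < 1 || (high - low) %% step != 0) {
    stop_field("step", "must divide (high - low)")
  }
  edges <- seq(as.integer(low), as.integer(high), by = as.integer(step))
  lapply(seq_len(length(edges) - 1L), function(i) {
    new_band_image(
      threshold_image(img, edges[i]) & !threshold_image(img, edges[i + 1L]),
      edges[i], edges[i + 1L], sprintf("unit_%d_%d", edges[i], edges[i + 1L]))
  })
}

#' Per-sample-unit domain fractions within an ROI
#'
#' Fraction of ROI area covered by each sample-unit band, in percent; one
#' observation per sample-unit image, as used for rank-based group
#' comparison.
#'
#' @inheritParams sample_unit_bands
#' @param roi a [roi_mask()].
#' @return numeric vector, one percentage per band.
#' @export
sample_unit_fractions <- function(img, roi, low = 15L, high = 95L, step = 5L) {
  stopifnot(inherits(roi, "roi_mask"))
  assert_same_shape(img, roi$mask, "image and ROI")
  bands <- sample_unit_bands(img, low, high, step)
  vapply(bands, function(b) 100 * sum(b$mask & roi$mask) / roi$area,
         numeric(1))
}
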