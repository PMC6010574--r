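#' Intensity co-localization scatterplot grid
#'
#' The exact 256 x 256 joint histogram of paired pixel intensities over an
#' ROI: entry (i, j) counts pixels with channel-A value i-1 and channel-B
#' value j-1. Swapping the channels transposes the grid; total mass equals
#' the ROI pixel count.
#'
#' @param a,b [gray8] images of identical shape.
#' @param roi optional [roi_mask()]; defaults to the whole frame.
#' @return an object of class `scatter_grid`: a list with `counts` (256 x
#'   256 integer matrix), `marginal_a`, `marginal_b` and `n`.
#' @export
scatterplot <- function(a, b, roi = NULL) {
  stopifnot(is_gray8(a), is_gray8(b))
  assert_same_shape(a, b, "channels")
  sel <- roi_selector(roi, a)
  av <- as_pixel_matrix(a)[sel]
  bv <- as_pixel_matrix(b)[sel]
  counts <- matrix(tabulate(av * 256L + bv + 1L, nbins = 256L * 256L),
                   256L, 256L, byrow = TRUE,
                   dimnames = list(a = 0:255, b = 0:255))
  structure(list(counts = counts,
                 marginal_a = rowSums(counts), marginal_b = colSums(counts),
                 n = length(av)),
            class = "scatter_grid")
}

#' @export
print.scatter_grid <- function(x, ...) {
  cat(sprintf("<scatter_grid> 256 x 256 joint histogram over %d px\n", x$n))
  invisible(x)
}

roi_selector <- function(roi, img) {
  if (is.null(roi)) {
    matrix(TRUE, nrow(img), ncol(img))
  } else {
    stopifnot(inherits(roi, "roi_mask"))
    assert_same_shape(img, roi$mask, "image and ROI")
    roi$mask
  }
}

#' Intensity correlation and nuclear/non-nuclear pattern call
#'
#' Quantifies the visual scatterplot reading: Pearson correlation of the two
#' channels over qualifying pixels (either channel at or above the baseline
#' — co-absent background is excluded so it cannot inflate the correlation)
#' plus the overlap fraction, the percentage of channel-A expression-domain
#' pixels also at or above baseline in channel B. When channel B is the
#' nuclear stain, the pattern is called `nuclear` if both the correlation and
#' overlap clear their cutoffs, `non_nuclear` if both fall below, `mixed`
#' otherwise.
#'
#' @param a,b [gray8] images of identical shape; `b` is typically the
#'   nuclear (DAPI) channel.
#' @param roi optional [roi_mask()].
#' @param baseline expression baseline intensity (default 15).
#' @param r_cutoff,overlap_cutoff decision cutoffs for the pattern call
#'   (defaults 0.5 and 50%); these are configurable conventions, not
#'   measured constants.
#' @return an object of class `coloc_result` with `pearson_r`,
#'   `overlap_fraction` (percent), `pattern_call` and `n_qualifying`.
#' @export
intensity_correlation <- function(a, b, roi = NULL, baseline = 15L,
                                  r_cutoff = 0.5, overlap_cutoff = 50) {
  stopifnot(is_gray8(a), is_gray8(b))
  assert_same_shape(a, b, "channels")
  sel <- roi_selector(roi, a)
  av <- as.numeric(as_pixel_matrix(a)[sel])
  bv <- as.numeric(as_pixel_matrix(b)[sel])
  qual <- av >= baseline | bv >= baseline
  if (sum(qual) < 2L) stop("insufficient signal", call. = FALSE)
  aq <- av[qual]; bq <- bv[qual]
  r <- if (stats::sd(aq) == 0 || stats::sd(bq) == 0) {
    NA_real_
  } else {
    stats::cor(aq, bq)
  }
  na <- sum(av >= baseline)
  overlap <- if (na == 0) 0 else 100 * sum(av >= baseline & bv >= baseline) / na
  b_nuclear <- identical(attr(b, "channel_tag"), "nuclear")
  high <- !is.na(r) && r >= r_cutoff && overlap >= overlap_cutoff
  low <- (is.na(r) || r < r_cutoff) && overlap < overlap_cutoff
  pattern <- if (b_nuclear && high) "nuclear"
             else if (low) "non_nuclear"
             else "mixed"
  structure(list(pearson_r = r, overlap_fraction = overlap,
                 pattern_call = pattern, n_qualifying = sum(qual),
                 baseline = as.integer(baseline)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> r = %.3f, overlap = %.1f%%, pattern '%s' (%d px)\n",
              x$pearson_r, x$overlap_fraction, x$pattern_call,
              x$n_qualifying))
  invisible(x)
}

#' Serial-threshold co-localization series
#'
#' Merges the reference channel thresholded at baseline with the probe
#' channel thresholded at a rising series of levels (default the first four
#' hotmap levels 15, 30, 45, 55). Overlap masks are nested, so overlap areas
#' are non-increasing with the probe level. The series is flagged
#' `baseline_only` when overlap at the lowest level exceeds the next level's
#' overlap by at least `flag_factor` (default 2): the probe co-localizes with
#' the reference only in the baseline intensity range.
#'
#' @param reference,probe [gray8] images of identical shape.
#' @param probe_thresholds strictly ascending probe levels.
#' @param baseline reference threshold (default 15).
#' @param roi optional [roi_mask()].
#' @param flag_factor drop factor triggering the baseline-only flag.
#' @return an object of class `serial_coloc_series` with `levels`, `masks`,
#'   `areas` and `baseline_only`.
#' @export
serial_coloc <- function(reference, probe,
                         probe_thresholds = c(15L, 30L, 45L, 55L),
                         baseline = 15L, roi = NULL, flag_factor = 2) {
  stopifnot(is_gray8(reference), is_gray8(probe))
  assert_same_shape(reference, probe, "reference and probe")
  if (length(probe_thresholds) < 1L || any(diff(probe_thresholds) <= 0)) {
    stop_field("probe_thresholds", "must be strictly ascending")
  }
  sel <- roi_selector(roi, reference)
  ref_mask <- threshold_image(reference, baseline) & sel
  masks <- lapply(probe_thresholds, function(t) {
    ref_mask & threshold_image(probe, t)
  })
  areas <- vapply(masks, sum, integer(1))
  baseline_only <- if (length(areas) >= 2L) {
    areas[1] > 0 && areas[1] >= flag_factor * areas[2]
  } else NA
  structure(list(levels = as.integer(probe_thresholds), masks = masks,
                 areas = areas, baseline_only = baseline_only,
                 baseline = as.integer(baseline)),
            class = "serial_coloc_series")
}

#' @export
print.serial_coloc_series <- function(x, ...) {
  cat(sprintf("<serial_coloc_series> levels %s -> areas %s%s\n",
              paste(x$levels, collapse = ", "),
              paste(x$areas, collapse = ", "),
              if (isTRUE(x$baseline_only)) " [baseline-only]" else ""))
  invisible(x)
}
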