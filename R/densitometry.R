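#' Pixel-to-optical-density calibration from step-tablet readings
#'
#' Builds a monotone piecewise-linear conversion from 8-bit pixel value to
#' optical density (OD) out of measurements of a calibrated step tablet
#' (nominally 21 steps spanning 0.05--3.05 OD; in 8-bit data the deepest
#' steps collapse onto the same pixel value, so fewer distinct readings
#' suffice). OD is anti-monotone in pixel value: increasing OD corresponds to
#' decreasing intensity. Pixels outside the measured range clamp to the
#' nearest endpoint OD.
#'
#' @param readings data.frame with columns `nominal_od` (each in
#'   \[0.05, 3.05\]) and `measured_pixel` (8-bit values); at least two
#'   readings with distinct pixel values.
#' @return an object of class `calibration_curve` with the sorted readings
#'   and a vectorized `mapping(pixel) -> OD` function.
#' @examples
#' cal <- build_calibration(data.frame(nominal_od = c(0.05, 3.05),
#'                                     measured_pixel = c(250, 5)))
#' cal$mapping(c(5, 127.5, 250))
#' @export
build_calibration <- function(readings) {
  if (!is.data.frame(readings) ||
      !all(c("nominal_od", "measured_pixel") %in% names(readings))) {
    stop_field("readings",
               "need columns 'nominal_od' and 'measured_pixel'")
  }
  if (any(readings$nominal_od < 0.05 - 1e-12 |
          readings$nominal_od > 3.05 + 1e-12)) {
    stop_field("nominal_od", "must lie in [0.05, 3.05]")
  }
  if (any(readings$measured_pixel < 0 | readings$measured_pixel > 255)) {
    stop_field("measured_pixel", "must lie in [0, 255]")
  }
  readings <- readings[order(readings$measured_pixel), , drop = FALSE]
  px <- readings$measured_pixel
  od <- readings$nominal_od
  dup <- duplicated(px)
  if (any(dup)) {
    same <- tapply(od, px, function(v) diff(range(v)) < 1e-12)
    if (!all(same)) {
      stop("duplicate pixel values with different OD", call. = FALSE)
    }
    readings <- readings[!dup, , drop = FALSE]
    px <- readings$measured_pixel
    od <- readings$nominal_od
  }
  if (nrow(readings) < 2L) {
    stop("need at least 2 readings with distinct pixel values", call. = FALSE)
  }
  if (any(diff(od) > 1e-12)) {
    stop("anti-monotone readings: OD must not increase with pixel value",
         call. = FALSE)
  }
  mapping <- function(pixel) {
    stats::approx(px, od, xout = pixel, rule = 2, ties = "ordered")$y
  }
  structure(list(readings = readings, mapping = mapping),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d readings, pixel [%d, %d] -> OD [%.2f, %.2f]\n",
              nrow(x$readings), min(x$readings$measured_pixel),
              max(x$readings$measured_pixel),
              min(x$readings$nominal_od), max(x$readings$nominal_od)))
  invisible(x)
}

#' Read step-tablet calibration measurements from CSV
#'
#' @param path CSV with columns `nominal_od`, `measured_pixel`.
#' @return a `calibration_curve` (see [build_calibration()]).
#' @export
read_calibration_csv <- function(path) {
  build_calibration(utils::read.csv(path))
}

#' Convert a pixel image to an optical-density grid
#'
#' Element-wise application of the calibration mapping; the result inherits
#' the image's physical pixel size for cm-calibrated axes.
#'
#' @param img a [gray8] image.
#' @param curve a `calibration_curve` from [build_calibration()].
#' @return an object of class `od_grid`: a numeric matrix of OD values with
#'   attribute `pixel_size`.
#' @export
to_od <- function(img, curve) {
  stopifnot(is_gray8(img), inherits(curve, "calibration_curve"))
  m <- as_pixel_matrix(img)
  grid <- matrix(curve$mapping(as.vector(m)), nrow(m), ncol(m))
  structure(grid, pixel_size = attr(img, "pixel_size"),
            class = c("od_grid", "matrix", "array"))
}

#' @export
print.od_grid <- function(x, ...) {
  cat(sprintf("<od_grid> %d x %d, OD range [%.3f, %.3f]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Vertical intensity plot profile in OD
#'
#' Scans the OD grid vertically, aggregating each row to one value, with
#' positions calibrated in cm (row offset times pixel size). The `"mean"`
#' statistic reports the mean OD per row; `"max"` reports the row's peak
#' signal, i.e. its minimum OD (OD is anti-monotone in intensity).
#'
#' @param grid an `od_grid` from [to_od()], carrying a pixel size.
#' @param row_statistic `"mean"` or `"max"`.
#' @return data.frame of class `profile_curve` with `position_cm` (strictly
#'   increasing, one per row) and `od`.
#' @export
plot_profile <- function(grid, row_statistic = c("mean", "max")) {
  stopifnot(inherits(grid, "od_grid"))
  row_statistic <- match.arg(row_statistic)
  ps <- attr(grid, "pixel_size")
  if (is.null(ps)) stop("pixel_size missing: calibrate the image in cm first",
                        call. = FALSE)
  vals <- switch(row_statistic,
                 mean = rowMeans(grid),
                 max = apply(grid, 1, min))  # peak intensity = minimum OD
  out <- data.frame(position_cm = (seq_len(nrow(grid)) - 1) * ps, od = vals)
  attr(out, "aggregation") <- row_statistic
  class(out) <- c("profile_curve", "data.frame")
  out
}

#' Surface-plot height field
#'
#' Pass-through of the OD grid with cm axes for 3D surface rendering;
#' optionally block-averaged to a coarser grid for display.
#'
#' @param grid an `od_grid`.
#' @param downsample integer block size for optional block-mean reduction
#'   (1 = none).
#' @return list with `x_cm` (columns), `y_cm` (rows) and `od` matrix.
#' @export
surface_plot_data <- function(grid, downsample = 1L) {
  stopifnot(inherits(grid, "od_grid"))
  ps <- attr(grid, "pixel_size") %||% 1
  od <- matrix(as.numeric(grid), nrow(grid), ncol(grid))
  if (downsample > 1L) {
    nr <- floor(nrow(od) / downsample)
    nc <- floor(ncol(od) / downsample)
    od <- vapply(seq_len(nc), function(j) {
      vapply(seq_len(nr), function(i) {
        mean(od[((i - 1) * downsample + 1):(i * downsample),
                ((j - 1) * downsample + 1):(j * downsample)])
      }, numeric(1))
    }, numeric(nr))
    step <- ps * downsample
  } else {
    step <- ps
  }
  list(x_cm = (seq_len(ncol(od)) - 1) * step,
       y_cm = (seq_len(nrow(od)) - 1) * step,
       od = od)
}
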