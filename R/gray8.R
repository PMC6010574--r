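#' 8-bit grayscale image
#'
#' The universal pixel currency of the pipeline: a rectangular integer matrix
#' with values in \[0, 255\], optionally carrying a physical pixel size (cm per
#' pixel, used for cm-calibrated densitometry axes) and a channel tag.
#'
#' @param pixels integer or numeric matrix with all values in \[0, 255\].
#' @param pixel_size optional physical size of one pixel in cm.
#' @param channel_tag one of `"nuclear"`, `"green"`, `"red"`, `"other"`.
#' @return an object of class `gray8`: an integer matrix with attributes
#'   `pixel_size` and `channel_tag`.
#' @examples
#' img <- gray8(matrix(0:255, 16, 16))
#' range(img)
#' @export
gray8 <- function(pixels, pixel_size = NULL, channel_tag = "other") {
  if (!is.matrix(pixels)) stop_field("pixels", "must be a matrix")
  if (anyNA(pixels)) stop_field("pixels", "contains NA")
  if (any(pixels < 0 | pixels > 255)) {
    stop_field("pixels", "values must lie in [0, 255]")
  }
  channel_tag <- match.arg(channel_tag, c("nuclear", "green", "red", "other"))
  if (!is.null(pixel_size) && (!is.numeric(pixel_size) || pixel_size <= 0)) {
    stop_field("pixel_size", "must be a positive number (cm/pixel)")
  }
  m <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  structure(m, pixel_size = pixel_size, channel_tag = channel_tag,
            class = c("gray8", "matrix", "array"))
}

#' @export
print.gray8 <- function(x, ...) {
  cat(sprintf("<gray8> %d x %d, channel '%s', range [%d, %d]%s\n",
              nrow(x), ncol(x), attr(x, "channel_tag"),
              min(x), max(x),
              if (!is.null(attr(x, "pixel_size")))
                sprintf(", pixel %.3g cm", attr(x, "pixel_size")) else ""))
  invisible(x)
}

is_gray8 <- function(x) inherits(x, "gray8")

#' @export
as.matrix.gray8 <- function(x, ...) {
  matrix(as.integer(x), nrow(x), ncol(x))
}

# Strip class/attributes down to a bare integer matrix.
as_pixel_matrix <- function(x) {
  if (is_gray8(x)) {
    matrix(as.integer(x), nrow(x), ncol(x))
  } else if (is.matrix(x)) {
    matrix(as.integer(x), nrow(x), ncol(x))
  } else {
    stop("expected a gray8 image or matrix", call. = FALSE)
  }
}

# Rebuild a gray8 carrying over calibration metadata from a template image.
gray8_like <- function(pixels, template) {
  gray8(pixels,
        pixel_size = attr(template, "pixel_size"),
        channel_tag = attr(template, "channel_tag") %||% "other")
}

#' Read an 8-bit grayscale image from TIFF or PNG
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @inheritParams gray8
#' @return a [gray8] image.
#' @export
read_gray8 <- function(path, pixel_size = NULL, channel_tag = "other") {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_field("path", "unsupported extension (use .tif/.tiff/.png)"))
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # first channel of an RGB read
  gray8(round(m * 255), pixel_size = pixel_size, channel_tag = channel_tag)
}

#' Write an 8-bit grayscale image to TIFF or PNG
#'
#' @param img a [gray8] image.
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray8 <- function(img, path) {
  stopifnot(is_gray8(img))
  m <- as_pixel_matrix(img) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    png = png::writePNG(m, path),
    stop_field("path", "unsupported extension (use .tif/.tiff/.png)"))
  invisible(path)
}

#' Marker point set for background verification
#'
#' Positions placed in structures known to be negative for the stain under
#' scrutiny (cell nuclei for factor channels, inter-nuclear spaces for the
#' nuclear stain). Intensities read at these points drive and audit the
#' dark-point background adjustment.
#'
#' @param points two-column matrix or data.frame of (row, col) positions.
#' @param expected_negative logical; marker structures should carry no true
#'   signal. Must be `TRUE` for use in [dark_point_adjust()].
#' @return an object of class `marker_points`.
#' @export
marker_points <- function(points, expected_negative = TRUE) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop_field("points", "must be non-empty")
  if (ncol(points) != 2L) stop_field("points", "must have (row, col) columns")
  if (anyNA(points) || any(points < 1)) {
    stop_field("points", "positions must be positive (row, col) indices")
  }
  structure(list(points = matrix(as.integer(points), ncol = 2L,
                                 dimnames = list(NULL, c("row", "col"))),
                 expected_negative = isTRUE(expected_negative)),
            class = "marker_points")
}

check_markers_in_bounds <- function(markers, img) {
  p <- markers$points
  if (any(p[, 1] > nrow(img)) || any(p[, 2] > ncol(img))) {
    stop_field("points", "marker point outside image bounds")
  }
  invisible(TRUE)
}
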