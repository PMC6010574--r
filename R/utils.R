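# Internal helpers shared across modules.

# 8-bit saturating arithmetic: clip to [0,255], round half-up.
clip8 <- function(x) {
  y <- pmin(255L, pmax(0L, floor(x + 0.5)))
  if (is.matrix(x)) {
    matrix(as.integer(y), nrow(x), ncol(x))
  } else {
    as.integer(y)
  }
}

# round() in R rounds half to even; the 8-bit dialect here rounds half up.
round_half_up <- function(x) {
  y <- floor(x + 0.5)
  if (is.matrix(x)) {
    matrix(as.integer(y), nrow(x), ncol(x))
  } else {
    as.integer(y)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(as_pixel_matrix(a)), dim(as_pixel_matrix(b)))) {
    stop(sprintf("shape mismatch: %s must have identical dimensions", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Run-length encode a logical matrix column-major, for plain-text sidecars.
rle_encode_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), lengths = r$lengths, values = as.logical(r$values))
}

rle_decode_mask <- function(enc) {
  v <- inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                  values = as.logical(enc$values)),
                             class = "rle"))
  matrix(v, nrow = enc$dim[1], ncol = enc$dim[2])
}
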