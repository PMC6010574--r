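#' Specification for a synthetic tooth-germ phantom
#'
#' Describes a two-factor (green/red) plus nuclear-channel fluorescence
#' micrograph of an epithelial/mesenchymal organ section: parametric
#' compartment geometry (enamel-organ epithelium enclosing a mesenchymal
#' papilla, cervical loops at the lateral margins, an inner-enamel-epithelium
#' interface band), compartment-restricted factor expression with linear
#' intensity gradients, DAPI-like nuclei, additive autofluorescent background
#' with Gaussian noise, and linear red/green spectral bleed-through.
#'
#' @param width,height frame size in pixels (each at least 64).
#' @param pixel_size physical pixel size in cm (for densitometry axes).
#' @param stage_label developmental stage geometry: `"bud"`, `"cap"`,
#'   `"bell_cl"` or `"bell_iee"`.
#' @param background_level mean autofluorescent background, 8-bit units,
#'   in \[0, 64\].
#' @param background_noise_sd SD of additive Gaussian noise (8-bit units).
#' @param leakage_green_to_red,leakage_red_to_green dimensionless
#'   bleed-through coefficients in \[0, 1).
#' @param nucleus_density nuclei per 1000 px^2 of tissue.
#' @param compartment_expression nested list
#'   `channel -> compartment -> list(mean, gradient_direction, gradient_span)`
#'   with mean intensity in 8-bit units, gradient direction in degrees (0 =
#'   along columns, 90 = along rows) and span the peak-to-peak intensity range
#'   of the linear gradient across the compartment.
#' @param seed integer seed making the phantom fully reproducible.
#' @return an object of class `phantom_spec`.
#' @seealso [generate_phantom()], [negative_control_phantom()]
#' @export
phantom_spec <- function(width = 192L, height = 144L,
                         pixel_size = 1.8e-4,
                         stage_label = c("cap", "bud", "bell_cl", "bell_iee"),
                         background_level = 25,
                         background_noise_sd = 3,
                         leakage_green_to_red = 0.15,
                         leakage_red_to_green = 0.10,
                         nucleus_density = 6,
                         compartment_expression = default_expression(),
                         seed = 1L) {
  stage_label <- match.arg(stage_label)
  spec <- structure(list(
    width = as.integer(width), height = as.integer(height),
    pixel_size = pixel_size, stage_label = stage_label,
    background_level = background_level,
    background_noise_sd = background_noise_sd,
    leakage_green_to_red = leakage_green_to_red,
    leakage_red_to_green = leakage_red_to_green,
    nucleus_density = nucleus_density,
    compartment_expression = compartment_expression,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Default compartment expression pattern
#'
#' Green factor strongest in the cervical loops and inner enamel epithelium
#' with a graded epithelial domain; red factor in the mesenchymal papilla.
#' Values are 8-bit intensities.
#'
#' @return nested list suitable for the `compartment_expression` field of
#'   [phantom_spec()].
#' @export
default_expression <- function() {
  list(
    green = list(
      epithelium    = list(mean = 110, gradient_direction = 90,
                           gradient_span = 60),
      cervical_loop = list(mean = 190, gradient_direction = 0,
                           gradient_span = 30),
      iee           = list(mean = 150, gradient_direction = 0,
                           gradient_span = 40)),
    red = list(
      mesenchyme    = list(mean = 90, gradient_direction = 0,
                           gradient_span = 50),
      cervical_loop = list(mean = 60, gradient_direction = 0,
                           gradient_span = 20)))
}

validate_phantom_spec <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("not a phantom_spec", call. = FALSE)
  if (spec$width < 64L) stop_field("width", "must be >= 64 pixels")
  if (spec$height < 64L) stop_field("height", "must be >= 64 pixels")
  if (spec$pixel_size <= 0) stop_field("pixel_size", "must be positive")
  if (spec$background_level < 0 || spec$background_level > 64) {
    stop_field("background_level", "must lie in [0, 64]")
  }
  if (spec$background_noise_sd < 0) {
    stop_field("background_noise_sd", "must be non-negative")
  }
  for (f in c("leakage_green_to_red", "leakage_red_to_green")) {
    v <- spec[[f]]
    if (v < 0 || v >= 1) stop_field(f, "must lie in [0, 1)")
  }
  if (spec$nucleus_density < 0) {
    stop_field("nucleus_density", "must be non-negative")
  }
  for (ch in names(spec$compartment_expression)) {
    for (comp in names(spec$compartment_expression[[ch]])) {
      e <- spec$compartment_expression[[ch]][[comp]]
      if (is.null(e$mean) || e$mean < 0 || e$mean > 255) {
        stop_field("compartment_expression",
                   sprintf("mean for %s/%s must lie in [0, 255]", ch, comp))
      }
      if ((e$gradient_span %||% 0) < 0) {
        stop_field("compartment_expression",
                   sprintf("gradient_span for %s/%s must be non-negative",
                           ch, comp))
      }
    }
  }
  invisible(spec)
}

# Parametric section geometry: label priority cervical_loop > iee >
# epithelium > mesenchyme > background; masks are disjoint and tile the frame.
phantom_geometry <- function(width, height, stage_label) {
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  ell <- function(cy, cx, ry, rx) ((row - cy) / ry)^2 + ((col - cx) / rx)^2 <= 1

  p <- switch(stage_label,
    bud      = list(Ey = 0.46, Ery = 0.30, Erx = 0.25,
                    Py = 0.58, Pry = 0.10, Prx = 0.11,
                    loop_r = 0.050, iee_thick = 4),
    cap      = list(Ey = 0.42, Ery = 0.34, Erx = 0.32,
                    Py = 0.56, Pry = 0.20, Prx = 0.23,
                    loop_r = 0.070, iee_thick = 5),
    bell_cl  = list(Ey = 0.40, Ery = 0.36, Erx = 0.34,
                    Py = 0.55, Pry = 0.24, Prx = 0.26,
                    loop_r = 0.085, iee_thick = 5),
    bell_iee = list(Ey = 0.40, Ery = 0.36, Erx = 0.34,
                    Py = 0.55, Pry = 0.24, Prx = 0.26,
                    loop_r = 0.070, iee_thick = 8))

  cx <- 0.5 * width
  E <- ell(p$Ey * height, cx, p$Ery * height, p$Erx * width)
  P <- ell(p$Py * height, cx, p$Pry * height, p$Prx * width)
  P <- P & E
  epithelium <- E & !P
  iee <- epithelium &
    ell(p$Py * height, cx,
        p$Pry * height + p$iee_thick, p$Prx * width + p$iee_thick)
  loop_r <- p$loop_r * min(width, height)
  ly <- p$Py * height + 0.6 * p$Pry * height
  lx_off <- p$Prx * width + 0.4 * loop_r
  cl <- (((row - ly)^2 + (col - (cx - lx_off))^2 <= loop_r^2) |
         ((row - ly)^2 + (col - (cx + lx_off))^2 <= loop_r^2)) & E

  lab <- matrix("background", height, width)
  lab[P] <- "mesenchyme"
  lab[epithelium] <- "epithelium"
  lab[iee] <- "iee"
  lab[cl] <- "cervical_loop"
  comps <- c("epithelium", "mesenchyme", "cervical_loop", "iee", "background")
  masks <- lapply(comps, function(k) lab == k)
  names(masks) <- comps
  masks
}

# Clean (pre-noise, pre-leakage, pre-background) factor raster for one channel.
clean_factor_channel <- function(masks, expr_map, width, height) {
  img <- matrix(0, height, width)
  if (is.null(expr_map)) return(img)
  row <- matrix(seq_len(height), height, width)
  col <- matrix(seq_len(width), height, width, byrow = TRUE)
  for (comp in names(expr_map)) {
    mask <- masks[[comp]]
    if (is.null(mask)) {
      stop_field("compartment_expression",
                 sprintf("unknown compartment '%s'", comp))
    }
    if (!any(mask)) next
    e <- expr_map[[comp]]
    span <- e$gradient_span %||% 0
    if (span > 0) {
      th <- (e$gradient_direction %||% 0) * pi / 180
      proj <- cos(th) * col[mask] + sin(th) * row[mask]
      rng <- range(proj)
      t <- if (diff(rng) > 0) (proj - rng[1]) / diff(rng) else 0.5
      img[mask] <- e$mean - span / 2 + span * t
    } else {
      img[mask] <- e$mean
    }
  }
  matrix(pmin(255, pmax(0, round_half_up(img))), height, width)
}

# Paint DAPI-like nuclei (disks, radius 2 px) uniformly over tissue pixels.
draw_nuclei <- function(masks, density, width, height) {
  tissue <- !masks$background
  img <- matrix(0L, height, width)
  n <- round_half_up(density * sum(tissue) / 1000)
  centers <- matrix(integer(0), 0, 2)
  if (n > 0 && any(tissue)) {
    pick <- sample(which(tissue), n, replace = n > sum(tissue))
    cy <- (pick - 1L) %% height + 1L
    cx <- (pick - 1L) %/% height + 1L
    inten <- round_half_up(200 + stats::runif(n, -30, 30))
    for (k in seq_len(n)) {
      rows <- max(1L, cy[k] - 2L):min(height, cy[k] + 2L)
      cols <- max(1L, cx[k] - 2L):min(width, cx[k] + 2L)
      for (i in rows) for (j in cols) {
        if ((i - cy[k])^2 + (j - cx[k])^2 <= 4) {
          img[i, j] <- max(img[i, j], inten[k])
        }
      }
    }
    centers <- cbind(row = cy, col = cx)
  }
  list(img = img, centers = centers)
}

phantom_baseline <- 15L  # "expressed" threshold used for all ground truth

#' Generate a synthetic tooth-germ phantom
#'
#' Builds the clean compartment-restricted signal for each channel, then the
#' observed channels as
#' `clip(clean + leakage * clean_counterchannel + background + noise)`,
#' and records complete ground truth: compartment masks, per-channel
#' expression-domain fractions (percentage of pixels at or above the baseline
#' intensity 15 in the clean raster), and channel-pair co-localization
#' fractions. Deterministic for a fixed seed.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom` with elements `channels` (observed
#'   [gray8] images: `nuclear`, `green`, `red`), `clean` (noise-, leak- and
#'   background-free rasters), `compartment_masks`, `true_domain_fraction`
#'   (data.frame channel/compartment/fraction), `true_coloc_fraction`
#'   (data.frame pair/fraction; percentage of first-channel expressed pixels
#'   also expressed in the second), `nucleus_centers`, and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' subset(ph$true_domain_fraction, compartment == "whole_frame")
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  build_phantom(spec, negative_control = FALSE)
}

#' Negative-control phantom (primary antibodies omitted)
#'
#' Emulates the negative-control staining in which factor channels carry no
#' specific signal: only autofluorescent background, noise and a faint
#' bleed-through of the nuclear stain remain. The nuclear channel is unchanged
#' (the nuclear counterstain is not a primary antibody). Ground-truth domain
#' fractions for the factor channels are zero by construction.
#'
#' @inheritParams generate_phantom
#' @return a `phantom`, as for [generate_phantom()].
#' @export
negative_control_phantom <- function(spec) {
  validate_phantom_spec(spec)
  build_phantom(spec, negative_control = TRUE)
}

# Faint nuclear-stain bleed into factor channels of the negative control.
dapi_bleed_coef <- 0.05

build_phantom <- function(spec, negative_control) {
  masks <- phantom_geometry(spec$width, spec$height, spec$stage_label)
  withr::with_seed(spec$seed, {
    nuc <- draw_nuclei(masks, spec$nucleus_density, spec$width, spec$height)
    clean <- list(
      nuclear = nuc$img,
      green = clean_factor_channel(masks, spec$compartment_expression$green,
                                   spec$width, spec$height),
      red = clean_factor_channel(masks, spec$compartment_expression$red,
                                 spec$width, spec$height))
    if (negative_control) {
      clean$green <- matrix(0L, spec$height, spec$width)
      clean$red <- matrix(0L, spec$height, spec$width)
    }
    noise <- function() {
      if (spec$background_noise_sd > 0) {
        matrix(stats::rnorm(spec$height * spec$width,
                            sd = spec$background_noise_sd),
               spec$height, spec$width)
      } else 0
    }
    bleed <- if (negative_control) dapi_bleed_coef * clean$nuclear else 0
    obs_green <- clip8(clean$green + spec$leakage_red_to_green * clean$red +
                         bleed + spec$background_level + noise())
    obs_red <- clip8(clean$red + spec$leakage_green_to_red * clean$green +
                       bleed + spec$background_level + noise())
    obs_nuc <- clip8(clean$nuclear + spec$background_level + noise())
  })

  channels <- list(
    nuclear = gray8(obs_nuc, spec$pixel_size, "nuclear"),
    green = gray8(obs_green, spec$pixel_size, "green"),
    red = gray8(obs_red, spec$pixel_size, "red"))

  comps <- c(names(masks), "whole_frame")
  tdf <- do.call(rbind, lapply(names(clean), function(ch) {
    do.call(rbind, lapply(comps, function(comp) {
      m <- if (comp == "whole_frame") TRUE else masks[[comp]]
      npx <- if (comp == "whole_frame") spec$height * spec$width else sum(m)
      frac <- if (npx == 0) 0 else 100 * sum(clean[[ch]][m] >= phantom_baseline) / npx
      data.frame(channel = ch, compartment = comp, fraction = frac,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(tdf) <- NULL

  pair_frac <- function(a, b) {
    na <- sum(a >= phantom_baseline)
    if (na == 0) 0 else 100 * sum(a >= phantom_baseline & b >= phantom_baseline) / na
  }
  tcf <- data.frame(
    pair = c("green_red", "green_nuclear", "red_nuclear"),
    fraction = c(pair_frac(clean$green, clean$red),
                 pair_frac(clean$green, clean$nuclear),
                 pair_frac(clean$red, clean$nuclear)),
    stringsAsFactors = FALSE)

  structure(list(channels = channels, clean = clean,
                 compartment_masks = masks,
                 true_domain_fraction = tdf, true_coloc_fraction = tcf,
                 nucleus_centers = nuc$centers, spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d, stage '%s', seed %d\n",
              x$spec$height, x$spec$width, x$spec$stage_label, x$spec$seed))
  invisible(x)
}

#' Ground-truth expression-domain fraction of a phantom
#'
#' @param phantom a `phantom`.
#' @param channel `"green"`, `"red"` or `"nuclear"`.
#' @param compartment a compartment name or `"whole_frame"`.
#' @return fraction in percent.
#' @export
true_fraction <- function(phantom, channel, compartment = "whole_frame") {
  d <- phantom$true_domain_fraction
  v <- d$fraction[d$channel == channel & d$compartment == compartment]
  if (length(v) != 1L) stop_field("compartment", "no such ground-truth entry")
  v
}

#' Marker points in ground-truth-negative structures
#'
#' Samples positions known to carry no factor signal in the phantom's clean
#' rasters (nuclei and inter-nuclear/background space), for use as
#' verification markers in the dark-point background adjustment.
#'
#' @param phantom a `phantom`.
#' @param n number of points.
#' @param structures `"factor_negative"` samples positions with no factor
#'   signal (nuclei and background space), for verifying factor channels;
#'   `"internuclear"` samples positions outside nuclei, for verifying the
#'   nuclear channel.
#' @param seed seed for the sample; defaults to the phantom's own seed + 1.
#' @return a [marker_points()] set with `expected_negative = TRUE`.
#' @export
negative_marker_points <- function(phantom, n = 40L,
                                   structures = c("factor_negative",
                                                  "internuclear"),
                                   seed = NULL) {
  structures <- match.arg(structures)
  neg <- switch(structures,
    factor_negative = phantom$clean$green < phantom_baseline &
      phantom$clean$red < phantom_baseline,
    internuclear = phantom$clean$nuclear == 0L)
  idx <- which(neg)
  if (length(idx) == 0L) stop("phantom has no factor-negative pixels",
                              call. = FALSE)
  seed <- seed %||% (phantom$spec$seed + 1L)
  pick <- withr::with_seed(seed, sample(idx, min(n, length(idx))))
  h <- phantom$spec$height
  marker_points(cbind((pick - 1L) %% h + 1L, (pick - 1L) %/% h + 1L))
}

#' Write a phantom to disk
#'
#' Channels are written as per-channel 8-bit TIFFs, with a JSON sidecar
#' holding the spec, run-length-encoded compartment masks and the ground
#' truth tables.
#'
#' @param phantom a `phantom`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(phantom$channels)) {
    write_gray8(phantom$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  }
  sidecar <- list(
    spec = unclass(phantom$spec),
    masks = lapply(phantom$compartment_masks, rle_encode_mask),
    true_domain_fraction = phantom$true_domain_fraction,
    true_coloc_fraction = phantom$true_coloc_fraction)
  jsonlite::write_json(sidecar, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
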