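#' Image rendering configuration
#'
#' @param side Image side length in pixels (square, >= 32).
#' @param background Mean background intensity in `[0, 1]`.
#' @param texture_sd Sd of the smooth background texture.
#' @param noise_sd Sd of per-pixel additive Gaussian noise.
#' @param apex_contrast Intensity added to the apical band at the maximum
#'   severity of finding 1 (contrast scales linearly in normalised
#'   severity).
#' @param apex_fraction Fraction of top rows forming the apical band.
#' @param spine_contrast Intensity of the vertical spine ridge.
#' @param spine_width Half-width of the ridge in pixels.
#' @param curve_gain Lateral sinusoid amplitude per unit severity of
#'   finding 2, as a fraction of the side.
#' @param severity_scale Severity at which the apex contrast saturates.
#' @return A list of class `image_config`.
#' @export
image_config <- function(side = 64L, background = 0.35, texture_sd = 0.02,
                         noise_sd = 0.02, apex_contrast = 0.35,
                         apex_fraction = 0.15, spine_contrast = 0.3,
                         spine_width = 2L, curve_gain = 0.08,
                         severity_scale = 5) {
  stopifnot(side >= 32)
  structure(list(side = as.integer(side), background = background,
                 texture_sd = texture_sd, noise_sd = noise_sd,
                 apex_contrast = apex_contrast, apex_fraction = apex_fraction,
                 spine_contrast = spine_contrast,
                 spine_width = as.integer(spine_width),
                 curve_gain = curve_gain, severity_scale = severity_scale),
            class = "image_config")
}

# Rows forming the apical band of an image of the given side.
apex_rows <- function(config) seq_len(max(1L, floor(config$apex_fraction * config$side)))

#' Render toy grayscale screening images for synthetic subjects
#'
#' Produces one square grayscale matrix per subject: a smooth lung-field
#' background texture, plus a bright apical band (top `apex_fraction` of
#' rows) whose contrast is proportional to the finding-1 severity, and a
#' vertical spine ridge whose lateral position follows a sinusoid with
#' amplitude proportional to the finding-2 severity. These stand in for
#' the apical-cap and spinal-curvature appearances the two findings have
#' on real radiographs, localised so saliency checks are unambiguous.
#'
#' @param truth Tibble from [sample_subjects()]; severities are read per
#'   subject with finding order taken from the tibble.
#' @param config An [image_config()].
#' @param seed Integer seed.
#' @return Named list of `side x side` matrices in `[0, 1]` (row-major,
#'   origin top-left), one per subject.
#' @export
render_images <- function(truth, config = image_config(), seed = 1L) {
  stopifnot(inherits(config, "image_config"))
  wide <- truth |>
    dplyr::select("subject_id", "finding", "severity") |>
    tidyr::pivot_wider(names_from = "finding", values_from = "severity")
  findings <- setdiff(names(wide), "subject_id")
  stopifnot(length(findings) >= 1)
  s1 <- wide[[findings[[1L]]]]
  s2 <- if (length(findings) >= 2L) wide[[findings[[2L]]]] else numeric(nrow(wide))
  withr::with_seed(seed, {
    imgs <- purrr::map(seq_len(nrow(wide)), function(i) {
      render_one_image(s1[[i]], s2[[i]], config)
    })
  })
  stats::setNames(imgs, wide$subject_id)
}

render_one_image <- function(s1, s2, config) {
  n <- config$side
  img <- matrix(config$background, n, n)
  if (config$texture_sd > 0) {
    # coarse smooth texture: low-res noise upsampled bilinearly
    coarse <- matrix(stats::rnorm(64L, 0, config$texture_sd), 8L, 8L)
    img <- img + resize_bilinear(coarse, n)
  }
  sev1 <- min(1, max(0, s1 / config$severity_scale))
  img[apex_rows(config), ] <- img[apex_rows(config), ] +
    config$apex_contrast * sev1
  amp <- config$curve_gain * s2 * n
  rows <- seq_len(n)
  centre <- (n + 1) / 2 + amp * sin(2 * pi * rows / n)
  w <- config$spine_width
  for (r in rows) {
    cols <- pmax(1L, pmin(n, round(centre[[r]]) + (-w:w)))
    img[r, cols] <- img[r, cols] + config$spine_contrast
  }
  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
  }
  pmin(pmax(img, 0), 1)
}

# Bilinear resize of a matrix to side x side (used for textures and
# Grad-CAM upsampling).
resize_bilinear <- function(m, side) {
  nr <- nrow(m)
  nc <- ncol(m)
  # map output pixel centres onto input pixel-centre coordinates
  ry <- (seq_len(side) - 0.5) / side * nr + 0.5
  rx <- (seq_len(side) - 0.5) / side * nc + 0.5
  y0 <- pmin(pmax(floor(ry), 1), nr)
  x0 <- pmin(pmax(floor(rx), 1), nc)
  y1 <- pmin(y0 + 1, nr)
  x1 <- pmin(x0 + 1, nc)
  fy <- pmin(pmax(ry - y0, 0), 1)
  fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE]
  b <- m[y0, x1, drop = FALSE]
  c_ <- m[y1, x0, drop = FALSE]
  d <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, side, side)
  wx <- matrix(fx, side, side, byrow = TRUE)
  (1 - wy) * ((1 - wx) * a + wx * b) + wy * ((1 - wx) * c_ + wx * d)
}

#' Write grayscale images to 8-bit PNG files
#'
#' @param images Named list of matrices in `[0, 1]`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths, named `<subject_id>.png`.
#' @export
write_images <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(images), function(id) {
    path <- file.path(dir, paste0(id, ".png"))
    png::writePNG(images[[id]], path)
    path
  }, character(1))
  invisible(paths)
}

#' Read grayscale PNG images
#'
#' @param paths PNG file paths; names default to the file stem.
#' @return Named list of matrices in `[0, 1]` (first channel if RGB).
#' @export
read_images <- function(paths) {
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.png$", "", basename(paths))
  }
  lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img
  })
}
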