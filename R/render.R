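# Synthetic fluorescence rendering of filament networks, plus TIFF I/O and
# z-stack projection.
#
# Image convention: matrices are indexed [row, col] = [y, x]; the origin is
# the top-left pixel, x grows rightward (columns), y downward (rows), pixel
# centres at integer pixel coordinates. The world (um) origin is the image
# centre, so generated cells (centred on 0) land mid-frame. Orientation is
# the angle of (dx, dy) to the +x axis, folded to [0, 180).

#' Rendering configuration
#'
#' @param pixel_size_um Pixel pitch, um/px (`> 0`).
#' @param image_px Image extent `c(rows, cols)` in pixels.
#' @param psf_sigma_px Gaussian point-spread-function SD in pixels
#'   (0 disables blurring).
#' @param amplitude Peak signal of a filament, a.u.
#' @param background Constant background level, a.u.
#' @param gain Photon gain for Poisson shot noise (a.u. per photon;
#'   0 disables shot noise).
#' @param read_noise_sd Additive Gaussian read-noise SD, a.u. (0 disables).
#' @param bit_depth Quantisation depth used when writing TIFF files.
#' @return List of class `render_config`.
#' @export
render_config <- function(pixel_size_um = 0.15, image_px = c(440, 440),
                          psf_sigma_px = 1, amplitude = 200, background = 8,
                          gain = 0, read_noise_sd = 0, bit_depth = 16) {
  check_scalar_number(pixel_size_um, "pixel_size_um", 1e-6)
  check_scalar_number(psf_sigma_px, "psf_sigma_px", 0)
  check_scalar_number(gain, "gain", 0)
  check_scalar_number(read_noise_sd, "read_noise_sd", 0)
  structure(list(
    pixel_size_um = pixel_size_um, image_px = as.integer(image_px),
    psf_sigma_px = psf_sigma_px, amplitude = amplitude,
    background = background, gain = gain, read_noise_sd = read_noise_sd,
    bit_depth = as.integer(bit_depth)
  ), class = "render_config")
}

# world (um, centre origin) -> pixel coordinates (1-based, x=col, y=row)
world_to_px <- function(x_um, y_um, rc) {
  list(
    x = x_um / rc$pixel_size_um + (rc$image_px[2] + 1) / 2,
    y = y_um / rc$pixel_size_um + (rc$image_px[1] + 1) / 2
  )
}

#' Render a filament set as a synthetic fluorescence image
#'
#' Each filament is rasterised as an anti-aliased straight line of its
#' width (pixel coverage decays linearly over one pixel at the line edge),
#' the frame is convolved with a Gaussian PSF, and background plus optional
#' Poisson-Gaussian noise are added. Filaments extending beyond the frame
#' are clipped with a warning.
#'
#' @param filaments Filament tibble (`length_um`, `width_um`, `theta_deg`,
#'   `x_um`, `y_um`; world origin at image centre).
#' @param rc A [render_config()].
#' @param seed Integer seed for the noise draws (local RNG scope).
#' @return Numeric matrix (a.u.), rows = y, cols = x.
#' @export
render_cell <- function(filaments, rc = render_config(), seed = 1) {
  img <- matrix(0, rc$image_px[1], rc$image_px[2])
  df <- as_tibble(filaments)
  clipped <- FALSE
  half_diag_x <- (rc$image_px[2] - 1) / 2 * rc$pixel_size_um
  half_diag_y <- (rc$image_px[1] - 1) / 2 * rc$pixel_size_um
  for (i in seq_len(nrow(df))) {
    f <- df[i, ]
    ux <- cos(deg2rad(f$theta_deg))
    uy <- sin(deg2rad(f$theta_deg))
    ex <- c(f$x_um - ux * f$length_um / 2, f$x_um + ux * f$length_um / 2)
    ey <- c(f$y_um - uy * f$length_um / 2, f$y_um + uy * f$length_um / 2)
    if (any(abs(ex) > half_diag_x) || any(abs(ey) > half_diag_y)) {
      clipped <- TRUE
    }
    p1 <- world_to_px(ex[1], ey[1], rc)
    p2 <- world_to_px(ex[2], ey[2], rc)
    half_w_px <- f$width_um / 2 / rc$pixel_size_um
    img <- rasterize_segment(img, p1$x, p1$y, p2$x, p2$y, half_w_px)
  }
  if (clipped) {
    warn("Some filaments extend beyond the image frame; they were clipped.")
  }
  img <- img * rc$amplitude
  if (rc$psf_sigma_px > 0 && any(img > 0)) {
    img <- EBImage::gblur(img, sigma = rc$psf_sigma_px)
    img[img < 0] <- 0
  }
  img <- img + rc$background
  if (rc$gain > 0 || rc$read_noise_sd > 0) {
    img <- with_seed(seed, {
      out <- img
      if (rc$gain > 0) {
        out <- rpois(length(img), pmax(img, 0) / rc$gain) * rc$gain
        out <- matrix(out, nrow(img), ncol(img))
      }
      if (rc$read_noise_sd > 0) {
        out <- out + matrix(rnorm(length(img), 0, rc$read_noise_sd),
                            nrow(img), ncol(img))
      }
      out
    })
    img[img < 0] <- 0
  }
  img
}

# Accumulate (via per-pixel max) the coverage of one thick anti-aliased
# segment. Coverage = clamp(half_width + 0.5 - distance_to_segment, 0, 1).
rasterize_segment <- function(img, x1, y1, x2, y2, half_w_px) {
  pad <- ceiling(half_w_px + 1.5)
  cmin <- max(1L, floor(min(x1, x2)) - pad)
  cmax <- min(ncol(img), ceiling(max(x1, x2)) + pad)
  rmin <- max(1L, floor(min(y1, y2)) - pad)
  rmax <- min(nrow(img), ceiling(max(y1, y2)) + pad)
  if (cmin > cmax || rmin > rmax) {
    return(img)
  }
  cols <- cmin:cmax
  rows <- rmin:rmax
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  py <- matrix(rows, length(rows), length(cols))
  dx <- x2 - x1
  dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) {
    matrix(0, length(rows), length(cols))
  } else {
    pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  }
  d <- sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
  cov <- pmin(pmax(half_w_px + 0.5 - d, 0), 1)
  img[rows, cols] <- pmax(img[rows, cols], cov)
  img
}

#' Maximum intensity projection of an image stack
#'
#' Collapses a confocal z-stack to a single plane by taking each pixel's
#' maximum across planes.
#'
#' @param stack A 3D numeric array (rows x cols x planes), a list of
#'   matrices, or a single matrix (returned unchanged).
#' @return A 2D numeric matrix.
#' @export
max_intensity_projection <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) abort("Empty image stack.")
    stack <- simplify2array(stack)
  }
  if (is.matrix(stack)) {
    return(stack)
  }
  if (!is.array(stack) || length(dim(stack)) != 3L) {
    abort("`stack` must be a matrix, a 3D array, or a list of matrices.")
  }
  if (dim(stack)[3] == 0L) abort("Empty image stack.")
  apply(stack, c(1, 2), max)
}

#' Write an image (or stack) to TIFF
#'
#' Intensities are quantised to the configured bit depth and written as a
#' single- or multi-page TIFF.
#'
#' @param img Matrix, 3D array or list of matrices (a.u.).
#' @param path Output file path.
#' @param rc A [render_config()] (supplies `bit_depth`); intensities are
#'   scaled by `2^bit_depth - 1`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, rc = render_config()) {
  maxv <- 2^rc$bit_depth - 1
  norm <- function(m) {
    m <- round(pmin(pmax(m, 0), maxv)) / maxv
    m
  }
  pages <- if (is.list(img)) {
    lapply(img, norm)
  } else if (is.matrix(img)) {
    norm(img)
  } else {
    lapply(seq_len(dim(img)[3]), function(k) norm(img[, , k]))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = min(rc$bit_depth, 16L))
  invisible(path)
}

#' Read a single- or multi-page TIFF as an intensity stack
#'
#' @param path TIFF file path.
#' @param bit_depth Bit depth used to rescale the `[0, 1]` TIFF samples back
#'   to a.u. (default 16).
#' @return A matrix (single page) or 3D array (multi-page), in a.u.
#' @export
read_image_stack <- function(path, bit_depth = 16) {
  pages <- tiff::readTIFF(path, all = TRUE)
  maxv <- 2^bit_depth - 1
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # collapse RGB if present
    p * maxv
  })
  if (length(pages) == 1L) pages[[1]] else simplify2array(pages)
}
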