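#' Imaging geometry and noise specification
#'
#' Parameters of the synthetic microscope: sampling, point-spread function,
#' cell width, camera background and noise, and z-stack geometry (default
#' 125-nm sections, as in 3D-SIM stacks of septal rings).
#'
#' @param pixel_size_um lateral pixel size, micrometres per pixel.
#' @param psf_sigma_um Gaussian PSF sigma, micrometres.
#' @param cell_width_um cell width, micrometres.
#' @param background_level camera background, ADU.
#' @param noise_sd additive Gaussian noise sigma, ADU.
#' @param z_step_um z-section spacing, micrometres (default 0.125).
#' @param n_z number of z-sections (>= 1).
#' @param cell_intensity cytoplasmic signal added inside the cell mask, ADU
#'   (0 renders foci/rings only).
#' @param margin_um empty margin around the cell in the frame.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(pixel_size_um = 0.064, psf_sigma_um = 0.1,
                       cell_width_um = 1.0, background_level = 100,
                       noise_sd = 0, z_step_um = 0.125, n_z = 12L,
                       cell_intensity = 40, margin_um = 0.5) {
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  if (psf_sigma_um <= 0) stopf("psf_sigma_um must be > 0")
  if (n_z < 1) stopf("n_z must be >= 1")
  structure(list(pixel_size_um = pixel_size_um, psf_sigma_um = psf_sigma_um,
                 cell_width_um = cell_width_um,
                 background_level = background_level, noise_sd = noise_sd,
                 z_step_um = z_step_um, n_z = as.integer(n_z),
                 cell_intensity = cell_intensity, margin_um = margin_um),
            class = "image_spec")
}

#' Render a cell into a 2D fluorescence frame
#'
#' Draws a rod-shaped (capped-rectangle) cell of the observation's length
#' and width on a horizontal medial axis, renders each focus of the chosen
#' channel as a 2D Gaussian of width `psf_sigma_um` at its axial position,
#' optionally renders a septal ring as a transverse Gaussian band, then adds
#' the background level and (if `noise_sd > 0`) i.i.d. Gaussian noise.
#' The peak amplitude of a focus is its `intensity`, so its integrated
#' signal is `intensity * 2 * pi * (psf_sigma_um / pixel_size_um)^2`.
#'
#' @param cell a [cell_observation()]; foci must lie inside the cell
#'   (`|lateral_um| <= width/2`).
#' @param spec an [image_spec()].
#' @param channel which focus channel to render (default: first).
#' @param ring_intensity peak amplitude of the septal band, ADU.
#' @param seed optional integer seed (identical seed, identical image).
#' @return object of class `rendered_cell`: list with `image` (matrix,
#'   rows = y), `mask` (logical matrix, the ground-truth cell footprint),
#'   `cell`, `spec`, `channel`, and the axis geometry (`x0_px`, `x1_px`,
#'   `y0_px`, pixel coordinates of the medial axis endpoints).
#' @export
render_cell_image <- function(cell, spec, channel = NULL,
                              ring_intensity = 200, seed = NULL) {
  stopifnot(inherits(cell, "cell_observation"), inherits(spec, "image_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  px <- spec$pixel_size_um
  len <- cell$length_um
  wid <- cell$width_um
  nx <- ceiling((len + 2 * spec$margin_um) / px)
  ny <- ceiling((wid + 2 * spec$margin_um) / px)
  # pixel-centre coordinates in um
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  x_mid <- nx * px / 2
  y_mid <- ny * px / 2
  x0 <- x_mid - len / 2          # pole at axial fraction 0
  x1 <- x_mid + len / 2
  r <- wid / 2
  # capped rectangle: distance to the medial segment [x0 + r, x1 - r]
  ax <- pmin(pmax(xc, x0 + r), x1 - r)
  X <- matrix(xc, ny, nx, byrow = TRUE)
  AX <- matrix(ax, ny, nx, byrow = TRUE)
  Y <- matrix(yc, ny, nx)
  D <- sqrt((X - AX)^2 + (Y - y_mid)^2)
  mask <- D <= r
  img <- matrix(0, ny, nx)
  img[mask] <- spec$cell_intensity
  sig <- spec$psf_sigma_um
  foci <- if (is.null(channel)) {
    if (length(cell$foci)) cell$foci[[1]] else NULL
  } else cell$foci[[channel]]
  if (!is.null(foci) && nrow(foci)) {
    if (any(foci$frac < 0 | foci$frac > 1) ||
        any(abs(foci$lateral_um) > r)) {
      stopf("focus outside the cell body")
    }
    for (i in seq_len(nrow(foci))) {
      fx <- x0 + foci$frac[i] * len
      fy <- y_mid + foci$lateral_um[i]
      img <- img + foci$intensity[i] *
        exp(-((X - fx)^2 + (Y - fy)^2) / (2 * sig^2))
    }
  }
  if (!is.null(cell$ring)) {
    rx <- x0 + cell$ring$frac * len
    band <- ring_intensity * exp(-(X - rx)^2 / (2 * sig^2))
    band[!mask] <- 0
    img <- img + band
  }
  img <- img + spec$background_level
  if (spec$noise_sd > 0) {
    img <- img + matrix(rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
  }
  structure(list(image = img, mask = mask, cell = cell, spec = spec,
                 channel = channel,
                 x0_px = x0 / px + 0.5, x1_px = x1 / px + 0.5,
                 y0_px = y_mid / px + 0.5),
            class = "rendered_cell")
}

#' Render a septal ring into a z-stack
#'
#' Places an annulus of the stated diameter in the plane transverse to the
#' cell axis (the y-z plane), blurred by the PSF, and samples it into `n_z`
#' sections spaced `z_step_um` apart. Voxel intensity is
#' `peak * exp(-(x - x0)^2 / (2 s^2)) * exp(-(d - r)^2 / (2 s^2))` where
#' `d` is the in-plane distance from the ring centre, plus background and
#' optional noise. A zero diameter degenerates to a single blurred spot.
#'
#' @param diameter_um ring diameter, micrometres; must not exceed the cell
#'   width or the stack's vertical extent `n_z * z_step_um`.
#' @param spec an [image_spec()].
#' @param peak peak amplitude, ADU.
#' @param seed optional integer seed.
#' @return object of class `ring_stack`: list with `stack` (array
#'   `[y, x, z]`), `spec`, `diameter_um`.
#' @export
render_ring_zstack <- function(diameter_um, spec, peak = 400, seed = NULL) {
  stopifnot(inherits(spec, "image_spec"))
  if (diameter_um < 0) stopf("diameter_um must be >= 0")
  if (diameter_um > spec$cell_width_um) {
    stopf("ring diameter (%.2f um) exceeds cell width (%.2f um)",
          diameter_um, spec$cell_width_um)
  }
  if (diameter_um > spec$n_z * spec$z_step_um) {
    stopf("ring diameter (%.2f um) exceeds stack depth (%.3f um)",
          diameter_um, spec$n_z * spec$z_step_um)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  px <- spec$pixel_size_um
  sig <- spec$psf_sigma_um
  r <- diameter_um / 2
  ny <- ceiling((spec$cell_width_um + 2 * spec$margin_um) / px)
  nx <- ceiling((4 * sig + 2 * spec$margin_um) / px)
  nz <- spec$n_z
  yc <- (seq_len(ny) - 0.5) * px
  xc <- (seq_len(nx) - 0.5) * px
  zc <- (seq_len(nz) - 0.5) * spec$z_step_um
  y0 <- ny * px / 2
  x0 <- nx * px / 2
  z0 <- nz * spec$z_step_um / 2
  axial <- exp(-(xc - x0)^2 / (2 * sig^2))
  stack <- array(0, dim = c(ny, nx, nz))
  for (k in seq_len(nz)) {
    plane <- peak * exp(-(sqrt((yc - y0)^2 + (zc[k] - z0)^2) - r)^2 / (2 * sig^2))
    stack[, , k] <- outer(plane, axial)
  }
  stack <- stack + spec$background_level
  if (spec$noise_sd > 0) {
    stack <- stack + array(rnorm(length(stack), 0, spec$noise_sd), dim(stack))
  }
  structure(list(stack = stack, spec = spec, diameter_um = diameter_um),
            class = "ring_stack")
}

#' Write / read images as (multi-page) TIFF
#'
#' Images are scaled to the 16-bit range on disk; `read_stack_tiff` returns
#' them rescaled by the stored factor when given one.
#'
#' @param images a matrix, a list of matrices, or a 3D array `[y, x, z]`.
#' @param path output TIFF file.
#' @param scale full-scale value mapped to 16-bit white (default 65535, i.e.
#'   ADU stored directly).
#' @return `path` / list of matrices.
#' @export
write_stack_tiff <- function(images, path, scale = 65535) {
  if (is.array(images) && length(dim(images)) == 3) {
    images <- lapply(seq_len(dim(images)[3]), function(k) images[, , k])
  }
  if (is.matrix(images)) images <- list(images)
  images <- lapply(images, function(m) {
    m <- pmin(pmax(m / scale, 0), 1)
    m
  })
  tiff::writeTIFF(images, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * scale)
}
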