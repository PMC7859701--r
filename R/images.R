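#' Calibrated 2D fluorescence image
#'
#' Wraps an intensity matrix with its physical pixel size. Pixel coordinates
#' used throughout the package are 0-based and address pixel centres: the
#' pixel stored at matrix row `r`, column `c` has coordinates
#' `(x, y) = (c - 1, r - 1)` and physical position `(x, y) * pixel_size_um`.
#'
#' @param pixels numeric matrix of nonnegative finite intensities
#'   (rows = y, columns = x).
#' @param pixel_size_um physical side length of one pixel, in micrometres.
#' @param channel optional channel name.
#' @return An object of class `plane_image`.
#' @export
plane_image <- function(pixels, pixel_size_um, channel = "") {
  check_that(is.matrix(pixels) && is.numeric(pixels),
             "pixels must be a numeric matrix")
  check_that(all(is.finite(pixels)), "pixels must be finite")
  check_that(all(pixels >= 0), "pixels must be nonnegative")
  check_that(is.numeric(pixel_size_um) && length(pixel_size_um) == 1 &&
               is.finite(pixel_size_um) && pixel_size_um > 0,
             "pixel_size_um must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel = as.character(channel)),
            class = "plane_image")
}

#' Calibrated 3D fluorescence z-stack
#'
#' @param voxels numeric 3D array (y, x, z) of nonnegative intensities.
#' @param pixel_size_um lateral (x-y) pixel size in micrometres.
#' @param z_step_um axial slice spacing in micrometres.
#' @param channel optional channel name.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, pixel_size_um, z_step_um, channel = "") {
  check_that(is.array(voxels) && length(dim(voxels)) == 3,
             "voxels must be a 3D array")
  check_that(all(is.finite(voxels)) && all(voxels >= 0),
             "voxels must be finite and nonnegative")
  check_that(is.numeric(pixel_size_um) && pixel_size_um > 0,
             "pixel_size_um must be positive")
  check_that(is.numeric(z_step_um) && z_step_um > 0,
             "z_step_um must be positive")
  structure(list(voxels = voxels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel = as.character(channel)),
            class = "volume_stack")
}

#' @export
print.plane_image <- function(x, ...) {
  cat(sprintf("<plane_image%s> %d x %d px, %.4g um/px, range [%.4g, %.4g]\n",
              if (nzchar(x$channel)) paste0(" ", x$channel) else "",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<volume_stack%s> %d x %d px x %d slices, %.4g um/px, dz %.4g um\n",
    if (nzchar(x$channel)) paste0(" ", x$channel) else "",
    d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Maximum-intensity projection of a z-stack
#'
#' Per-pixel maximum over z, as used for measuring cilium and dendrite
#' lengths from projections of a pan-ciliary marker. Calibration is kept.
#'
#' @param stack a [volume_stack].
#' @return A [plane_image].
#' @export
max_projection <- function(stack) {
  check_that(inherits(stack, "volume_stack"), "stack must be a volume_stack")
  proj <- apply(stack$voxels, c(1, 2), max)
  plane_image(proj, stack$pixel_size_um, channel = stack$channel)
}

#' Resample a z-stack onto a finer axial step
#'
#' Linear interpolation along z onto `target_step_um`; the x-y raster is
#' untouched. Used to build 3D models at a finer modelling step (default in
#' the workflow: acquisition at 0.2 um, modelling at 0.1 um).
#'
#' @param stack a [volume_stack].
#' @param target_step_um desired axial step in micrometres.
#' @return A [volume_stack] with the new `z_step_um`.
#' @export
resample_z <- function(stack, target_step_um) {
  check_that(inherits(stack, "volume_stack"), "stack must be a volume_stack")
  check_that(is.numeric(target_step_um) && target_step_um > 0,
             "target_step_um must be positive")
  nz <- dim(stack$voxels)[3]
  if (nz == 1 && target_step_um < stack$z_step_um)
    stop("cannot resample a single-slice stack onto a finer step",
         call. = FALSE)
  z_old <- (seq_len(nz) - 1) * stack$z_step_um
  z_new <- seq(0, z_old[nz], by = target_step_um)
  d <- dim(stack$voxels)
  flat <- matrix(stack$voxels, nrow = d[1] * d[2], ncol = nz)
  # interpolation weights: each new slice is a convex combination of the
  # two bracketing acquired slices
  out <- matrix(0, nrow = d[1] * d[2], ncol = length(z_new))
  for (k in seq_along(z_new)) {
    i <- findInterval(z_new[k], z_old, rightmost.closed = TRUE)
    if (i >= nz) {
      out[, k] <- flat[, nz]
    } else {
      w <- (z_new[k] - z_old[i]) / (z_old[i + 1] - z_old[i])
      out[, k] <- (1 - w) * flat[, i] + w * flat[, i + 1]
    }
  }
  volume_stack(array(out, dim = c(d[1], d[2], length(z_new))),
               stack$pixel_size_um, target_step_um, channel = stack$channel)
}

# --- internal: separable Gaussian blur -------------------------------------

# kernel truncated at 4 sigma and renormalised, so convolution conserves mass
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- dnorm(seq(-h, h), sd = sigma)
  k / sum(k)
}

conv1_zero <- function(v, k) {
  if (length(k) == 1L) return(v * k)
  h <- (length(k) - 1L) %/% 2L
  convolve(c(rep(0, h), v, rep(0, h)), k, type = "filter")
}

blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- gaussian_kernel(sigma_px)
  m <- t(apply(m, 1, conv1_zero, k = k))   # along x (columns)
  apply(m, 2, conv1_zero, k = k)           # along y (rows)
}

blur_array <- function(a, sigma_xy_px, sigma_z_steps) {
  d <- dim(a)
  if (sigma_xy_px > 0) {
    for (k in seq_len(d[3])) a[, , k] <- blur_matrix(a[, , k], sigma_xy_px)
  }
  if (sigma_z_steps > 0 && d[3] > 1) {
    kz <- gaussian_kernel(sigma_z_steps)
    flat <- matrix(a, nrow = d[1] * d[2], ncol = d[3])
    flat <- t(apply(flat, 1, conv1_zero, k = kz))
    a <- array(flat, dim = d)
  }
  a
}
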