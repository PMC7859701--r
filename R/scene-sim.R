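#' Ground-truth parameters for a synthetic phasmid-cilium scene
#'
#' Defines everything the simulator needs to draw one phasmid cilium:
#' a transition zone (TZ) rendered as a hollow cylindrical shell of known
#' length, radius and axial structure, a pan-ciliary marker spanning the
#' TZ plus middle and distal axoneme segments, and an optional periciliary
#' leakage signal. Two modalities are supported, matching the two imaging
#' arms of the workflow:
#'
#' * `"widefield"`: 2D single focal plane, 0.08 um pixels (so 20 pixels
#'   span 1.6 um), default PSF FWHM 0.25 um (typical for a 1.40 NA oil
#'   objective at ~510 nm).
#' * `"superres"`: 3D z-stack, 26.7 nm pixels, PSF FWHM 148.6 nm, 0.2 um
#'   z-steps (confocal super-resolution acquisition settings).
#'
#' The axial TZ intensity is modulated as `1 - m*cos(2*pi*P*x/L)` so that
#' the `axial_peak_count` P cosine peaks all lie strictly inside the TZ
#' support and P is an exact ground truth for peak-count recovery; an
#' optional exponential proximal-to-distal decay with scale
#' `asymmetry_decay_um` produces proximally enriched distributions.
#'
#' @param seed integer seed; identical seeds and fields give bit-identical
#'   scenes.
#' @param modality `"widefield"` or `"superres"`.
#' @param tz_length_um TZ length (default 0.8 um).
#' @param tz_shell_radius_um shell radius (default 0.125 um: below
#'   wide-field resolution, resolvable at super-resolution).
#' @param tz_shell_thickness_um radial thickness of the shell (default
#'   0.06 um, a protein-layer-scale shell).
#' @param axial_peak_count integer >= 0; 0 disables axial modulation.
#' @param axial_modulation_depth modulation depth m in \[0, 1\] (default 0.5).
#' @param asymmetry_decay_um exponential decay length of the
#'   proximal-to-distal intensity fall-off, or `NULL` for a uniform axial
#'   envelope.
#' @param tz_amplitude TZ emission, photons per emitting pixel/voxel.
#' @param middle_segment_um,distal_segment_um axoneme segment lengths on
#'   the marker channel (defaults 3 um each).
#' @param marker_amplitude pan-ciliary marker emission (photons/pixel).
#' @param leakage_amplitude periciliary leakage emission along the cilium
#'   (photons/pixel; default 0).
#' @param background_level constant background (photons/pixel).
#' @param background_gradient linear background slope along the
#'   proximal-to-distal axis (photons/pixel per um).
#' @param psf_fwhm_um lateral Gaussian PSF full width at half maximum.
#' @param psf_axial_fwhm_um axial (z) PSF full width at half maximum for
#'   super-resolution stacks. The default equals the lateral FWHM: the
#'   stacks this simulator emulates are deconvolved before analysis, and
#'   deconvolution restores a near-isotropic effective PSF (raw confocal
#'   axial resolution is 2-3x worse; set this larger to emulate
#'   non-deconvolved data).
#' @param pixel_size_um lateral pixel size.
#' @param z_step_um axial step (super-resolution stacks only).
#' @param read_noise_sd Gaussian read noise standard deviation (photons).
#' @param poisson_noise apply Poisson photon noise (disable together with
#'   `read_noise_sd = 0` for noiseless scenes).
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(seed = 1L,
                        modality = c("widefield", "superres"),
                        tz_length_um = 0.8,
                        tz_shell_radius_um = 0.125,
                        tz_shell_thickness_um = 0.06,
                        axial_peak_count = 3L,
                        axial_modulation_depth = 0.5,
                        asymmetry_decay_um = NULL,
                        tz_amplitude = if (modality[1] == "widefield") 400 else 500,
                        middle_segment_um = 3,
                        distal_segment_um = 3,
                        marker_amplitude = 100,
                        leakage_amplitude = 0,
                        background_level = 10,
                        background_gradient = 0,
                        psf_fwhm_um = if (modality[1] == "widefield") 0.25 else 0.1486,
                        psf_axial_fwhm_um = psf_fwhm_um,
                        pixel_size_um = if (modality[1] == "widefield") 0.08 else 0.0267,
                        z_step_um = 0.2,
                        read_noise_sd = 2,
                        poisson_noise = TRUE) {
  modality <- match.arg(modality)
  pos <- function(v, name)
    check_that(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
               paste0(name, " must be a single positive number"))
  nneg <- function(v, name)
    check_that(is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0,
               paste0(name, " must be a single nonnegative number"))
  pos(tz_length_um, "tz_length_um")
  pos(tz_shell_radius_um, "tz_shell_radius_um")
  pos(tz_shell_thickness_um, "tz_shell_thickness_um")
  pos(middle_segment_um, "middle_segment_um")
  pos(distal_segment_um, "distal_segment_um")
  pos(psf_fwhm_um, "psf_fwhm_um")
  pos(psf_axial_fwhm_um, "psf_axial_fwhm_um")
  pos(pixel_size_um, "pixel_size_um")
  pos(z_step_um, "z_step_um")
  nneg(tz_amplitude, "tz_amplitude")
  nneg(marker_amplitude, "marker_amplitude")
  nneg(leakage_amplitude, "leakage_amplitude")
  nneg(background_level, "background_level")
  check_that(is.numeric(background_gradient) && is.finite(background_gradient),
             "background_gradient must be a finite number")
  nneg(read_noise_sd, "read_noise_sd")
  check_that(axial_peak_count >= 0 && axial_peak_count == round(axial_peak_count),
             "axial_peak_count must be a nonnegative integer")
  check_that(axial_modulation_depth >= 0 && axial_modulation_depth <= 1,
             "axial_modulation_depth must be in [0, 1]")
  if (!is.null(asymmetry_decay_um)) pos(asymmetry_decay_um, "asymmetry_decay_um")
  structure(list(
    seed = as.integer(seed), modality = modality,
    tz_length_um = tz_length_um,
    tz_shell_radius_um = tz_shell_radius_um,
    tz_shell_thickness_um = tz_shell_thickness_um,
    axial_peak_count = as.integer(axial_peak_count),
    axial_modulation_depth = axial_modulation_depth,
    asymmetry_decay_um = asymmetry_decay_um,
    tz_amplitude = tz_amplitude,
    middle_segment_um = middle_segment_um,
    distal_segment_um = distal_segment_um,
    marker_amplitude = marker_amplitude,
    leakage_amplitude = leakage_amplitude,
    background_level = background_level,
    background_gradient = background_gradient,
    psf_fwhm_um = psf_fwhm_um,
    psf_axial_fwhm_um = psf_axial_fwhm_um,
    pixel_size_um = pixel_size_um,
    z_step_um = z_step_um,
    read_noise_sd = read_noise_sd,
    poisson_noise = isTRUE(poisson_noise)), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %s, TZ %.2f um (r %.3f um), %d peaks, decay %s, seed %d\n",
    x$modality, x$tz_length_um, x$tz_shell_radius_um, x$axial_peak_count,
    if (is.null(x$asymmetry_decay_um)) "none"
    else sprintf("%.2f um", x$asymmetry_decay_um), x$seed))
  invisible(x)
}

# axial intensity envelope on [0, L] (x relative to the TZ proximal end)
axial_envelope <- function(truth, x) {
  e <- rep(1, length(x))
  if (truth$axial_peak_count > 0)
    e <- e - truth$axial_modulation_depth *
      cos(2 * pi * truth$axial_peak_count * x / truth$tz_length_um)
  if (!is.null(truth$asymmetry_decay_um))
    e <- e * exp(-x / truth$asymmetry_decay_um)
  pmax(e, 0)
}

apply_noise <- function(signal, truth) {
  if (truth$poisson_noise)
    signal[] <- rpois(length(signal), lambda = pmax(signal, 0))
  if (truth$read_noise_sd > 0)
    signal[] <- signal + rnorm(length(signal), sd = truth$read_noise_sd)
  pmax(signal, 0)
}

simulate_widefield <- function(truth) {
  px <- truth$pixel_size_um
  L <- truth$tz_length_um
  cilium_um <- L + truth$middle_segment_um + truth$distal_segment_um
  x0 <- 2.0                       # proximal TZ start; leaves room for the box
  tip <- x0 + cilium_um
  width_um <- tip + 2.0
  height_um <- 4.8
  nx <- round(width_um / px) + 1L
  ny <- round(height_um / px) + 1L
  xs <- (seq_len(nx) - 1) * px
  y0 <- (ny - 1) %/% 2 * px       # axis on an exact pixel row
  row0 <- round(y0 / px) + 1L
  tz_rows <- row0 + c(-1L, 1L) * round(truth$tz_shell_radius_um / px)

  blank <- matrix(0, ny, nx)
  tz <- blank
  # half-open pixel-centre interval: a segment of length L emits from
  # exactly L / px pixels, keeping the rendered length calibration exact
  in_tz <- xs >= x0 - 1e-9 & xs < x0 + L - 1e-9
  tz[tz_rows, in_tz] <- rep(truth$tz_amplitude *
                              axial_envelope(truth, xs[in_tz] - x0),
                            each = 2)
  in_cil <- xs >= x0 - 1e-9 & xs < tip - 1e-9
  marker <- blank
  marker[row0, in_cil] <- truth$marker_amplitude
  leak <- blank
  leak[row0, in_cil] <- truth$leakage_amplitude

  emission <- list(tz = tz, marker = marker, leakage = leak)
  sigma_px <- truth$psf_fwhm_um / (2 * sqrt(2 * log(2))) / px
  bg <- matrix(truth$background_level + truth$background_gradient * xs,
               ny, nx, byrow = TRUE)
  set.seed(truth$seed)
  channels <- lapply(emission, function(e)
    plane_image(apply_noise(blur_matrix(e, sigma_px) + bg, truth), px))
  for (nm in names(channels)) channels[[nm]]$channel <- nm

  list(channels = channels,
       layout = list(
         x0_um = x0, y0_um = y0, tip_um = tip,
         tz_center_px = c(x = (x0 + L / 2) / px, y = y0 / px),
         axis_row_px = y0 / px,
         emission_voxels = vapply(emission, function(e) sum(e > 0), 0),
         emission_totals = vapply(emission, sum, 0)))
}

simulate_superres <- function(truth) {
  px <- truth$pixel_size_um
  L <- truth$tz_length_um
  r <- truth$tz_shell_radius_um
  t2 <- truth$tz_shell_thickness_um / 2
  x0 <- 0.5
  width_um <- L + 1.0
  half_y <- r + t2 + 0.4
  nx <- round(width_um / px) + 1L
  ny <- 2L * round(half_y / px) + 1L
  nz <- 7L                         # acquisition slices at z_step_um
  k <- 8L                          # fine sub-steps per slice for rendering
  fine <- truth$z_step_um / k
  nzf <- (nz - 1L) * k + 1L
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  zf <- (seq_len(nzf) - 1) * fine
  y0 <- ys[(ny + 1) %/% 2]
  z0 <- (nz - 1L) * truth$z_step_um / 2   # central slice passes through the axis

  env <- numeric(nx)
  in_tz <- xs >= x0 - 1e-9 & xs < x0 + L - 1e-9
  env[in_tz] <- axial_envelope(truth, xs[in_tz] - x0)
  # radial shell occupancy in the (y, z) plane, shared by every x column;
  # 4x4 subsampling per cell antialiases the thin band so the rendered
  # emission density is uniform along the ring
  sub <- (seq_len(4) - 2.5) / 4
  occ_yz <- matrix(0, ny, nzf)
  for (sy in sub) for (sz in sub) {
    rad <- sqrt(outer((ys + sy * px - y0)^2, (zf + sz * fine - z0)^2, `+`))
    occ_yz <- occ_yz + (abs(rad - r) <= t2)
  }
  occ_yz <- occ_yz / 16
  tz <- array(0, c(ny, nx, nzf))
  for (izf in seq_len(nzf)) {
    rows <- which(occ_yz[, izf] > 0)
    if (length(rows))
      tz[rows, , izf] <- occ_yz[rows, izf] %o% (truth$tz_amplitude * env)
  }
  axis_row <- (ny + 1) %/% 2
  axis_zf <- which.min(abs(zf - z0))
  marker <- array(0, c(ny, nx, nzf))
  marker[axis_row, xs >= x0, axis_zf] <- truth$marker_amplitude
  leak <- array(0, c(ny, nx, nzf))
  leak[axis_row, xs >= x0, axis_zf] <- truth$leakage_amplitude

  emission <- list(tz = tz, marker = marker, leakage = leak)
  sigma_px <- truth$psf_fwhm_um / (2 * sqrt(2 * log(2))) / px
  sigma_zf <- truth$psf_axial_fwhm_um / (2 * sqrt(2 * log(2))) / fine
  bg <- truth$background_level + truth$background_gradient * xs
  set.seed(truth$seed)
  channels <- lapply(emission, function(e) {
    b <- blur_array(e, sigma_px, sigma_zf)
    # acquisition slices are optical sections: point samples of the blurred
    # object at the slice z positions (the PSF provides the sectioning)
    acq <- b[, , (seq_len(nz) - 1L) * k + 1L, drop = FALSE]
    acq <- acq + rep(matrix(bg, ny, nx, byrow = TRUE), nz)
    volume_stack(apply_noise(acq, truth), px, truth$z_step_um)
  })
  for (nm in names(channels)) channels[[nm]]$channel <- nm

  list(channels = channels,
       layout = list(
         x0_um = x0, y0_um = y0, z0_um = z0,
         tz_center_px = c(x = (x0 + L / 2) / px, y = y0 / px),
         axis_row_px = y0 / px,
         emission_voxels = vapply(emission, function(e) sum(e > 0), 0),
         emission_totals = vapply(emission, sum, 0)))
}

#' Simulate one synthetic phasmid-cilium scene
#'
#' Renders the TZ shell, pan-ciliary marker and leakage channels described
#' by a [scene_truth], convolves them with a mass-conserving separable
#' Gaussian PSF (kernel truncated at 4 sigma and renormalised), adds the
#' constant-plus-gradient background, then applies Poisson photon noise and
#' Gaussian read noise (negative values clipped at 0). The ground truth is
#' echoed unchanged, together with a scene layout (TZ position, axis row,
#' per-channel emitted photon totals and emitting-voxel counts) that plays
#' the role of the manual annotations a user would supply for real images.
#'
#' @param truth a [scene_truth].
#' @return An object of class `tz_scene`: a list with `channels` (named
#'   [plane_image] or [volume_stack] objects `tz`, `marker`, `leakage`),
#'   `truth`, and `layout`.
#' @export
simulate_phasmid_scene <- function(truth) {
  check_that(inherits(truth, "scene_truth"),
             "truth must be a scene_truth object")
  res <- if (truth$modality == "widefield") simulate_widefield(truth)
         else simulate_superres(truth)
  structure(list(channels = res$channels, truth = truth,
                 layout = res$layout), class = "tz_scene")
}

#' @export
print.tz_scene <- function(x, ...) {
  cat(sprintf("<tz_scene> %s, channels: %s\n", x$truth$modality,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Line-scan polyline along the simulated cilium axis
#'
#' Convenience accessor building the proximal-to-distal line a user would
#' draw through the TZ of a simulated scene, padded on both sides.
#'
#' @param scene a `tz_scene`.
#' @param pad_um padding before the TZ proximal end and after its distal
#'   end, in micrometres.
#' @return A [polyline] in pixel coordinates.
#' @export
scene_axis_line <- function(scene, pad_um = 1) {
  check_that(inherits(scene, "tz_scene"), "scene must be a tz_scene")
  px <- scene$truth$pixel_size_um
  x0 <- scene$layout$x0_um
  x1 <- x0 + scene$truth$tz_length_um
  y <- scene$layout$axis_row_px
  polyline(c((x0 - pad_um) / px, (x1 + pad_um) / px), c(y, y))
}
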