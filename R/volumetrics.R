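# modal intensity of a stack via a 256-bin histogram; robust background
# estimate for mostly-empty stacks
stack_mode <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = 257)
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-1] + breaks[-257]) / 2
  mids[which.max(tabulate(idx, nbins = 256))]
}

# largest 26-connected component of a logical 3D mask (BFS over voxels)
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  nb <- nb[rowSums(nb != 0) > 0, , drop = FALSE]
  comp <- 0L
  sizes <- integer(0)
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    lab[start] <- comp
    queue <- arrayInd(start, d)
    size <- 1L
    while (nrow(queue) > 0) {
      nxt <- NULL
      for (q in seq_len(nrow(queue))) {
        p <- queue[q, ]
        cand <- sweep(nb, 2, p, `+`)
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        if (!nrow(cand)) next
        hit <- mask[cand] & lab[cand] == 0L
        if (any(hit)) {
          sel <- cand[hit, , drop = FALSE]
          lab[sel] <- comp
          size <- size + nrow(sel)
          nxt <- rbind(nxt, sel)
        }
      }
      queue <- if (is.null(nxt)) matrix(0, 0, 3) else nxt
    }
    sizes[comp] <- size
  }
  if (comp == 0L) return(mask & FALSE)
  lab == which.max(sizes)
}

#' Segment the fluorescent TZ compartment from a z-stack
#'
#' Builds a 3D model of the fluorescent compartment: the stack is
#' resampled onto the modelling z-step (default 0.1 um), background is
#' estimated as the modal intensity, voxels at or above
#' `background + threshold_fraction * (max - background)` are kept, and
#' the mask is restricted to its largest 26-connected component (26
#' connectivity keeps thin shells connected). The compartment volume is
#' the voxel count times the voxel volume.
#'
#' @param stack a [volume_stack].
#' @param threshold_fraction fraction of the background-corrected dynamic
#'   range used as the surface threshold (default 0.5; the value is
#'   configurable and recorded in the result because the corresponding
#'   commercial surface-rendering settings are not standardised).
#' @param model_z_step_um z-step used for 3D modelling (default 0.1 um);
#'   the stack is linearly resampled onto it when coarser.
#' @return An object of class `compartment_model` with elements `mask`,
#'   `volume_um3`, `axial_profile` (background-subtracted intensity summed
#'   per axial position over the compartment's cross-sectional footprint,
#'   so discontinuous TZs keep all their axial peaks), `axial_peak_count`,
#'   `background`,
#'   `threshold`, `threshold_fraction` and the voxel calibration.
#' @export
segment_compartment <- function(stack, threshold_fraction = 0.5,
                                model_z_step_um = 0.1) {
  check_that(inherits(stack, "volume_stack"), "stack must be a volume_stack")
  check_that(threshold_fraction > 0 && threshold_fraction < 1,
             "threshold_fraction must be in (0, 1)")
  if (stack$z_step_um > model_z_step_um + 1e-12)
    stack <- resample_z(stack, model_z_step_um)
  v <- stack$voxels
  bg <- stack_mode(v)
  if (max(v) <= bg)
    stop("no compartment above threshold: stack maximum does not exceed ",
         "the background", call. = FALSE)
  thr <- bg + threshold_fraction * (max(v) - bg)
  mask_all <- v >= thr
  if (!any(mask_all))
    stop("no compartment above threshold", call. = FALSE)
  mask <- largest_component(mask_all)
  voxel_um3 <- stack$pixel_size_um^2 * stack$z_step_um
  # axial profile: background-subtracted intensity summed, per axial
  # position, over the compartment's cross-sectional (y, z) footprint
  # (union of all thresholded components). Masking per-voxel instead
  # would clip dim axial regions nonlinearly, and a discontinuous TZ
  # must still show all its axial peaks even though the volume is that
  # of the largest connected compartment.
  footprint <- apply(mask_all, c(1, 3), any)
  prof <- vapply(seq_len(dim(v)[2]), function(j)
    sum((v[, j, ] - bg)[footprint]), 0)
  structure(list(
    mask = mask,
    volume_um3 = sum(mask) * voxel_um3,
    axial_profile = intensity_profile(
      (seq_along(prof) - 1) * stack$pixel_size_um, prof),
    axial_peak_count = count_peaks(prof, 0.2),
    background = bg, threshold = thr,
    threshold_fraction = threshold_fraction,
    pixel_size_um = stack$pixel_size_um,
    z_step_um = stack$z_step_um), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf(
    "<compartment_model> volume %.4f um^3 (%d voxels), %d axial peaks, threshold %.3g\n",
    x$volume_um3, sum(x$mask), x$axial_peak_count, x$threshold))
  invisible(x)
}

# local maxima (plateaus collapsed to their midpoint) with topographic
# prominence; returns peak indices and prominences. Values are quantised
# to 1e-9 of the dynamic range first so float-noise plateaus do not split
# into spurious tied maxima.
peak_prominences <- function(v) {
  rng <- max(v) - min(v)
  if (rng > 0) v <- round((v - min(v)) / rng * 1e9) / 1e9 * rng + min(v)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  peaks <- integer(0)
  if (m >= 3) {
    for (i in 2:(m - 1)) {
      if (r$values[i] > r$values[i - 1] && r$values[i] > r$values[i + 1])
        peaks <- c(peaks, (starts[i] + ends[i]) %/% 2)
    }
  }
  if (!length(peaks)) return(list(peaks = integer(0), prominence = numeric(0)))
  prom <- vapply(peaks, function(p) {
    h <- v[p]
    left <- v[seq_len(p - 1)]
    hi <- which(left > h)
    lbase <- min(left[seq.int(if (length(hi)) max(hi) + 1 else 1, p - 1)])
    right <- v[seq.int(p + 1, length(v))]
    hi <- which(right > h)
    rbase <- min(right[seq_len(if (length(hi)) min(hi) - 1 else length(right))])
    h - max(lbase, rbase)
  }, 0)
  list(peaks = peaks, prominence = prom)
}

count_peaks <- function(v, prominence_fraction) {
  rng <- max(v) - min(v)
  if (rng <= 0) return(0L)
  pp <- peak_prominences(v)
  sum(pp$prominence >= prominence_fraction * rng)
}

#' Count axial intensity peaks
#'
#' Number of local maxima whose topographic prominence is at least
#' `prominence_fraction` times the dynamic range (max - min) of the
#' profile. Applied to the masked axial profile of a segmented TZ
#' compartment this reproduces the "number of peaks of axial signal"
#' phenotype score; the count is invariant to intensity rescaling. A flat
#' profile has 0 peaks.
#'
#' @param x a `compartment_model`, an [intensity_profile], or a numeric
#'   vector of axial intensities (at least 5 samples).
#' @param prominence_fraction prominence threshold as a fraction of the
#'   profile dynamic range (default 0.2).
#' @return Integer peak count.
#' @export
axial_peak_count <- function(x, prominence_fraction = 0.2) {
  check_that(prominence_fraction > 0 && prominence_fraction <= 1,
             "prominence_fraction must be in (0, 1]")
  v <- if (inherits(x, "compartment_model")) x$axial_profile$values
       else if (inherits(x, "intensity_profile")) x$values
       else if (is.numeric(x)) x
       else stop("x must be a compartment_model, intensity_profile or numeric",
                 call. = FALSE)
  check_that(length(v) >= 5, "axial profile needs at least 5 samples")
  count_peaks(v, prominence_fraction)
}

#' Hollow-core assessment of a TZ z-stack
#'
#' Measures whether the signal is excluded from the inner core of the TZ
#' (the shell-like super-resolution signature). Voxels are binned by
#' radial distance from the cilium axis; the radial intensity profile must
#' show an off-axis shell peak or, for solid signals, peak on the axis.
#' The returned ratio is the background-subtracted mean intensity in a
#' core cylinder (radius one third of the shell-peak radius) divided by
#' the mean in the shell annulus at the radial peak; ratios below 1
#' indicate a hollow core.
#'
#' @param stack a [volume_stack].
#' @param axis a [polyline] (x-y pixel coordinates) tracing the cilium
#'   axis; its axial z-position is taken as the intensity-weighted
#'   z-centroid of the stack.
#' @return Core-to-shell intensity ratio (nonnegative).
#' @export
hollowness <- function(stack, axis) {
  check_that(inherits(stack, "volume_stack"), "stack must be a volume_stack")
  check_that(inherits(axis, "polyline"), "axis must be a polyline")
  v <- stack$voxels
  d <- dim(v)
  bg <- stack_mode(v)
  sig <- v - bg
  px <- stack$pixel_size_um
  # axis as a straight 3D line: x-y from the polyline ends, z at the
  # intensity-weighted centroid
  zs <- (seq_len(d[3]) - 1) * stack$z_step_um
  w <- apply(pmax(sig, 0), 3, sum)
  zc <- if (sum(w) > 0) sum(w * zs) / sum(w) else mean(zs)
  p0 <- c(axis$x[1], axis$y[1]) * px
  p1 <- c(tail(axis$x, 1), tail(axis$y, 1)) * px
  dir <- p1 - p0
  dir <- dir / sqrt(sum(dir^2))
  yy <- ((seq_len(d[1]) - 1) * px)
  xx <- ((seq_len(d[2]) - 1) * px)
  # perpendicular distance of every voxel centre to the 3D axis line
  gx <- rep(xx, each = d[1])
  gy <- rep(yy, d[2])
  t_par <- (gx - p0[1]) * dir[1] + (gy - p0[2]) * dir[2]
  perp2_xy <- (gx - p0[1] - t_par * dir[1])^2 + (gy - p0[2] - t_par * dir[2])^2
  inside <- t_par >= 0 & t_par <= sqrt(sum((p1 - p0)^2))
  rad <- sqrt(outer(perp2_xy, (zs - zc)^2, `+`))   # (ny*nx) x nz
  vals <- matrix(sig, nrow = d[1] * d[2], ncol = d[3])[inside, , drop = FALSE]
  rad <- rad[inside, , drop = FALSE]
  r_max <- min(max(abs(c(yy - mean(yy)))), max(abs(zs - zc)) + stack$z_step_um)
  bins <- floor(rad / px)
  n_bins <- max(1, floor(r_max / px))
  prof <- vapply(seq_len(n_bins) - 1, function(b)
    mean(vals[bins == b]), 0)
  prof[is.nan(prof)] <- 0
  if (max(prof) <= 0 || (max(prof) - min(prof)) <= 1e-9 * max(abs(prof), 1))
    stop("no shell peak: radial intensity profile is degenerate",
         call. = FALSE)
  pk <- which.max(prof)
  if (pk == n_bins)
    stop("no shell peak: radial intensity profile is monotone increasing",
         call. = FALSE)
  r_peak <- pk - 1L    # bin index 0 = on-axis
  core_bins <- 0:max(0L, floor(r_peak / 3))
  shell_bins <- max(0L, r_peak - 1L):min(n_bins - 1L, r_peak + 1L)
  core <- mean(vals[bins %in% core_bins])
  shell <- mean(vals[bins %in% shell_bins])
  max(core / shell, 0)
}
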