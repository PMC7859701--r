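#' Integrated box intensity with local ring background subtraction
#'
#' Implements the TZ intensity measurement used for wide-field images: the
#' integrated signal in an inner box (default 40x40 px) centred on the TZ
#' pair, background-corrected using the one-pixel ring obtained by growing
#' the box by one pixel in each direction (42x42 px for the defaults). The
#' per-pixel background is the mean over the ring (164 pixels for the
#' defaults) and is subtracted from every inner-box pixel. Because the ring
#' is centre-symmetric about the box, the estimate is exactly unbiased under
#' constant and linear background gradients. Negative net values are
#' returned as-is, keeping group means unbiased.
#'
#' @param image a [plane_image].
#' @param center length-2 numeric `(x, y)` box centre in 0-based pixel
#'   coordinates.
#' @param inner_box_px side of the inner box in pixels (default 40).
#' @return Net (background-subtracted) integrated intensity; may be negative.
#' @export
integrated_box_intensity <- function(image, center, inner_box_px = 40L) {
  check_that(inherits(image, "plane_image"), "image must be a plane_image")
  check_that(length(center) == 2 && all(is.finite(center)),
             "center must be a finite (x, y) pair")
  check_that(inner_box_px >= 2, "inner_box_px must be >= 2")
  half <- inner_box_px / 2
  cx <- round(center[1]); cy <- round(center[2])
  # 0-based pixel index ranges; ring = outer box minus inner box
  xi <- (cx - ceiling(half) + 1):(cx + floor(half))
  yi <- (cy - ceiling(half) + 1):(cy + floor(half))
  xo <- (min(xi) - 1):(max(xi) + 1)
  yo <- (min(yi) - 1):(max(yi) + 1)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (min(xo) < 0 || max(xo) > nc - 1 || min(yo) < 0 || max(yo) > nr - 1)
    stop("box out of bounds: the outer box must lie fully inside the image",
         call. = FALSE)
  inner <- sum(image$pixels[yi + 1, xi + 1])
  outer <- sum(image$pixels[yo + 1, xo + 1])
  n_in <- length(xi) * length(yi)
  n_ring <- length(xo) * length(yo) - n_in
  inner - (outer - inner) / n_ring * n_in
}

#' Normalise measurements to a reference group
#'
#' Divides each value by the mean of the reference group (the "normalised
#' to WT" convention), optionally expressed as a percentage.
#'
#' @param values numeric measurements.
#' @param reference_values numeric reference-group measurements.
#' @param percent return percentages instead of fractions.
#' @param center reference summary to normalise by: `"mean"` (the
#'   convention used here) or `"median"`.
#' @return Normalised values.
#' @export
normalize_to_group <- function(values, reference_values, percent = FALSE,
                               center = c("mean", "median")) {
  center <- match.arg(center)
  check_that(length(reference_values) >= 1, "reference group is empty")
  ref <- if (center == "mean") mean(reference_values)
         else median(reference_values)
  check_that(is.finite(ref) && ref > 0,
             "reference group center must be positive")
  out <- values / ref
  if (percent) out * 100 else out
}

#' Allele-competition index
#'
#' Heterozygote TZ fluorescence expressed as a percentage of the tagged
#' homozygote reference: `100 * mean(het) / mean(homo)`. The homozygous
#' reference maps to 100% by construction; 50% indicates that tagged and
#' untagged alleles compete equally for TZ incorporation.
#'
#' @param het_net_intensities net TZ intensities of the heterozygous group.
#' @param homo_net_intensities net TZ intensities of the homozygous
#'   (tagged/tagged) reference group.
#' @return Relative fluorescence in percent.
#' @export
competition_index <- function(het_net_intensities, homo_net_intensities) {
  mean(normalize_to_group(het_net_intensities, homo_net_intensities,
                          percent = TRUE))
}

#' Ciliary leakage intensity of a periciliary marker
#'
#' Quantifies how much of a periciliary membrane protein has leaked into
#' the cilium proper. The image is sampled along the cilium trace and, at
#' each arc position, summed across a perpendicular window wide relative to
#' the PSF, giving a cross-section-integrated profile that is invariant to
#' lateral PSF blur (it recovers the emission line density of a uniform
#' in-cilium signal). Background is the mean of this profile over the
#' region at the far end of the trace beyond the ciliary tip (clear of
#' PSF smear from the tip itself), and the returned value is
#' the background-subtracted profile at a point (`window_um` of length 1,
#' the 4-um RPI-2 convention) or its mean over an interval (`window_um` of
#' length 2, the 2-4 um TRAM-1 convention).
#'
#' @param image a [plane_image] of the leakage channel.
#' @param cilium a [polyline] drawn from the ciliary base to beyond the tip.
#' @param window_um measurement position in micrometres from the base:
#'   a single value or an interval `c(from, to)`.
#' @param tip_um arc position of the ciliary tip in micrometres; samples
#'   beyond it define the background region.
#' @param tip_background_um length of the trace-end window used for
#'   background estimation (default 0.5 um); the trace must extend beyond
#'   the tip by at least this much.
#' @param width_px perpendicular summation window in pixels (default 25).
#' @return Net leakage intensity (cross-section-integrated counts per pixel
#'   of arc length); may be negative.
#' @export
leakage_intensity <- function(image, cilium, window_um, tip_um,
                              tip_background_um = 0.5, width_px = 25L) {
  check_that(inherits(image, "plane_image"), "image must be a plane_image")
  check_that(inherits(cilium, "polyline"), "cilium must be a polyline")
  check_that(length(window_um) %in% c(1L, 2L) && all(window_um > 0),
             "window_um must be one position or an interval of positions")
  check_that(tip_um > max(window_um),
             "measurement window must lie inside the cilium (before the tip)")
  arc_um <- sum(cilium$seg_lengths) * image$pixel_size_um
  if (arc_um < tip_um + tip_background_um)
    stop("cilium trace must extend beyond the tip by at least the ",
         "background window", call. = FALSE)
  prof <- extract_line_profile(image, cilium, width_px = width_px)
  sums <- prof$values * width_px   # cross-section integral per arc position
  pos <- prof$positions_um
  bg <- mean(sums[pos >= max(pos) - tip_background_um])
  net <- sums - bg
  if (length(window_um) == 1L) {
    approx(pos, net, window_um)$y
  } else {
    sel <- pos >= min(window_um) & pos <= max(window_um)
    check_that(any(sel), "no profile samples inside the measurement window")
    mean(net[sel])
  }
}
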