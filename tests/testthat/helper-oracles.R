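# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense-grid numerics, direct summation, and
# closed forms only.

# brute-force bilinear interpolation at one 0-based pixel-centre point
oracle_bilinear <- function(mat, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  mat[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
    mat[y0 + 1, x0 + 2] * fx * (1 - fy) +
    mat[y0 + 2, x0 + 1] * (1 - fx) * fy +
    mat[y0 + 2, x0 + 2] * fx * fy
}

# dense-grid crossing search for the FWHM of a function on [a, b]
oracle_fwhm_dense <- function(f, a, b, baseline = 0, n = 200001) {
  x <- seq(a, b, length.out = n)
  v <- f(x)
  half <- baseline + (max(v) - baseline) / 2
  above <- which(v >= half)
  x[max(above)] - x[min(above)]
}

# dense 1D convolution of an arbitrary emission function with a Gaussian
oracle_conv1 <- function(f, a, b, sigma, h = 0.001) {
  x <- seq(a, b, by = h)
  e <- f(x)
  half <- round(4 * sigma / h)
  k <- dnorm(seq(-half, half), sd = sigma / h)
  k <- k / sum(k)
  v <- stats::convolve(c(rep(0, half), e, rep(0, half)), k, type = "filter")
  list(x = x, v = v)
}

# Kruskal-Wallis H by direct rank arithmetic (tie-corrected)
oracle_kw_h <- function(groups) {
  all_v <- unlist(groups, use.names = FALSE)
  rk <- rank(all_v)
  N <- length(all_v)
  grp <- rep(seq_along(groups), vapply(groups, length, 0L))
  rbar <- tapply(rk, grp, mean)
  n <- tapply(rk, grp, length)
  H <- 12 / (N * (N + 1)) * sum(n * rbar^2) - 3 * (N + 1)
  ties <- table(all_v)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# continuous-space half-max volume of a PSF-blurred cylindrical shell:
# fine-grid 2D cross-section blur (independent of the package's raster
# and sampling code), times the length (a top-hat keeps its half-max
# length under symmetric blur)
oracle_shell_halfmax_volume <- function(radius, thickness, length_um,
                                        psf_fwhm, h = 0.004) {
  g <- seq(-(radius + thickness + 6 * psf_fwhm), radius + thickness + 6 * psf_fwhm,
           by = h)
  yy <- matrix(g, length(g), length(g))
  zz <- t(yy)
  ann <- (abs(sqrt(yy^2 + zz^2) - radius) <= thickness / 2) * 1
  sig <- psf_fwhm / (2 * sqrt(2 * log(2)))
  half <- round(4 * sig / h)
  k <- dnorm(seq(-half, half), sd = sig / h)
  k <- k / sum(k)
  pad_conv <- function(v) stats::convolve(c(rep(0, half), v, rep(0, half)),
                                          k, type = "filter")
  b <- apply(apply(ann, 2, pad_conv), 1, pad_conv)
  sum(b >= max(b) / 2) * h^2 * length_um
}

# noiseless widefield truth with every stochastic element switched off
noiseless_truth <- function(...) {
  scene_truth(poisson_noise = FALSE, read_noise_sd = 0, ...)
}

# uniform-envelope TZ (no modulation, no decay)
uniform_truth <- function(...) {
  noiseless_truth(axial_peak_count = 0, ...)
}
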