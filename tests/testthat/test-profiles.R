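make_profile <- function(f, from = 0, to = 4, step = 0.02) {
  x <- seq(from, to, by = step)
  intensity_profile(x - x[1], f(x))
}

test_that("line profiles sample by bilinear interpolation", {
  img <- plane_image(matrix(3.7, 30, 30), 0.08)
  line <- polyline(c(2, 20), c(15, 15))
  prof <- extract_line_profile(img, line)
  expect_true(all(prof$values == 3.7))
  expect_equal(prof$positions_um[1], 0)
  expect_equal(prof$step_um, 0.08)

  # single bright column crossed perpendicularly: values match the
  # brute-force bilinear oracle at off-grid sample points
  m <- matrix(0, 20, 20)
  m[, 10] <- 100
  img <- plane_image(m, 0.08)
  line <- polyline(c(5.3, 13.3), c(8.6, 8.6))
  prof <- extract_line_profile(img, line)
  for (i in seq_along(prof$values)) {
    x <- 5.3 + (i - 1)
    expect_equal(prof$values[i], oracle_bilinear(m, x, 8.6))
  }

  expect_error(extract_line_profile(img, polyline(c(15, 25), c(5, 5))),
               "exits the image")
})

test_that("a 1.6 um wide-field scan has 20 samples", {
  img <- plane_image(matrix(1, 40, 40), 0.08)
  prof <- extract_line_profile(img, polyline(c(5, 35), c(20, 20)),
                               length_um = 1.6)
  expect_length(prof$values, 20)
})

test_that("noiseless scene line scan matches the 1D convolution oracle", {
  tr <- uniform_truth(seed = 1, modality = "widefield")
  sc <- simulate_phasmid_scene(tr)
  prof <- extract_line_profile(sc$channels$tz, scene_axis_line(sc))

  # oracle: axial top-hat emission convolved with the PSF on a dense grid,
  # scaled by the perpendicular response of the two shell rows, plus bg
  px <- tr$pixel_size_um
  sigma <- tr$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  x0 <- sc$layout$x0_um
  # the rasterised emission occupies pixel centres on [x0, x0 + L), whose
  # continuous equivalent is a top-hat of exactly the true length,
  # shifted proximally by half a pixel
  o <- oracle_conv1(function(x)
    (x >= x0 - px / 2 & x < x0 + tr$tz_length_um - px / 2) * 1,
    x0 - 1.2, x0 + tr$tz_length_um + 1.2, sigma)
  dy_px <- round(tr$tz_shell_radius_um / px)
  ky <- dnorm(seq(-20, 20), sd = sigma / px)
  ky <- ky / sum(ky)
  perp <- 2 * ky[21 + dy_px]
  pred <- tr$tz_amplitude * perp *
    approx(o$x, o$v, prof$positions_um + (x0 - 1), rule = 2)$y +
    tr$background_level
  rms <- sqrt(mean((prof$values - pred)^2)) / max(pred)
  expect_lt(rms, 0.01)
})

test_that("FWHM matches closed forms and is scale invariant", {
  # top-hat of width 0.8 um
  top <- make_profile(function(x) as.numeric(x >= 0.4 & x <= 1.2),
                      to = 1.6, step = 0.02)
  expect_equal(fwhm_length(top, baseline = 0), 0.8, tolerance = 0.03)

  # Gaussian: FWHM = 2 sqrt(2 log 2) sigma, checked against a dense
  # crossing-search oracle
  f <- function(x) exp(-(x - 2)^2 / (2 * 0.34^2))
  g <- make_profile(f)
  expected <- oracle_fwhm_dense(f, 0, 4)
  expect_equal(expected, 2 * sqrt(2 * log(2)) * 0.34, tolerance = 1e-4)
  expect_equal(fwhm_length(g, baseline = 0), expected, tolerance = 0.01)

  # positive rescaling leaves the FWHM unchanged
  g7 <- intensity_profile(g$positions_um, 7.3 * g$values)
  expect_equal(fwhm_length(g7, baseline = 0), fwhm_length(g, baseline = 0))

  # affine rescaling with identically rescaled baseline too
  ga <- intensity_profile(g$positions_um, 5 + 2 * g$values)
  expect_equal(fwhm_length(ga, baseline = 5), fwhm_length(g, baseline = 0))
})

test_that("FWHM rejects flat and truncated profiles", {
  flat <- intensity_profile(seq(0, 1, by = 0.1), rep(2, 11))
  expect_error(fwhm_length(flat, baseline = 2), "no signal above baseline")
  ramp <- make_profile(function(x) x, to = 2)
  expect_error(fwhm_length(ramp, baseline = 0), "truncated")
})

test_that("asymmetry index quantifies proximal enrichment", {
  # symmetric profiles sit at 0.5
  gauss <- make_profile(function(x) exp(-(x - 2)^2 / 0.18))
  expect_equal(asymmetry_index(gauss), 0.5, tolerance = 0.01)

  # right triangle falling from its proximal support edge: the proximal
  # half of the half-max window holds 7/12 of the windowed signal
  # (direct-integration oracle: window [0, W/2], split at W/4,
  # integral of (1 - x/W))
  tri <- make_profile(function(x) pmax(1 - (x - 1) / 2, 0) * (x >= 1),
                      to = 4, step = 0.01)
  w_frac <- function(a, b) (b - a) - (b^2 - a^2) / (2 * 2)
  oracle <- w_frac(0, 0.5) / w_frac(0, 1)
  expect_equal(oracle, 7 / 12)
  expect_equal(asymmetry_index(tri, baseline = 0), oracle, tolerance = 0.02)

  # essentially all mass in the proximal quarter of the window scores
  # > 0.9: a tall proximal block plus a faint distal marker that keeps
  # the outermost half-max crossings (and hence the window) wide
  blocky <- make_profile(function(x)
    as.numeric(x >= 1 & x <= 1.475) +
      0.01 * as.numeric(x > 1.475 & x < 2.9) +
      0.6 * as.numeric(x >= 2.9 & x <= 2.95),
    to = 4, step = 0.005)
  expect_gt(asymmetry_index(blocky, baseline = 0), 0.9)

  # mirroring a profile mirrors the index around 0.5
  asym <- make_profile(function(x) pmax(1 - abs(x - 1.6) / 0.6, 0)^2 *
                         (1 + 0.8 * (x < 1.6)), to = 4, step = 0.01)
  mirr <- intensity_profile(asym$positions_um, rev(asym$values))
  expect_equal(asymmetry_index(asym) + asymmetry_index(mirr), 1,
               tolerance = 1e-4)
})

test_that("group axial distributions align, average and normalise", {
  f <- function(x) exp(-(x - 1.7)^2 / 0.08)
  p1 <- make_profile(f)
  same <- mean_axial_distribution(list(p1, p1, p1))
  expect_true(all(same$sd == 0))
  expect_equal(max(same$mean), max(p1$values), tolerance = 1e-6)

  # self-normalisation sets the peak of the group mean to 1
  norm <- mean_axial_distribution(list(p1, p1),
                                  reference_profiles = list(p1, p1))
  expect_equal(max(norm$mean), 1, tolerance = 1e-9)

  # alignment at the proximal half-max crossing collapses shifted copies
  g <- function(sh) make_profile(function(x) f(x - sh))
  shifted <- mean_axial_distribution(list(g(0), g(0.3), g(-0.2)))
  expect_lt(max(shifted$sd), 0.02 * max(shifted$mean))

  p_coarse <- intensity_profile(seq(0, 4, by = 0.1),
                                f(seq(0, 4, by = 0.1)))
  expect_error(mean_axial_distribution(list(p1, p_coarse)), "mixed sampling")
})
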