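test_that("scene parameters are validated with messages naming the field", {
  expect_error(scene_truth(tz_amplitude = -1), "tz_amplitude")
  expect_error(scene_truth(pixel_size_um = 0), "pixel_size_um")
  expect_error(scene_truth(psf_fwhm_um = -0.1), "psf_fwhm_um")
  expect_error(scene_truth(axial_peak_count = 2.5), "axial_peak_count")
  expect_error(scene_truth(asymmetry_decay_um = 0), "asymmetry_decay_um")
})

test_that("modality defaults match the acquisition calibrations", {
  wf <- scene_truth(modality = "widefield")
  expect_equal(wf$pixel_size_um, 0.08)       # 20 px span 1.6 um
  expect_equal(20 * wf$pixel_size_um, 1.6)
  sr <- scene_truth(modality = "superres")
  expect_equal(sr$pixel_size_um, 0.0267)
  expect_equal(sr$psf_fwhm_um, 0.1486)
  expect_equal(sr$z_step_um, 0.2)
  expect_equal(sr$tz_length_um, 0.8)
  expect_equal(sr$middle_segment_um, 3)
})

test_that("a zero-amplitude noiseless scene is exactly the background plane", {
  tr <- uniform_truth(seed = 1, modality = "widefield", tz_amplitude = 0,
                      marker_amplitude = 0, background_level = 5,
                      background_gradient = 0)
  sc <- simulate_phasmid_scene(tr)
  expect_true(all(sc$channels$tz$pixels == 5))
  expect_true(all(sc$channels$marker$pixels == 5))

  # with a gradient, every pixel sits exactly on the background plane
  trg <- uniform_truth(seed = 1, modality = "widefield", tz_amplitude = 0,
                       marker_amplitude = 0, background_level = 5,
                       background_gradient = 2)
  scg <- simulate_phasmid_scene(trg)
  xs <- (seq_len(ncol(scg$channels$tz$pixels)) - 1) * 0.08
  expect_equal(scg$channels$tz$pixels,
               matrix(5 + 2 * xs, nrow(scg$channels$tz$pixels),
                      ncol(scg$channels$tz$pixels), byrow = TRUE))
})

test_that("noiseless TZ FWHM equals the truth up to the PSF bound", {
  tr <- uniform_truth(seed = 1, modality = "widefield")
  sc <- simulate_phasmid_scene(tr)
  prof <- extract_line_profile(sc$channels$tz, scene_axis_line(sc))
  measured <- fwhm_length(prof)

  # independent 1D oracle: top-hat of the true length convolved with the
  # PSF, FWHM by dense crossing search
  sigma <- tr$psf_fwhm_um / (2 * sqrt(2 * log(2)))
  o <- oracle_conv1(function(x) as.numeric(x >= 1 & x <= 1 + tr$tz_length_um),
                    0, 3, sigma)
  fw_oracle <- {
    half <- max(o$v) / 2
    idx <- which(o$v >= half)
    o$x[max(idx)] - o$x[min(idx)]
  }
  expect_equal(measured, fw_oracle, tolerance = 0.08 / fw_oracle)
  # broadening never shrinks the top-hat and stays under one PSF FWHM
  expect_gte(measured + 0.08, tr$tz_length_um)
  expect_lt(measured, tr$tz_length_um + tr$psf_fwhm_um)
})

test_that("super-res axial modulation yields exactly the true peak count", {
  tr <- noiseless_truth(seed = 2, modality = "superres",
                        axial_peak_count = 3)
  sc <- simulate_phasmid_scene(tr)
  cm <- segment_compartment(sc$channels$tz)
  expect_identical(cm$axial_peak_count, 3L)

  # closed-form check: the emission envelope 1 - m cos(2 pi P x / L) has
  # exactly P interior maxima on (0, L)
  x <- seq(0, 0.8, by = 1e-4)[-1]
  env <- 1 - 0.5 * cos(2 * pi * 3 * x / 0.8)
  interior_max <- sum(diff(sign(diff(env))) == -2)
  expect_identical(interior_max, 3L)
})

test_that("scenes are bit-identical for identical seeds and parameters", {
  a <- simulate_phasmid_scene(scene_truth(seed = 42, modality = "widefield"))
  b <- simulate_phasmid_scene(scene_truth(seed = 42, modality = "widefield"))
  expect_identical(a$channels$tz$pixels, b$channels$tz$pixels)
  expect_identical(a$channels$marker$pixels, b$channels$marker$pixels)
  c <- simulate_phasmid_scene(scene_truth(seed = 43, modality = "widefield"))
  expect_false(identical(a$channels$tz$pixels, c$channels$tz$pixels))

  ca <- simulate_behavior_cohort(behavior_sim_params(30, seed = 9,
                                                     escape_rate = 0.2))
  cb <- simulate_behavior_cohort(behavior_sim_params(30, seed = 9,
                                                     escape_rate = 0.2))
  expect_identical(ca, cb)
})

test_that("PSF convolution conserves photons in background-free channels", {
  for (peaks in c(0L, 3L)) {
    tr <- noiseless_truth(seed = 1, modality = "widefield",
                          axial_peak_count = peaks, background_level = 0,
                          marker_amplitude = 0)
    sc <- simulate_phasmid_scene(tr)
    total <- sum(sc$channels$tz$pixels)
    expect_equal(total, sc$layout$emission_totals[["tz"]],
                 tolerance = 1e-3)
  }
  # uniform envelope: total = amplitude x emitting-pixel count
  tr <- uniform_truth(seed = 1, modality = "widefield",
                      background_level = 0)
  sc <- simulate_phasmid_scene(tr)
  expect_equal(sum(sc$channels$tz$pixels),
               tr$tz_amplitude * sc$layout$emission_voxels[["tz"]],
               tolerance = 1e-3)
})

test_that("asymmetry rises monotonically as the proximal decay sharpens", {
  ladder <- list(NULL, 2, 1, 0.5)
  idx <- vapply(ladder, function(d) {
    tr <- uniform_truth(seed = 3, modality = "widefield",
                        asymmetry_decay_um = d)
    measure_tz_widefield(simulate_phasmid_scene(tr))$asymmetry_index
  }, 0)
  expect_equal(idx[1], 0.5, tolerance = 0.02)  # uniform TZ is symmetric
  expect_true(all(diff(idx) > 0))
})

test_that("truth is echoed unchanged in the scene", {
  tr <- scene_truth(seed = 77, modality = "widefield", tz_amplitude = 123)
  sc <- simulate_phasmid_scene(tr)
  expect_identical(sc$truth, tr)
})
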