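solid_cuboid_stack <- function() {
  a <- array(0, c(20, 24, 9))
  a[6:15, 8:17, 3:7] <- 50        # 10 x 10 x 5 voxels at uniform amplitude
  volume_stack(a, 0.1, 0.1)
}

test_that("a noiseless solid cuboid is segmented exactly", {
  stk <- solid_cuboid_stack()
  cm <- segment_compartment(stk, 0.5)
  expect_equal(sum(cm$mask), 500)
  expect_equal(cm$volume_um3, 500 * 0.1 * 0.1 * 0.1)
})

test_that("segmentation keeps only the largest connected component", {
  a <- array(0, c(12, 30, 6))
  a[2:6, 2:10, 2:4] <- 30         # large blob
  a[9:11, 20:24, 2:3] <- 30       # smaller disjoint blob
  cm <- segment_compartment(volume_stack(a, 0.1, 0.1), 0.5)
  expect_equal(sum(cm$mask), 5 * 9 * 3)
  expect_true(all(which(cm$mask, arr.ind = TRUE)[, 1] <= 6))
})

test_that("volume is monotone non-increasing in the threshold", {
  tr <- noiseless_truth(seed = 3, modality = "superres",
                        axial_peak_count = 0)
  stk <- simulate_phasmid_scene(tr)$channels$tz
  vols <- vapply(c(0.3, 0.5, 0.7),
                 function(f) segment_compartment(stk, f)$volume_um3, 0)
  expect_true(all(diff(vols) <= 0))
})

test_that("segmentation rejects empty stacks", {
  flat <- volume_stack(array(7, c(6, 6, 6)), 0.1, 0.1)
  expect_error(segment_compartment(flat), "no compartment above threshold")
})

test_that("peak counting uses prominence and ignores intensity scale", {
  expect_equal(axial_peak_count(rep(1, 10)), 0)
  v <- 10 + 5 * sin(seq(0, 6 * pi, length.out = 120))  # 3 full bumps
  expect_equal(axial_peak_count(v), 3)
  expect_equal(axial_peak_count(1000 * v), 3)
  # shallow ripple below the prominence threshold is not counted
  w <- c(seq(0, 10, length.out = 40), 9.7, 9.9, 9.6,
         seq(9.5, 0, length.out = 40))
  expect_equal(axial_peak_count(w, prominence_fraction = 0.2), 1)
  expect_error(axial_peak_count(c(1, 2, 1)), "at least 5")
})

test_that("simulated axial peak counts are recovered from the model", {
  for (p in c(2L, 3L)) {
    tr <- noiseless_truth(seed = p, modality = "superres",
                          axial_peak_count = p)
    cm <- segment_compartment(simulate_phasmid_scene(tr)$channels$tz)
    expect_identical(cm$axial_peak_count, p)
  }
  # 4 peaks over 0.8 um put the 0.2 um modulation period at the optical
  # resolution limit: at the default modulation depth the blurred ripple
  # falls below the 20% prominence criterion, at full depth it is counted
  tr4 <- noiseless_truth(seed = 4, modality = "superres",
                         axial_peak_count = 4, axial_modulation_depth = 1)
  cm4 <- segment_compartment(simulate_phasmid_scene(tr4)$channels$tz)
  expect_identical(cm4$axial_peak_count, 4L)
})

test_that("hollowness separates shells from solid signals", {
  # directly constructed ideal stacks (no PSF): voxel grid with a shell
  # annulus vs a filled cylinder, plus constant background
  build <- function(hollow) {
    ny <- 41; nx <- 40; nz <- 9
    a <- array(10, c(ny, nx, nz))
    y0 <- 21; z0 <- 5
    for (iz in 1:nz) for (iy in 1:ny) {
      r_um <- sqrt(((iy - y0) * 0.0267)^2 + ((iz - z0) * 0.1)^2)
      inside <- if (hollow) abs(r_um - 0.3) <= 0.06 else r_um <= 0.36
      if (inside) a[iy, 8:33, iz] <- a[iy, 8:33, iz] + 200
    }
    volume_stack(a, 0.0267, 0.1)
  }
  axis <- polyline(c(8, 33), c(20, 20))
  expect_lt(hollowness(build(TRUE), axis), 0.2)
  expect_equal(hollowness(build(FALSE), axis), 1, tolerance = 0.1)

  flat <- volume_stack(array(10, c(41, 40, 9)), 0.0267, 0.1)
  expect_error(hollowness(flat, axis), "no shell peak")
})

test_that("simulated shells read as hollow at super-resolution", {
  tr <- noiseless_truth(seed = 6, modality = "superres",
                        axial_peak_count = 0)
  sc <- simulate_phasmid_scene(tr)
  px <- tr$pixel_size_um
  axis <- polyline(c(sc$layout$x0_um / px,
                     (sc$layout$x0_um + tr$tz_length_um) / px),
                   rep(sc$layout$axis_row_px, 2))
  h <- hollowness(sc$channels$tz, axis)
  expect_lt(h, 1)
})

test_that("WT-like vs G155S-like scenes show the qualitative signature", {
  # lower volume, fewer axial peaks, and a core shifted towards filled
  n_rep <- 10
  hits <- 0
  for (i in seq_len(n_rep)) {
    mw <- measure_tz_superres(simulate_phasmid_scene(
      condition_truth("wt", "superres", seed = 300 + i)))
    mg <- measure_tz_superres(simulate_phasmid_scene(
      condition_truth("g155s", "superres", seed = 600 + i)))
    ok <- mg$volume_um3 < mw$volume_um3 &&
      mg$peak_count < mw$peak_count
    hits <- hits + ok
  }
  expect_gte(hits / n_rep, 0.8)
})
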