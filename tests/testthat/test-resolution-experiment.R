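test_that("overlap metric is 100 for identical and 0 for disjoint profiles", {
  a <- psf_profile(0.5, 0.2)
  expect_equal(as.numeric(overlap_percent(a, a)), 100, tolerance = 1e-9)
  d <- seq(0, 1, length.out = 101)
  left <- depth_profile(ifelse(d < 0.4, 1, 0), depths = d)
  right <- depth_profile(ifelse(d > 0.6, 1, 0), depths = d)
  expect_equal(as.numeric(overlap_percent(left, right)), 0)
  expect_error(overlap_percent(a, depth_profile(c(1, NA, 1))), "missing bins")
})

test_that("overlap is symmetric, scale-invariant and clips negative lobes", {
  d <- seq(0, 1, length.out = 201)
  a <- depth_profile(exp(-(d - 0.45)^2 / 0.01), depths = d)
  b <- depth_profile(exp(-(d - 0.6)^2 / 0.02), depths = d)
  o_ab <- as.numeric(overlap_percent(a, b))
  o_ba <- as.numeric(overlap_percent(b, a))
  expect_equal(o_ab, o_ba, tolerance = 1e-9)
  b5 <- depth_profile(5 * b$values, depths = d)
  expect_equal(as.numeric(overlap_percent(a, b5)), o_ab, tolerance = 1e-12)
  neg <- depth_profile(b$values - 0.05, depths = d)
  o_neg <- overlap_percent(a, neg)
  expect_true(attr(o_neg, "clipped"))
})

test_that("overlap of two same-centre Gaussians matches brute-force quadrature", {
  # FWHM 0.2 vs 0.4, both centred at 0.5; oracle: dense trapezoidal
  # integration of the pointwise minimum of the unit-area curves.
  dd <- seq(0, 1, by = 5e-5)
  s1 <- 0.2 / (2 * sqrt(2 * log(2))); s2 <- 2 * s1
  g1 <- exp(-(dd - 0.5)^2 / (2 * s1^2)); g1 <- g1 / pracma::trapz(dd, g1)
  g2 <- exp(-(dd - 0.5)^2 / (2 * s2^2)); g2 <- g2 / pracma::trapz(dd, g2)
  oracle <- 100 * pracma::trapz(dd, pmin(g1, g2))
  got <- overlap_percent(psf_profile(0.5, 0.2), psf_profile(0.5, 0.4))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-3)
})

test_that("ROI selection returns exact grey-matter voxel counts", {
  p <- flat3(length_mm = 20)
  g <- place_grid(p, 0.75, offset_mm = c(0.1, 0.2))
  s <- measure(induced_psf(), p, g)
  for (n in c(5, 24, 30)) {
    roi <- roi_select(s, n, start_col = 3)
    gm <- s$tissue == "gm" & s$col %in% roi$cols &
      !(s$col == roi$trim_col & s$cy_mm < roi$trim_y_below)
    expect_identical(sum(gm), as.integer(n))
  }
  expect_error(roi_select(s, 1e5), "exceeds")
})

test_that("the overlap experiment is seeded, bounded and shaped as requested", {
  p <- flat3(length_mm = 30)
  sc <- overlap_scene(max_roi = 24, patch = p)
  cv <- run_overlap_experiment(roi_sizes = c(8, 24), snr = Inf,
                               n_depths_sampled = 7, n_realizations = 8,
                               seed = 5, scene = sc)
  expect_identical(nrow(cv), 2L)
  expect_true(all(cv$mean_overlap_pct >= 0 & cv$mean_overlap_pct <= 100))
  expect_true(all(cv$sd_overlap >= 0))
  cv2 <- run_overlap_experiment(roi_sizes = c(8, 24), snr = Inf,
                                n_depths_sampled = 7, n_realizations = 8,
                                seed = 5, scene = sc)
  expect_identical(cv$mean_overlap_pct, cv2$mean_overlap_pct)
  expect_error(
    run_overlap_experiment(roi_sizes = 5000, n_realizations = 2, scene = sc),
    "exceeds")
})

test_that("more sampled depths reconstruct the PSF better on large ROIs", {
  p <- flat3(length_mm = 40)
  sc <- overlap_scene(max_roi = 100, patch = p)
  cv21 <- run_overlap_experiment(roi_sizes = 100, snr = Inf,
                                 n_depths_sampled = 21, n_realizations = 30,
                                 seed = 2, scene = sc)
  cv3 <- run_overlap_experiment(roi_sizes = 100, snr = Inf,
                                n_depths_sampled = 3, n_realizations = 30,
                                seed = 2, scene = sc)
  expect_gt(cv21$mean_overlap_pct, cv3$mean_overlap_pct)
})

test_that("pial-rim sampling at the raster pitch reproduces the field's bin means", {
  p <- make_flat_patch(2, 6, resolution_mm = 0.02)
  f <- pial_boundary_field(0.2, 1, p)
  g <- place_grid(p, 0.02, offset_mm = c(0, 0))
  s <- measure(f, p, g)
  prof <- centroid_sort_profile(s, 10)
  # rim occupies depths [0, 0.05] of the 2 mm cortex: only the first of 10
  # bins holds signal
  expect_gt(prof$values[1], 0)
  expect_true(all(prof$values[3:10] < 1e-9))
})

test_that("a zero-amplitude rim yields identically zero profiles", {
  pl <- run_pial_leakage_experiment(peak_amplitude = 0,
                                    voxel_sizes_mm = c(0.75, 0.25),
                                    n_realizations = 2, n_depths = 5, seed = 1,
                                    patch = make_flat_patch(2.5, 6))
  for (prof in pl$profiles)
    expect_true(all(prof$values == 0))
})

test_that("larger voxels leak the pial signal deeper into the cortex", {
  pl <- run_pial_leakage_experiment(voxel_sizes_mm = c(0.75, 0.125),
                                    n_realizations = 15, seed = 3,
                                    patch = make_flat_patch(2.5, 8))
  expect_gt(pl$extent_10pct[["0.75_mm"]], pl$extent_10pct[["0.125_mm"]])
})

test_that("printed-resolution arithmetic holds", {
  expect_equal(resolution_gain_pct(0.7, 0.1), 100 * 6 / 7, tolerance = 1e-12)
  expect_equal(roi_tangential_extent(80, 4), 20)
})
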