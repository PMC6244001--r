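test_that("depth bins are half-open with the last bin closed, CSFB first", {
  expect_equal(depth_bin_centers(4), c(0.125, 0.375, 0.625, 0.875))
  # d = 0.5 with 2 bins falls in the second (half-open binning)
  expect_identical(laminarsim:::depth_bin_index(c(0, 0.499, 0.5, 1), 2),
                   c(1L, 1L, 2L, 2L))
})

test_that("upsample-and-bin recovers a constant field as a flat profile", {
  p <- flat3()
  g <- place_grid(p, 0.75, offset_mm = c(0.2, 0.37))
  # domain-wide constant: every voxel mean is exactly the constant
  const <- laminarsim:::new_activation_field(
    function(d, x, t) rep(3, length(d)), "constant everywhere")
  s <- measure(const, p, g)
  prof <- upsample_and_bin(s, p, n_depths = 10)
  expect_equal(prof$values, rep(3, 10), tolerance = 1e-9)
  # a single bin collapses to the overall GM mean
  prof1 <- upsample_and_bin(s, p, n_depths = 1)
  expect_equal(prof1$values, 3, tolerance = 1e-9)
  # a GM-confined constant is diluted near the boundaries by partial
  # volume, but keeps the constant value in the cortical interior
  s_gm <- measure(constant_gm_field(3), p, g)
  prof_gm <- upsample_and_bin(s_gm, p, n_depths = 10)
  expect_equal(prof_gm$values[4:7], rep(3, 4), tolerance = 1e-6)
  expect_true(all(prof_gm$values <= 3 + 1e-9))
})

test_that("upsample-and-bin rejects samples without grey matter", {
  p <- flat3()
  g <- place_grid(p, 0.75, offset_mm = c(0, 0))
  s <- measure(constant_gm_field(1), p, g)
  s$tissue[] <- "csf"
  expect_error(upsample_and_bin(s, p, 10), "no grey-matter")
  expect_error(centroid_sort_profile(s, 4), "no grey-matter")
})

test_that("profiles are invariant to tangential grid translation on a flat patch", {
  p <- flat3(length_mm = 20)
  f <- induced_psf(0.5, 0.2, 1)
  g1 <- place_grid(p, 0.75, offset_mm = c(0.1, 0.25))
  g2 <- place_grid(p, 0.75, offset_mm = c(0.6, 0.25))
  s1 <- measure(f, p, g1); s2 <- measure(f, p, g2)
  p1 <- upsample_and_bin(s1, p, 15); p2 <- upsample_and_bin(s2, p, 15)
  expect_equal(p1$values, p2$values, tolerance = 1e-6)
})

test_that("centroid sorting puts mid-depth centroids in the upper half-open bin", {
  # 0.8 mm cortex with one 0.75 mm voxel row centred on the midline:
  # every GM centroid sits exactly at depth 0.5
  p <- make_flat_patch(0.8, 10)
  g <- place_grid(p, 0.75, offset_mm = c(0, 0.375))
  s <- measure(constant_gm_field(1), p, g)
  expect_true(all(abs(s$centroid_depth[s$tissue == "gm"] - 0.5) < 1e-9))
  prof <- centroid_sort_profile(s, 2)
  expect_true(is.na(prof$values[1]))
  expect_false(is.na(prof$values[2]))
})

test_that("a single voxel populates exactly its own bin", {
  p <- make_flat_patch(0.8, 0.6)
  g <- place_grid(p, 0.75, offset_mm = c(0, 0.375))
  s <- measure(constant_gm_field(2), p, g)
  s_one <- s[s$tissue == "gm", ][1, ]
  attr(s_one, "grid") <- attr(s, "grid")
  class(s_one) <- class(s)
  prof <- centroid_sort_profile(s_one, 5)
  expect_identical(sum(!is.na(prof$values)), 1L)
  expect_equal(prof$values[3], 2, tolerance = 1e-9)  # d = 0.5 -> bin 3 of 5
})

test_that("centroid sorting reproduces the erf-oracle voxel means per bin", {
  p <- flat3()
  f <- induced_psf(0.5, 0.2, 1)
  g <- place_grid(p, 0.75, offset_mm = c(0, 0))
  s <- measure(f, p, g)
  prof <- centroid_sort_profile(s, 4)
  sigma_y <- sigma_y_of(0.2, 3)
  centres <- c(1.125, 0.375, -0.375, -1.125)  # bin order CSFB -> WMB
  oracle <- vapply(centres, function(c0)
    gauss_interval_mean(c0 - 0.375, c0 + 0.375, sigma_y), numeric(1))
  expect_equal(prof$values, oracle, tolerance = 1e-6)
})

test_that("window extraction separates a boxcar response from its absence", {
  times <- 0:60
  tc <- matrix(0, 3, length(times))
  amp <- c(3, 2, 1)
  for (k in 1:3) tc[k, times >= 10 & times <= 30] <- amp[k]
  ex <- extract_positive_and_undershoot(tc, times, 10, 20, rise_lag_s = 1,
                                        undershoot_window_s = 10)
  expect_equal(ex$positive$values, amp)
  expect_equal(ex$undershoot$values, c(0, 0, 0))
  expect_error(
    extract_positive_and_undershoot(tc, times, 50, 20),
    "outside the sampled time range")
})

test_that("profile normalization modes behave and are idempotent", {
  pr <- depth_profile(c(2, 4))
  pk <- normalize_profile(pr, "peak")
  expect_equal(pk$values, c(0.5, 1))
  ua <- normalize_profile(depth_profile(exp(-(depth_bin_centers(21) - 0.5)^2 / 0.01)),
                          "unit_area")
  expect_equal(pracma::trapz(ua$depths, ua$values), 1, tolerance = 1e-10)
  expect_equal(normalize_profile(ua, "unit_area")$values, ua$values,
               tolerance = 1e-12)
  expect_error(normalize_profile(depth_profile(c(0, 0)), "peak"), "all-zero")
  # reference profile supplies the scale (joint positive/undershoot scaling)
  und <- depth_profile(c(-1, -2))
  scaled <- normalize_profile(und, "peak", reference = pr)
  expect_equal(scaled$values, c(-0.25, -0.5))
})

test_that("depth profiles round-trip through TSV", {
  pr <- depth_profile(c(0.1, NA, 0.3), n_samples = c(5L, 0L, 7L),
                      normalization = "none")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_depth_profile_tsv(pr, path)
  q <- read_depth_profile_tsv(path)
  expect_equal(q$values, pr$values)
  expect_equal(q$depths, pr$depths)
  expect_identical(q$normalization, "none")
})

test_that("jitter-averaged upsample-and-bin matches the convolution oracle", {
  # Phase-sweep the grid offset across the voxel pitch: the average
  # reconstructed profile converges to the induced Gaussian convolved with
  # the boxcar voxel kernel and the triangular kernel of linear
  # interpolation, all binned. Compare against a numeric convolution of
  # the closed-form Gaussian x boxcar profile.
  p <- flat3(length_mm = 12)
  f <- induced_psf(0.5, 0.2, 1)
  v <- 0.75; n_bins <- 15; K <- 30
  acc <- 0
  for (k in seq_len(K)) {
    g <- place_grid(p, v, offset_mm = c(0.3, (k - 0.5) / K * v))
    s <- measure(f, p, g)
    acc <- acc + upsample_and_bin(s, p, n_bins)$values / K
  }
  sigma_y <- sigma_y_of(0.2, 3)
  yy <- seq(-3, 3, by = 1e-3)
  gb <- gauss_conv_box(yy, sigma_y, v)
  tri <- (1 - abs(seq(-v, v, by = 1e-3)) / v); tri <- tri / sum(tri)
  gbt <- stats::convolve(gb, rev(tri), type = "open")
  yy2 <- seq(-3 - v, 3 + v, by = 1e-3)[seq_along(gbt)]
  centres_y <- 1.5 - depth_bin_centers(n_bins) * 3
  oracle <- vapply(centres_y, function(c0) {
    w <- 3 / n_bins / 2
    mean(gbt[yy2 >= c0 - w & yy2 < c0 + w])
  }, numeric(1))
  expect_gt(cor(acc, oracle), 0.999)
  expect_lt(max(abs(acc - oracle)), 0.02)
  # broadened and unimodal, peaked at the bin containing d = 0.5
  expect_identical(which.max(acc), 8L)
  expect_true(all(diff(acc[1:8]) > 0) && all(diff(acc[8:15]) < 0))
})
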