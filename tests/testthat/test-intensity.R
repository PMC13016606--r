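# Region-in-region background correction and dimer-standard calibration.

test_that("region-in-region is zero on constant frames and offset invariant", {
  frame <- matrix(5, 40, 40)
  roi <- roi_spec(c(20, 20), 3, 6)
  expect_equal(region_in_region(frame, roi)$corrected_integrated_intensity,
               0)

  set.seed(3)
  noisy <- matrix(rnorm(1600, 100, 5), 40, 40)
  m0 <- region_in_region(noisy, roi)$corrected_integrated_intensity
  m7 <- region_in_region(noisy + 73.2, roi)$corrected_integrated_intensity
  expect_equal(m0, m7, tolerance = 1e-10)

  expect_error(roi_spec(c(20, 20), 6, 6))
  expect_error(roi_spec(c(20, 20), 0, 6))
  expect_error(region_in_region(frame, roi_spec(c(2, 2), 3, 6)),
               "outside")
})

test_that("a rendered punctum's photons are recovered on flat background", {
  cfg <- tiny_config(photons_per_fluorophore = 500, camera_gain = 1)
  frame <- matrix(50, 64, 64)
  frame <- kymotrace:::add_punctum(frame, c(30.3, 31.7), 2, cfg)
  m <- region_in_region(frame, roi_spec(c(30.3, 31.7), 4, 9))
  expect_lt(abs(m$corrected_integrated_intensity - 1000) / 1000, 0.01)
})

test_that("cytoplasmic level subtracts equal-size nuclear ROI", {
  img <- matrix(1, 60, 60)
  expect_equal(cytoplasmic_level(img, c(5, 5), c(30, 30)), 0)
  img2 <- matrix(1, 60, 60); img2[, 1:30] <- 2  # columns 0..29 hold 2s
  expect_equal(cytoplasmic_level(img2, c(2, 10), c(32, 10)), 625)
  expect_error(cytoplasmic_level(img, c(5, 5), c(30, 30), size = 24),
               "25 x 25")
  expect_error(cytoplasmic_level(img, c(50, 50), c(30, 30)), "outside")
})

test_that("copy-number estimation against the dimer standard", {
  e <- estimate_copy_number(c(5, 5, 5), c(5, 5, 5), n_boot = 200, seed = 1)
  expect_equal(e$ratio_to_standard, 1.0)
  expect_equal(e$mean_copies, 2.0)
  expect_equal(e$ci, c(2, 2))

  set.seed(4)
  std <- rnorm(200, 1000, 50)
  half <- rnorm(200, 500, 40)
  e2 <- estimate_copy_number(half, std, n_boot = 500, seed = 2)
  expect_lt(abs(e2$mean_copies - 1.0), 0.1)
  expect_true(e2$ci[1] <= e2$mean_copies && e2$mean_copies <= e2$ci[2])

  # invariance under a common gain
  e3 <- estimate_copy_number(half * 3.7, std * 3.7, n_boot = 500, seed = 2)
  expect_equal(e3$mean_copies, e2$mean_copies, tolerance = 1e-12)

  expect_error(estimate_copy_number(c(1, 2), c(-5, -6)))
  expect_error(estimate_copy_number(numeric(0), c(1)))
})

test_that("mean copies converges to two for heterozygous two-dimer puncta", {
  # intensities proportional to Binomial(4, 0.5) tag counts (two dimers,
  # 50% chain labeling) against an exact-dimer standard
  set.seed(6)
  for (n in c(200, 2000)) {
    k <- stats::rbinom(n, 4, 0.5)
    test_i <- k * 1000 + rnorm(n, 0, 50)
    std_i <- 2 * 1000 + rnorm(n, 0, 50)
    e <- estimate_copy_number(test_i, std_i, n_boot = 200, seed = 3)
    expect_lt(abs(e$mean_copies - 2), 4 * sd(test_i) / 1000 / sqrt(n) + 0.02)
  }
})

test_that("run intensity is measured at a clean, well-resolved frame", {
  cfg <- tiny_config(photons_per_fluorophore = 500)
  # punctum drifting 1 px/frame along y = 32, 4 fluorophores, flat bg 50
  track <- data.frame(frame = 1:25, x = 14 + (1:25), y = 32, n = 4)
  mov <- manual_movie(track, cfg, constant = 50)
  path <- kymo_path(c(12, 43), c(32, 32), cfg$pixel_size)
  k <- extract_kymograph(mov, path)
  traces <- detect_traces(k, min_speed = 0.2)
  expect_length(traces, 1)
  tr <- traces[[1]]
  m <- measure_run_intensity(mov, tr, k)
  expect_lt(abs(m$corrected_intensity - 2000) / 2000, 0.05)

  # a neighbor inside the outer region excludes that frame
  nb <- data.frame(frame = tr$frames, x = m$x + 3, y = m$y + 3)
  m2 <- measure_run_intensity(mov, tr, k, neighbors = nb)
  expect_true(is.na(m2$frame) || m2$frame != m$frame)
})
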