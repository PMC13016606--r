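# Kymograph extraction: path geometry, interpolation, reducer properties.

test_that("path length sums Euclidean segments times pixel size", {
  expect_equal(path_length(kymo_path(c(0, 10), c(0, 0), 0.13)), 1.3)
  expect_equal(path_length(kymo_path(c(0, 3), c(0, 4), 1.0)), 5.0)
  expect_equal(path_length(kymo_path(c(0, 10, 10), c(0, 0, 10), 0.1)), 2.0)
  expect_error(kymo_path(0, 0, 0.13))
  expect_error(kymo_path(c(1, 1), c(2, 2), 0.13))
})

test_that("a constant movie gives a constant kymograph", {
  mov <- constant_movie(7)
  path <- kymo_path(c(3, 20, 25), c(4, 10, 25), 0.13)
  k <- extract_kymograph(mov, path, line_width = 5)
  expect_true(all(abs(k$values - 7) < 1e-9))
  k3 <- extract_kymograph(mov, path, line_width = 3, reducer = "mean")
  expect_true(all(abs(k3$values - 7) < 1e-9))
})

test_that("a punctum moving 1 px/frame makes a diagonal ridge", {
  cfg <- tiny_config()
  track <- data.frame(frame = 1:20, x = 9 + (1:20), y = 32, n = 4)
  mov <- manual_movie(track, cfg)
  path <- kymo_path(c(5, 55), c(32, 32), cfg$pixel_size)
  k <- extract_kymograph(mov, path)
  ridge <- apply(k$values[1:20, ], 1, which.max)
  expect_true(all(diff(ridge) == 1))

  # stationary punctum: zero-slope ridge at any line width
  track_s <- data.frame(frame = 1:20, x = 30, y = 32, n = 4)
  mov_s <- manual_movie(track_s, cfg)
  for (w in c(1, 5, 9)) {
    ks <- extract_kymograph(mov_s, path, line_width = w)
    ridge_s <- apply(ks$values[1:20, ], 1, which.max)
    expect_true(all(ridge_s == ridge_s[1]))
  }
})

test_that("ridge localization tracks subpixel ground truth within 0.25 px", {
  spec <- population_spec("runner", count = 1, velocity_mean = 0.9,
                          velocity_sd = 0, run_time_mean = 8,
                          copy_number = copy_fixed(6))
  cfg <- tiny_config(populations = list(spec), n_frames = 40,
                     bleach_rate = 0, rng_seed = 5L)
  sim <- simulate_movie(cfg, noise = FALSE)
  gt <- sim$ground_truth
  p <- gt$particles[1, ]
  pos <- gt$positions[gt$positions$id == p$id, ]
  path <- kymotrace:::particle_path(p, cfg$pixel_size)
  k <- extract_kymograph(sim$movie, path)
  traces <- detect_traces(k, min_speed = 0.2)
  expect_gte(length(traces), 1)
  tr <- traces[[which.max(vapply(traces, function(t) length(t$frames),
                                 numeric(1)))]]
  proj <- ((pos$x - path$x[1]) * cos(p$theta) +
             (pos$y - path$y[1]) * sin(p$theta)) / k$sample_step
  common <- intersect(tr$frames, pos$frame)
  err <- tr$dist[match(common, tr$frames)] - proj[match(common, pos$frame)]
  expect_true(all(abs(err) * k$sample_step <= 0.25))
})

test_that("max-reducer kymograph values are monotone in line width", {
  spec <- population_spec("runner", count = 3, velocity_mean = 1,
                          velocity_sd = 0.2, run_time_mean = 5,
                          copy_number = copy_fixed(4))
  cfg <- tiny_config(populations = list(spec), rng_seed = 13L)
  mov <- simulate_movie(cfg)$movie
  path <- kymo_path(c(5, 58), c(10, 50), cfg$pixel_size)
  k1 <- extract_kymograph(mov, path, line_width = 1)
  k5 <- extract_kymograph(mov, path, line_width = 5)
  k9 <- extract_kymograph(mov, path, line_width = 9)
  expect_true(all(k5$values >= k1$values - 1e-9))
  expect_true(all(k9$values >= k5$values - 1e-9))
})

test_that("reversing the path flips the distance axis exactly", {
  spec <- population_spec("runner", count = 2, velocity_mean = 1,
                          velocity_sd = 0.2, run_time_mean = 5,
                          copy_number = copy_fixed(4))
  cfg <- tiny_config(populations = list(spec), rng_seed = 17L)
  mov <- simulate_movie(cfg)$movie
  path <- kymo_path(c(6, 40, 57), c(8, 30, 55), cfg$pixel_size)
  rpath <- kymo_path(rev(path$x), rev(path$y), cfg$pixel_size)
  k <- extract_kymograph(mov, path)
  rk <- extract_kymograph(mov, rpath)
  expect_equal(rk$values, k$values[, ncol(k$values):1])
})

test_that("invalid kymograph arguments error", {
  mov <- constant_movie(1)
  path <- kymo_path(c(2, 20), c(2, 20), 0.13)
  expect_error(extract_kymograph(mov, path, line_width = 4), "odd")
  expect_warning(
    extract_kymograph(mov, kymo_path(c(-3, 10), c(0, 0), 0.13)),
    "clamped")
})
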