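# Run measurement: velocity, run time/length arithmetic, trace detection,
# directional-switch scoring, measurement properties.

test_that("run time and run length follow their definitions", {
  expect_equal(run_time(3, 16, 0.2), 2.6)
  expect_equal(run_time(0, 1, 0.2), 0.2)
  expect_error(run_time(10, 10, 0.2))
  expect_error(run_time(3, 16, 0))

  expect_equal(run_length(1.2, 2.6), 3.12)
  expect_equal(run_length(0, 5), 0)
  expect_equal(run_length(0.5, 12), 6.0)
})

test_that("endpoint velocity is net displacement over elapsed time", {
  tr <- kymo_trace(frames = c(1, 14), dist = c(0, 10))
  v <- measure_velocity(tr, pixel_size = 0.13, frame_interval = 0.2)
  expect_equal(as.numeric(v), 0.5)
  expect_equal(attr(v, "direction"), 1)

  still <- kymo_trace(frames = c(1, 5, 9), dist = c(4, 4, 4))
  expect_equal(as.numeric(measure_velocity(still, 0.13, 0.2)), 0)

  # least-squares equals endpoint exactly on linear traces
  lin <- kymo_trace(frames = 1:10, dist = 2 + 1.5 * (1:10))
  ve <- measure_velocity(lin, 0.13, 0.2, method = "endpoint")
  vl <- measure_velocity(lin, 0.13, 0.2, method = "lsq")
  expect_equal(as.numeric(ve), as.numeric(vl))
})

test_that("directional switches need resolvable arms on both sides", {
  px <- 0.13
  mono <- kymo_trace(1:10, seq(0, 18, length.out = 10))
  expect_equal(count_reversals(mono, 0.5, pixel_size = px), 0)

  v_shape <- kymo_trace(1:11, c(0:5, 4:0) * 1.6)  # arms ~1 um
  expect_equal(count_reversals(v_shape, 0.5, pixel_size = px), 1)

  shallow <- kymo_trace(1:11, c(0:5, 4.6, 4.4, 4.2, 4.4, 4.2))
  expect_equal(count_reversals(shallow, 0.5, pixel_size = px), 0)

  zigzag <- kymo_trace(1:21, c(0:5, 4:0, 1:5, 4:0) * 1.6)
  expect_equal(count_reversals(zigzag, 0.5, pixel_size = px), 3)
})

test_that("a clean diagonal ridge yields exactly one trace", {
  vals <- matrix(100, 30, 40) + matrix(rnorm(1200, 0, 1), 30, 40)
  for (f in 1:25) vals[f, 5 + f] <- 400
  k <- manual_kymo(vals)
  traces <- detect_traces(k)
  expect_length(traces, 1)
  expect_gte(length(traces[[1]]$frames), 20)
  v <- trace_velocity(traces[[1]], k)
  expect_lt(abs(as.numeric(v) - 0.13 / 0.2), 0.05)
})

test_that("pure-noise kymographs yield no traces at snr 5", {
  set.seed(55)
  hits <- 0
  for (i in 1:100) {
    vals <- matrix(140 + rnorm(30 * 60, 0, 9), 30, 60)
    if (length(detect_traces(manual_kymo(vals), snr_threshold = 5)) > 0)
      hits <- hits + 1
  }
  expect_lte(hits, 1)  # 0 traces in >= 99% of noise-only kymographs
})

test_that("high-SNR simulated runners are recovered against ground truth", {
  matched <- 0; observable <- 0
  per_run_ok <- TRUE
  for (seed in c(71L, 72L)) {
    spec <- population_spec("runner", count = 10, velocity_mean = 1,
                            velocity_sd = 0.2, run_time_mean = 8,
                            copy_number = copy_fixed(6))
    cfg <- simulation_config(image_width = 128, image_height = 128,
                             n_frames = 40, populations = list(spec),
                             bleach_rate = 0, rng_seed = seed)
    sim <- simulate_movie(cfg)
    res <- kymotrace:::analyze_movie(sim$movie, sim$ground_truth,
                                     measure_intensity = FALSE)
    # a run must be in the field for >= 4 frames to be scoreable at all
    pos <- sim$ground_truth$positions
    vis <- table(factor(pos$id[pos$n_active > 0], levels = res$id))
    observable <- observable + sum(vis >= 4)
    matched <- matched + sum(res$matched)
    r <- res[res$matched, ]
    # endpoint velocity within one sample of localization per endpoint
    bound <- 1 * cfg$pixel_size / r$run_time_s
    per_run_ok <- per_run_ok &&
      all(abs(r$velocity_um_s - r$true_velocity_um_s) <= bound)
  }
  expect_gte(observable, 12)
  expect_gte(matched, 0.9 * observable)
  expect_true(per_run_ok)
})

test_that("measured velocity and run length are scale covariant", {
  tr <- kymo_trace(frames = 1:11, dist = seq(0, 20, 2))
  v1 <- as.numeric(measure_velocity(tr, 0.13, 0.2))
  v2 <- as.numeric(measure_velocity(tr, 0.26, 0.2))
  expect_equal(v2, 2 * v1)

  v3 <- as.numeric(measure_velocity(tr, 0.13, 0.4))
  expect_equal(v3, v1 / 2)

  rt1 <- run_time(1, 11, 0.2); rt3 <- run_time(1, 11, 0.4)
  expect_equal(run_length(v1, rt1), run_length(v3, rt3))
})

test_that("measure_trace uses the dominant arm of a switching trace", {
  k <- manual_kymo(matrix(0, 40, 60))
  # 21 points out at 2 samples/frame, then 6 back at the same speed
  tr <- kymo_trace(1:27, c(seq(0, 40, 2), seq(38, 28, -2)))
  m <- measure_trace(tr, k, min_reversal_length = 0.5)
  expect_equal(m$n_reversals, 1)
  # dominant-arm speed: 2 samples/frame = 2 * 0.13 / 0.2 um/s
  expect_lt(abs(m$velocity_um_s - 2 * 0.13 / 0.2), 0.05)
  expect_equal(m$run_time_s, 26 * 0.2)
})
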