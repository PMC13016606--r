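# Synthetic movie generator: labeling models, run sampling, PSF rendering,
# photobleaching, censoring and determinism.

test_that("labeling models reproduce their distributions", {
  expect_equal(draw_copy_number(copy_fixed(3), 5), rep(3, 5))

  # heterozygous dimer: counts 0/1/2 with probabilities 1/4, 1/2, 1/4
  set.seed(11)
  k <- draw_copy_number(dimer_binomial(2, 0.5), 10000)
  freq <- tabulate(k + 1, nbins = 3) / 10000
  p <- c(0.25, 0.5, 0.25)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < 3 * se))

  expect_error(copy_binomial(4, 1.2))
  expect_error(copy_fixed(-1))
})

test_that("sampled runs follow the configured motility distributions", {
  cfg <- tiny_config(n_frames = 60)
  spec <- population_spec("runner", count = 1, velocity_mean = 1,
                          velocity_sd = 0, run_length_mean = 3)

  set.seed(7)
  lens <- replicate(10000, sample_run(spec, cfg)$run_length_um)
  # Exp(3): sample mean within 3 standard errors (SD = mean for exponential)
  expect_lt(abs(mean(lens) - 3), 3 * 3 / sqrt(10000))

  set.seed(8)
  spec_rev <- population_spec("runner", count = 1, velocity_mean = 1,
                              velocity_sd = 0, run_length_mean = 3,
                              reversal_prob = 1)
  revs <- replicate(200, sample_run(spec_rev, cfg)$n_reversals)
  expect_true(all(revs >= 1))

  # the reported ~3% per-run switch rate is recovered in ground truth
  set.seed(9)
  spec3 <- population_spec("runner", count = 1, velocity_mean = 1,
                           velocity_sd = 0, run_length_mean = 3,
                           reversal_prob = 0.03)
  frac <- mean(replicate(10000, sample_run(spec3, cfg)$n_reversals) >= 1)
  expect_lt(abs(frac - 0.03), 2.58 * sqrt(0.03 * 0.97 / 10000))

  expect_error(population_spec("runner", count = 1, velocity_mean = -1,
                               run_length_mean = 3))
  expect_error(population_spec("runner", count = 1, velocity_mean = 1,
                               run_length_mean = 3, run_time_mean = 3))
})

test_that("run-time parameterization gives exponential durations", {
  cfg <- tiny_config(n_frames = 60)
  spec <- population_spec("runner", count = 1, velocity_mean = 1.2,
                          velocity_sd = 0.3, run_time_mean = 2.5)
  set.seed(12)
  rt <- replicate(10000, sample_run(spec, cfg)$true_run_time_s)
  expect_lt(abs(mean(rt) - 2.5), 3 * 2.5 / sqrt(10000))
})

test_that("rendered puncta conserve photons independent of subpixel offset", {
  cfg <- tiny_config(photons_per_fluorophore = 500)

  expect_true(all(render_punctum(c(10, 10), 0, cfg)$patch == 0))

  p1 <- render_punctum(c(10, 10), 2, cfg)
  expect_lt(abs(sum(p1$patch) - 1000) / 1000, 0.01)

  p2 <- render_punctum(c(10.5, 10.5), 2, cfg)
  expect_lt(abs(sum(p1$patch) - sum(p2$patch)) / sum(p1$patch), 0.005)
})

test_that("movies are deterministic and photon-conserving", {
  spec <- population_spec("stationary", count = 1,
                          copy_number = copy_fixed(4))
  cfg <- tiny_config(populations = list(spec), bleach_rate = 0,
                     background_photons = 0, read_noise_sd = 0,
                     n_frames = 6, rng_seed = 21L)

  sim1 <- simulate_movie(cfg)
  sim2 <- simulate_movie(cfg)
  expect_identical(unclass(sim1$movie), unclass(sim2$movie))
  expect_identical(sim1$ground_truth$particles, sim2$ground_truth$particles)

  # noise-free expectation: integrated signal above offset is constant
  # across frames and equals fluorophores x photons x gain
  exp_sim <- simulate_movie(cfg, noise = FALSE)
  per_frame <- apply(exp_sim$movie, 3, sum) -
    cfg$camera_offset * cfg$image_width * cfg$image_height
  target <- 4 * cfg$photons_per_fluorophore * cfg$camera_gain
  expect_true(all(abs(per_frame - target) / target < 0.01))
  expect_lt(max(abs(per_frame - per_frame[1])), 1e-6)
})

test_that("photobleaching follows exponential survival", {
  spec <- population_spec("stationary", count = 1000,
                          copy_number = copy_fixed(3))
  cfg <- tiny_config(populations = list(spec), bleach_rate = 0.5,
                     n_frames = 15, rng_seed = 31L)
  sim <- simulate_movie(cfg)
  pos <- sim$ground_truth$positions
  for (f in c(2, 6, 11)) {
    t <- (f - 1) * cfg$frame_interval
    surv <- exp(-cfg$bleach_rate * t)
    m <- mean(pos$n_active[pos$frame == f])
    se <- sqrt(3 * surv * (1 - surv) / 1000)
    expect_lt(abs(m - 3 * surv), 3 * se + 1e-9)
  }
})

test_that("observed run times never exceed true run times", {
  spec <- population_spec("runner", count = 30, velocity_mean = 1.2,
                          velocity_sd = 0.4, run_time_mean = 3,
                          copy_number = copy_binomial(4, 0.5))
  cfg <- tiny_config(populations = list(spec), n_frames = 40,
                     rng_seed = 41L)
  sim <- simulate_movie(cfg)
  p <- sim$ground_truth$particles
  expect_true(all(p$observed_run_time_s <= p$true_run_time_s + 1e-9))
  expect_true(all(p$n_reversals >= 0))
})

test_that("invalid configurations error before rendering", {
  expect_error(simulation_config(n_frames = 1))
  expect_error(simulation_config(psf_sigma = 0.2))
  expect_error(simulation_config(pixel_size = 0))
})
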