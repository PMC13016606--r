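# Synthetic TIRFM movie generator with per-particle ground truth.
#
# The generator emulates streaming TIRFM of fluorescently tagged motor
# complexes: processive "runner" puncta, slow plus-end "comet" puncta,
# and immobile cortical puncta, rendered as diffraction-limited Gaussian
# spots with per-fluorophore photobleaching, Poisson shot noise and
# Gaussian camera read noise.

#' Fluorophore copy-number models
#'
#' A punctum carries an integer number of fluorophores drawn from a simple
#' labeling model. `copy_fixed(k)` gives exactly `k` fluorophores.
#' `copy_binomial(n, p)` draws Binomial(`n`, `p`): `n` taggable subunits,
#' each tagged independently with probability `p`. `dimer_binomial()` and
#' `multimer_binomial()` are domain-named aliases of `copy_binomial()`:
#' a heterozygously tagged dimer is `dimer_binomial(2, 0.5)` (counts 0/1/2
#' with probabilities 1/4, 1/2, 1/4), and a complex with four copies of a
#' subunit of which a fraction `p_tag` is tagged is
#' `multimer_binomial(4, p_tag)`.
#'
#' @param k Fixed fluorophore count (integer >= 0).
#' @param n,n_chains,n_copies Number of independently taggable subunits.
#' @param p,p_tag Per-subunit probability of carrying the tag, in \[0, 1\].
#' @return A `copy_model` object understood by [population_spec()].
#' @examples
#' draw_copy_number(dimer_binomial(2, 0.5), 5)
#' @export
copy_fixed <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, k == round(k))
  structure(list(model = "fixed", k = as.integer(k)), class = "copy_model")
}

#' @rdname copy_fixed
#' @export
copy_binomial <- function(n, p) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  stopifnot(is.numeric(p), length(p) == 1, p >= 0, p <= 1)
  structure(list(model = "binomial", n = as.integer(n), p = p),
            class = "copy_model")
}

#' @rdname copy_fixed
#' @export
dimer_binomial <- function(n_chains, p_tag) copy_binomial(n_chains, p_tag)

#' @rdname copy_fixed
#' @export
multimer_binomial <- function(n_copies, p_tag) copy_binomial(n_copies, p_tag)

#' @rdname copy_fixed
#' @param model A `copy_model`.
#' @param n_draws Number of puncta to draw counts for.
#' @export
draw_copy_number <- function(model, n_draws = 1) {
  stopifnot(inherits(model, "copy_model"))
  switch(model$model,
    fixed    = rep(model$k, n_draws),
    binomial = stats::rbinom(n_draws, model$n, model$p),
    stop("unknown copy model: ", model$model)
  )
}

#' Specify one simulated particle population
#'
#' @param kind `"runner"` (processive motility at constant speed along a
#'   straight track), `"comet"` (slow tip-tracking, same mechanics at the
#'   plus-end polymerization speed), or `"stationary"` (immobile punctum
#'   present for the whole movie, emulating the cortical pool).
#' @param count Number of particles.
#' @param velocity_mean,velocity_sd Speed distribution in um/s; speeds are
#'   drawn from a normal truncated at zero. Required positive mean for
#'   runner/comet.
#' @param run_length_mean Exponential mean of the run length in um: the
#'   run's extent is drawn Exp(`run_length_mean`) and its duration is
#'   length over speed. Mutually exclusive with `run_time_mean`.
#' @param run_time_mean Exponential mean of the run duration in s: the
#'   motor detaches at a constant rate `1/run_time_mean` (the standard
#'   single-molecule kinetic model) and the run length is speed times
#'   duration. Mutually exclusive with `run_length_mean`. Preferred when
#'   observed run-time and run-length means are both available, since with
#'   speed-independent exponential lengths the implied mean duration
#'   E(L)E(1/v) substantially exceeds E(L)/E(v).
#' @param reversal_prob Probability that a run contains one directional
#'   switch. A switching run is given two resolvable arms (see
#'   `min_reversal_arm`), because a switch is only a switch if both arms are
#'   observable movement.
#' @param min_reversal_arm Minimum arm length (um) on each side of a
#'   directional switch; the run length of a switching run is drawn
#'   conditional on exceeding twice this value.
#' @param copy_number A [copy_model][copy_fixed] for the initial fluorophore
#'   count per punctum.
#' @return A `population_spec` object.
#' @export
population_spec <- function(kind = c("runner", "comet", "stationary"),
                            count,
                            velocity_mean = NULL,
                            velocity_sd = 0,
                            run_length_mean = NULL,
                            run_time_mean = NULL,
                            reversal_prob = 0,
                            min_reversal_arm = 0.5,
                            copy_number = copy_fixed(1)) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(count), length(count) == 1, count >= 0,
            count == round(count))
  stopifnot(reversal_prob >= 0, reversal_prob <= 1)
  stopifnot(inherits(copy_number, "copy_model"))
  if (kind %in% c("runner", "comet")) {
    if (is.null(velocity_mean) || velocity_mean <= 0)
      stop("velocity_mean must be > 0 for kind '", kind, "'")
    if (is.null(run_length_mean) == is.null(run_time_mean))
      stop("give exactly one of run_length_mean or run_time_mean")
    if (!is.null(run_length_mean) && run_length_mean <= 0)
      stop("run_length_mean must be > 0")
    if (!is.null(run_time_mean) && run_time_mean <= 0)
      stop("run_time_mean must be > 0")
    stopifnot(velocity_sd >= 0)
  } else {
    velocity_mean <- 0; velocity_sd <- 0; run_length_mean <- 0
    run_time_mean <- NULL; reversal_prob <- 0
  }
  structure(list(kind = kind, count = as.integer(count),
                 velocity_mean = velocity_mean, velocity_sd = velocity_sd,
                 run_length_mean = run_length_mean,
                 run_time_mean = run_time_mean,
                 reversal_prob = reversal_prob,
                 min_reversal_arm = min_reversal_arm,
                 copy_number = copy_number),
            class = "population_spec")
}

#' Simulation configuration
#'
#' Physical and camera parameters of a synthetic TIRFM acquisition. Defaults
#' describe streaming TIRFM at 5 frames per second (0.2 s interval) for 12 s
#' (60 frames) with 2x2 camera binning (0.13 um/px) on an sCMOS-style camera
#' (Poisson shot noise plus Gaussian read noise, no EM excess noise).
#'
#' @param image_width,image_height Frame size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param pixel_size Pixel size, um/px.
#' @param frame_interval Time between frames, s.
#' @param psf_sigma Gaussian PSF sigma, px (>= 0.5).
#' @param photons_per_fluorophore Detected photons per fluorophore per frame.
#' @param bleach_rate Per-fluorophore photobleaching rate, 1/s.
#' @param background_photons Background photons per pixel per frame.
#' @param camera_gain ADU per photon.
#' @param camera_offset Camera offset, ADU.
#' @param read_noise_sd Gaussian read noise SD, ADU.
#' @param populations List of [population_spec()] objects.
#' @param rng_seed Integer seed; identical seeds give identical movies.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(image_width = 128, image_height = 128,
                              n_frames = 60, pixel_size = 0.13,
                              frame_interval = 0.2, psf_sigma = 1.3,
                              photons_per_fluorophore = 600,
                              bleach_rate = 0.02,
                              background_photons = 20,
                              camera_gain = 2, camera_offset = 100,
                              read_noise_sd = 1.5,
                              populations = list(),
                              rng_seed = 1L) {
  stopifnot(image_width >= 8, image_height >= 8, n_frames >= 2)
  stopifnot(pixel_size > 0, frame_interval > 0, psf_sigma >= 0.5)
  stopifnot(photons_per_fluorophore > 0, bleach_rate >= 0,
            background_photons >= 0, camera_gain > 0, camera_offset >= 0,
            read_noise_sd >= 0)
  if (!is.list(populations)) populations <- list(populations)
  for (p in populations) stopifnot(inherits(p, "population_spec"))
  structure(list(image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 psf_sigma = psf_sigma,
                 photons_per_fluorophore = photons_per_fluorophore,
                 bleach_rate = bleach_rate,
                 background_photons = background_photons,
                 camera_gain = camera_gain, camera_offset = camera_offset,
                 read_noise_sd = read_noise_sd,
                 populations = populations,
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

# Truncated-at-zero normal speed draw (rejection; vectorized).
draw_speed <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] <= 0]
  }
  out
}

#' Sample one particle's run
#'
#' Draws the latent motility variables of a single particle: speed from a
#' truncated-at-zero normal, run extent from an exponential (in length or,
#' via `run_time_mean`, in duration at this run's speed), at most one
#' directional switch (probability `reversal_prob`) placed uniformly in the
#' interior of the run with both arms at least `min_reversal_arm` um, a
#' random track orientation, and a start time uniform over the acquisition.
#' The trajectory is a straight segment (reflected at the switch) traversed
#' at constant speed.
#'
#' Uses the current RNG state; seed with [set.seed()] (or via
#' `simulation_config$rng_seed` inside [simulate_movie()]).
#'
#' @param spec A [population_spec()] with kind `"runner"` or `"comet"`.
#' @param config A [simulation_config()] (supplies field size and timing).
#' @return A one-row data frame of latent variables (speed um/s, run length
#'   um, true run time s, reversal position um or `NA`, direction, start
#'   time s, start position px, `exited` flag).
#' @export
sample_run <- function(spec, config) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(config, "simulation_config"))
  if (!spec$kind %in% c("runner", "comet"))
    stop("sample_run() requires a runner or comet population")
  duration <- (config$n_frames - 1) * config$frame_interval

  v <- draw_speed(1, spec$velocity_mean, spec$velocity_sd)
  # run extent: either exponential length, or exponential duration
  # (constant detachment rate) converted to length at this run's speed
  scale_um <- if (!is.null(spec$run_time_mean))
    v * spec$run_time_mean else spec$run_length_mean
  reverses <- stats::runif(1) < spec$reversal_prob
  if (reverses) {
    # A scored directional switch needs two observable arms: condition the
    # exponential run extent on >= 2 arms (memoryless shift) and place the
    # switch uniformly in the resolvable interior.
    arm <- spec$min_reversal_arm
    len <- 2 * arm + stats::rexp(1, 1 / scale_um)
    s_rev <- stats::runif(1, arm, len - arm)
  } else {
    len <- stats::rexp(1, 1 / scale_um)
    s_rev <- NA_real_
  }
  theta <- stats::runif(1, 0, 2 * pi)
  t0 <- stats::runif(1, 0, duration)

  # Spatial extent along the track direction covered by the run (um):
  # position along the line is s for s < s_rev, then reflected.
  lo <- if (reverses) min(0, 2 * s_rev - len) else 0
  hi <- if (reverses) s_rev else len
  place <- place_segment(theta, lo / config$pixel_size,
                         hi / config$pixel_size,
                         config$image_width, config$image_height,
                         margin = 4)

  data.frame(kind = spec$kind, velocity_um_s = v, run_length_um = len,
             true_run_time_s = len / v, reversal_s_um = s_rev,
             n_reversals = as.integer(reverses),
             theta = theta, t0_s = t0,
             x0 = place$x0, y0 = place$y0, exited = place$exited)
}

# Choose a start pixel position so the line-coordinate range [lo, hi] (px)
# along direction theta fits inside [margin, size-1-margin] where possible;
# otherwise center the extent and flag the particle as exiting the field.
place_segment <- function(theta, lo, hi, width, height, margin = 4) {
  dx <- cos(theta); dy <- sin(theta)
  pick <- function(d, ext_lo, ext_hi, size) {
    # start + d * [ext_lo, ext_hi] must lie in [margin, size - 1 - margin]
    r <- sort(c(d * ext_lo, d * ext_hi))
    a <- margin - r[1]; b <- (size - 1 - margin) - r[2]
    if (a <= b) list(pos = stats::runif(1, a, b), fits = TRUE)
    else list(pos = (a + b) / 2, fits = FALSE)
  }
  px <- pick(dx, lo, hi, width)
  py <- pick(dy, lo, hi, height)
  list(x0 = px$pos, y0 = py$pos, exited = !(px$fits && py$fits))
}

# Line coordinate (um) at arc position s (um along the run).
line_coord <- function(s, s_rev) {
  if (is.na(s_rev)) s else ifelse(s < s_rev, s, 2 * s_rev - s)
}

#' Render a diffraction-limited punctum
#'
#' Returns the additive photon image patch of a point emitter at a subpixel
#' position: an isotropic 2D Gaussian of sigma `psf_sigma`, integrated over
#' pixel areas, whose total photon count is
#' `n_fluorophores * photons_per_fluorophore` (up to the <1% truncation of
#' the finite rendering window of half-width `ceiling(3 * psf_sigma)` px).
#' The integral is conserved independent of the subpixel offset.
#'
#' @param position Numeric `c(x, y)` in pixels (0-based, pixel centers at
#'   integer coordinates).
#' @param n_fluorophores Number of active fluorophores (>= 0).
#' @param config A [simulation_config()].
#' @return A list with `patch` (photon matrix, rows = y), and `x0`, `y0`,
#'   the 0-based pixel coordinates of the patch's top-left pixel.
#' @export
render_punctum <- function(position, n_fluorophores, config) {
  stopifnot(length(position) == 2, n_fluorophores >= 0)
  x <- position[1]; y <- position[2]
  h <- ceiling(3 * config$psf_sigma)
  cx <- round(x); cy <- round(y)
  xs <- (cx - h):(cx + h)
  ys <- (cy - h):(cy + h)
  if (n_fluorophores == 0) {
    patch <- matrix(0, length(ys), length(xs))
  } else {
    s <- config$psf_sigma
    wx <- stats::pnorm(xs + 0.5, x, s) - stats::pnorm(xs - 0.5, x, s)
    wy <- stats::pnorm(ys + 0.5, y, s) - stats::pnorm(ys - 0.5, y, s)
    patch <- (n_fluorophores * config$photons_per_fluorophore) * outer(wy, wx)
  }
  list(patch = patch, x0 = cx - h, y0 = cy - h)
}

# Add a punctum patch into a photon image (matrix rows = y, 0-based coords),
# clipping at the image edge.
add_punctum <- function(img, position, n_fluorophores, config) {
  p <- render_punctum(position, n_fluorophores, config)
  nr <- nrow(img); nc <- ncol(img)
  ys <- p$y0 + seq_len(nrow(p$patch)) - 1L
  xs <- p$x0 + seq_len(ncol(p$patch)) - 1L
  keep_y <- ys >= 0 & ys <= nr - 1
  keep_x <- xs >= 0 & xs <= nc - 1
  if (!any(keep_y) || !any(keep_x)) return(img)
  img[ys[keep_y] + 1L, xs[keep_x] + 1L] <-
    img[ys[keep_y] + 1L, xs[keep_x] + 1L] + p$patch[keep_y, keep_x]
  img
}

#' Simulate a TIRFM movie with ground truth
#'
#' Generates the latent particles of every population, samples initial
#' fluorophore counts from each population's copy-number model, draws
#' independent exponential photobleaching times per fluorophore, renders
#' every frame as background plus Gaussian puncta, and applies camera noise:
#' `ADU = Poisson(photons) * gain + offset + Normal(0, read_noise_sd)`,
#' clipped at zero. Identical seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @param noise If `FALSE`, return the noise-free expected image
#'   (`photons * gain + offset`), useful for photon-conservation checks.
#' @return A list with `movie` (a `tirfm_movie`: `height x width x n_frames`
#'   array with `pixel_size`/`frame_interval` attributes) and `ground_truth`
#'   (a `ground_truth` object: `$particles` one row per particle, and
#'   `$positions` per-frame subpixel positions and surviving-fluorophore
#'   counts for frames where the particle is present in the field).
#' @export
simulate_movie <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  W <- config$image_width; H <- config$image_height
  nf <- config$n_frames; dt <- config$frame_interval
  duration <- (nf - 1) * dt

  parts <- list(); k <- 0L
  for (spec in config$populations) {
    for (i in seq_len(spec$count)) {
      k <- k + 1L
      if (spec$kind == "stationary") {
        row <- data.frame(kind = "stationary", velocity_um_s = 0,
                          run_length_um = 0, true_run_time_s = duration,
                          reversal_s_um = NA_real_, n_reversals = 0L,
                          theta = 0, t0_s = 0,
                          x0 = stats::runif(1, 4, W - 5),
                          y0 = stats::runif(1, 4, H - 5), exited = FALSE)
      } else {
        row <- sample_run(spec, config)
      }
      row$id <- k
      row$n_fluorophores_initial <- draw_copy_number(spec$copy_number, 1)
      parts[[k]] <- row
    }
  }
  if (length(parts) == 0) {
    particles <- empty_particle_table()
  } else {
    particles <- do.call(rbind, parts)
  }
  n_part <- nrow(particles)

  # Per-fluorophore bleach times (from illumination start at t = 0).
  bleach_of <- vector("list", n_part)
  dark_time <- rep(Inf, n_part)
  for (i in seq_len(n_part)) {
    n0 <- particles$n_fluorophores_initial[i]
    bt <- if (config$bleach_rate > 0 && n0 > 0)
      stats::rexp(n0, config$bleach_rate) else rep(Inf, n0)
    bleach_of[[i]] <- bt
    dark_time[i] <- if (n0 > 0) max(bt) else 0
  }

  # Per-frame positions (frame midpoint sampling) and presence.
  pos_rows <- vector("list", n_part)
  observed_rt <- numeric(n_part)
  for (i in seq_len(n_part)) {
    p <- particles[i, ]
    t_end_true <- p$t0_s + p$true_run_time_s
    times <- (seq_len(nf) - 1) * dt
    if (p$kind == "stationary") {
      present <- rep(TRUE, nf)
      x <- rep(p$x0, nf); y <- rep(p$y0, nf)
    } else {
      present <- times >= p$t0_s & times <= t_end_true
      s_um <- (times - p$t0_s) * p$velocity_um_s
      lc <- line_coord(s_um, p$reversal_s_um) / config$pixel_size
      x <- p$x0 + cos(p$theta) * lc
      y <- p$y0 + sin(p$theta) * lc
    }
    inside <- x >= 0 & x <= W - 1 & y >= 0 & y <= H - 1
    # once a moving particle leaves the field it is censored (no re-entry)
    if (p$kind != "stationary") {
      out_frames <- which(present & !inside)
      if (length(out_frames)) present[present & seq_len(nf) >= min(out_frames)] <- FALSE
    }
    keep <- which(present & inside)
    n_active <- vapply(times[keep], function(tt) sum(bleach_of[[i]] > tt),
                       integer(1))
    pos_rows[[i]] <- data.frame(id = rep(p$id, length(keep)), frame = keep,
                                time_s = times[keep],
                                x = x[keep], y = y[keep],
                                n_active = n_active)
    # observed run time: censored by field exit, movie end and full bleach
    if (p$kind == "stationary") {
      observed_rt[i] <- duration
    } else {
      t_exit <- if (length(keep)) times[max(keep)] else p$t0_s
      t_obs_end <- min(t_end_true, duration, t_exit,
                       if (is.finite(dark_time[i])) dark_time[i] else Inf)
      observed_rt[i] <- max(0, t_obs_end - p$t0_s)
    }
  }
  positions <- if (n_part) do.call(rbind, pos_rows) else
    data.frame(id = integer(), frame = integer(), time_s = numeric(),
               x = numeric(), y = numeric(), n_active = integer())
  particles$observed_run_time_s <- observed_rt

  # Render frames.
  frames <- array(0, dim = c(H, W, nf))
  for (f in seq_len(nf)) {
    photons <- matrix(config$background_photons, H, W)
    rows <- positions[positions$frame == f & positions$n_active > 0, ]
    for (j in seq_len(nrow(rows))) {
      photons <- add_punctum(photons, c(rows$x[j], rows$y[j]),
                             rows$n_active[j], config)
    }
    if (noise) {
      adu <- stats::rpois(length(photons), photons) * config$camera_gain +
        config$camera_offset +
        stats::rnorm(length(photons), 0, config$read_noise_sd)
    } else {
      adu <- photons * config$camera_gain + config$camera_offset
    }
    frames[, , f] <- pmax(matrix(adu, H, W), 0)
  }

  movie <- structure(frames, pixel_size = config$pixel_size,
                     frame_interval = config$frame_interval,
                     class = "tirfm_movie")
  gt <- structure(list(particles = particles, positions = positions),
                  class = "ground_truth")
  list(movie = movie, ground_truth = gt)
}

empty_particle_table <- function() {
  data.frame(kind = character(), velocity_um_s = numeric(),
             run_length_um = numeric(), true_run_time_s = numeric(),
             reversal_s_um = numeric(), n_reversals = integer(),
             theta = numeric(), t0_s = numeric(), x0 = numeric(),
             y0 = numeric(), exited = logical(), id = integer(),
             n_fluorophores_initial = integer())
}

#' @export
print.tirfm_movie <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<tirfm_movie> %d x %d px, %d frames, %.3f um/px, %.2f s/frame\n",
              d[2], d[1], d[3], attr(x, "pixel_size"),
              attr(x, "frame_interval")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d particles (%s)\n", nrow(x$particles),
              paste(names(table(x$particles$kind)),
                    table(x$particles$kind), sep = ":", collapse = ", ")))
  invisible(x)
}
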