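# Shared fixture builders: everything is generated in code at test time.

tiny_config <- function(..., populations = list(), rng_seed = 1L) {
  defaults <- list(image_width = 64, image_height = 64, n_frames = 30,
                   background_photons = 10, read_noise_sd = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config,
          c(args, list(populations = populations, rng_seed = rng_seed)))
}

# A movie built deterministically from explicit punctum positions:
# `track` is a data.frame with columns frame, x, y, n (fluorophores).
manual_movie <- function(track, config, constant = 0) {
  H <- config$image_height; W <- config$image_width
  frames <- array(constant, dim = c(H, W, config$n_frames))
  for (i in seq_len(nrow(track))) {
    f <- track$frame[i]
    frames[, , f] <- kymotrace:::add_punctum(frames[, , f],
                                             c(track$x[i], track$y[i]),
                                             track$n[i], config)
  }
  structure(frames, pixel_size = config$pixel_size,
            frame_interval = config$frame_interval, class = "tirfm_movie")
}

constant_movie <- function(value, width = 32, height = 32, n_frames = 10,
                           pixel_size = 0.13, frame_interval = 0.2) {
  structure(array(value, dim = c(height, width, n_frames)),
            pixel_size = pixel_size, frame_interval = frame_interval,
            class = "tirfm_movie")
}

# A bare kymograph object with given values (frames x samples).
manual_kymo <- function(values, pixel_size = 0.13, frame_interval = 0.2,
                        sample_step = 1) {
  structure(list(values = values, sample_step = sample_step,
                 line_width = 5L, pixel_size = pixel_size,
                 frame_interval = frame_interval, reducer = "max",
                 path = kymo_path(c(0, ncol(values) - 1), c(0, 0),
                                  pixel_size = pixel_size)),
            class = "kymograph")
}
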