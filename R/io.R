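# Movie and table I/O: 16-bit multi-page TIFF for movies, CSV for paths
# and results.

#' Read and write TIRFM movies as multi-page 16-bit TIFF
#'
#' Movies are stored as one 16-bit page per frame. Because baseline TIFF
#' carries no physical calibration, `pixel_size` (um/px) and
#' `frame_interval` (s) are written to a JSON sidecar
#' (`<path>.meta.json`); on read they are taken from the sidecar unless
#' supplied explicitly.
#'
#' @param movie A `tirfm_movie` (see [simulate_movie()]).
#' @param path File path.
#' @param pixel_size,frame_interval Physical calibration to attach on read
#'   (overrides the sidecar).
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a `tirfm_movie`.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "tirfm_movie"))
  nf <- dim(movie)[3]
  scaled <- pmin(pmax(movie, 0), 65535) / 65535
  pages <- lapply(seq_len(nf), function(f) scaled[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = attr(movie, "pixel_size"),
         frame_interval_s = attr(movie, "frame_interval")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (is.null(pixel_size)) pixel_size <- meta$pixel_size_um
    if (is.null(frame_interval)) frame_interval <- meta$frame_interval_s
  }
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("pixel_size and frame_interval must be supplied ",
         "(no calibration sidecar found)")
  frames <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                             length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * 65535
  structure(frames, pixel_size = pixel_size,
            frame_interval = frame_interval, class = "tirfm_movie")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the [simulation_config()] arguments; `populations` is a
#' list of entries with `kind`, `count`, the motility parameters, and a
#' `copy_number` block: `{model: fixed, k: 2}` or
#' `{model: binomial, n_subunits: 4, p_tag: 0.5}` (named to avoid the
#' YAML 1.1 boolean interpretation of a bare `n`/`p` key).
#'
#' @param file Path to a `.yaml`/`.yml`/`.json` configuration.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(file) {
  raw <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  pops <- lapply(raw$populations, function(p) {
    cm <- p$copy_number
    copy_model <- if (is.null(cm)) copy_fixed(1)
      else if (identical(cm$model, "fixed")) copy_fixed(cm$k)
      else if (identical(cm$model, "binomial"))
        copy_binomial(cm$n_subunits, cm$p_tag)
      else stop("unknown copy_number model: ", cm$model)
    do.call(population_spec,
            c(p[setdiff(names(p), "copy_number")],
              list(copy_number = copy_model)))
  })
  args <- raw[setdiff(names(raw), "populations")]
  do.call(simulation_config, c(args, list(populations = pops)))
}

#' Read and write polyline paths as CSV
#'
#' Path CSVs have a header and columns `x`, `y` (pixels, 0-based, pixel
#' centers at integer coordinates).
#'
#' @param path_obj A `kymo_path` (see [kymo_path()]).
#' @param file File path.
#' @param pixel_size um/px calibration to attach on read.
#' @export
write_path_csv <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "kymo_path"))
  utils::write.csv(data.frame(x = path_obj$x, y = path_obj$y), file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_path_csv
#' @export
read_path_csv <- function(file, pixel_size) {
  d <- utils::read.csv(file)
  if (!all(c("x", "y") %in% names(d)))
    stop("path CSV must have columns 'x' and 'y'")
  kymo_path(d$x, d$y, pixel_size = pixel_size)
}
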