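# Kymograph extraction along polyline paths.
#
# A kymograph maps intensity along a traced path (distance axis) against
# time (frame axis). Paths are traced with a finite line width; at each
# arc-length sample the intensities at perpendicular offsets across the
# width are reduced to one value (maximum by default, mean optionally).

#' Construct a polyline path
#'
#' @param x,y Vertex coordinates in pixels (0-based, pixel centers at
#'   integer coordinates). At least two vertices; consecutive vertices must
#'   be distinct.
#' @param pixel_size Pixel size, um/px.
#' @return A `kymo_path` object.
#' @export
kymo_path <- function(x, y, pixel_size) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2) stop("a path needs at least 2 vertices")
  stopifnot(pixel_size > 0)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  if (any(seg == 0)) stop("consecutive path vertices must be distinct")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 pixel_size = pixel_size),
            class = "kymo_path")
}

#' Path length in micrometers
#'
#' Sum of Euclidean vertex-to-vertex distances times the pixel size.
#'
#' @param path A [kymo_path()].
#' @return Length in um.
#' @examples
#' path_length(kymo_path(c(0, 3), c(0, 4), pixel_size = 1))  # 5
#' @export
path_length <- function(path) {
  stopifnot(inherits(path, "kymo_path"))
  sum(sqrt(diff(path$x)^2 + diff(path$y)^2)) * path$pixel_size
}

# Arc-length parameterization: position and unit tangent at arc s (px).
path_interp <- function(path, s) {
  segdx <- diff(path$x); segdy <- diff(path$y)
  seglen <- sqrt(segdx^2 + segdy^2)
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(seglen))
  frac <- (s - cum[idx]) / seglen[idx]
  list(x = path$x[idx] + frac * segdx[idx],
       y = path$y[idx] + frac * segdy[idx],
       tx = segdx[idx] / seglen[idx],
       ty = segdy[idx] / seglen[idx])
}

# Vectorized bilinear interpolation with clamp-to-edge. img rows = y,
# coordinates 0-based pixel centers. Returns values and whether any
# coordinate was clamped.
bilinear_interp <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  clamped <- any(x < 0 | x > nc - 1 | y < 0 | y > nr - 1)
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2); y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1          # column-major linear index
  v <- img[i00]       * (1 - fx) * (1 - fy) +
       img[i00 + nr]  * fx       * (1 - fy) +
       img[i00 + 1]   * (1 - fx) * fy +
       img[i00 + nr + 1] * fx    * fy
  list(values = v, clamped = clamped)
}

#' Extract a kymograph along a path
#'
#' For each frame and each arc-length sample point along the path, samples
#' the movie at `line_width` perpendicular offsets (bilinear interpolation,
#' clamp-to-edge outside the image) and reduces them across the width.
#' Sample points are spaced evenly with `n_samples = ceiling(L / sample_step)
#' + 1` over the path length `L` (px), so both endpoints are sampled and the
#' distance axis flips exactly under path reversal.
#'
#' @param movie A `tirfm_movie`.
#' @param path A [kymo_path()].
#' @param line_width Width across the path in pixels; odd, default 5.
#' @param reducer `"max"` (default; robust to a path slightly off the
#'   particle center) or `"mean"`.
#' @param sample_step Arc-length sampling step, px (default 1).
#' @return A `kymograph`: list with `values` (`n_frames x n_samples`
#'   matrix, time on axis 1), `sample_step` (actual step, px),
#'   `line_width`, `pixel_size`, `frame_interval`, and the `path`.
#' @export
extract_kymograph <- function(movie, path, line_width = 5,
                              reducer = c("max", "mean"), sample_step = 1) {
  stopifnot(inherits(movie, "tirfm_movie"), inherits(path, "kymo_path"))
  reducer <- match.arg(reducer)
  if (line_width < 1 || line_width %% 2 == 0)
    stop("line_width must be odd and >= 1")
  nf <- dim(movie)[3]
  if (nf < 1) stop("empty movie")

  total <- sum(sqrt(diff(path$x)^2 + diff(path$y)^2))
  n_samples <- ceiling(total / sample_step) + 1
  s <- seq(0, total, length.out = n_samples)
  actual_step <- if (n_samples > 1) total / (n_samples - 1) else sample_step

  pp <- path_interp(path, s)
  offsets <- seq(-(line_width - 1) / 2, (line_width - 1) / 2)
  # perpendicular = (-ty, tx)
  xs <- matrix(pp$x, n_samples, line_width) - outer(pp$ty, offsets)
  ys <- matrix(pp$y, n_samples, line_width) + outer(pp$tx, offsets)

  values <- matrix(0, nf, n_samples)
  clamped <- FALSE
  for (f in seq_len(nf)) {
    bi <- bilinear_interp(movie[, , f], as.vector(xs), as.vector(ys))
    clamped <- clamped || bi$clamped
    m <- matrix(bi$values, n_samples, line_width)
    values[f, ] <- if (reducer == "max") do.call(pmax, asplit(m, 2))
                   else rowMeans(m)
  }
  if (clamped)
    warning("kymograph samples outside the image were clamped to the edge")

  structure(list(values = values, sample_step = actual_step,
                 line_width = as.integer(line_width),
                 pixel_size = path$pixel_size,
                 frame_interval = attr(movie, "frame_interval"),
                 reducer = reducer, path = path),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "<kymograph> %d frames x %d samples (step %.3f px, width %d, %s)\n",
    nrow(x$values), ncol(x$values), x$sample_step, x$line_width, x$reducer))
  invisible(x)
}
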