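# Segmentation and measurement of motility events on kymographs.
#
# A motile punctum appears on a kymograph as a sloped ridge. Ridges are
# detected per frame as local maxima above a robust noise threshold,
# linked frame-to-frame into traces, and measured: velocity from the
# start-to-end slope, run time from the spanned frames, run length as
# velocity times run time, and directional switches from sign changes of
# the displacement with resolvable arms.

#' Construct a kymograph trace
#'
#' A trace is an ordered set of (frame, distance-sample) ridge points with
#' subpixel-refined distances. Frame indices are strictly increasing.
#'
#' @param frames Integer frame indices (1-based rows of the kymograph).
#' @param dist Subpixel distance coordinates in sample units.
#' @return A `kymo_trace` object.
#' @export
kymo_trace <- function(frames, dist) {
  stopifnot(length(frames) == length(dist), length(frames) >= 2)
  if (any(diff(frames) <= 0)) stop("frame indices must be strictly increasing")
  structure(list(frames = as.integer(frames), dist = as.numeric(dist)),
            class = "kymo_trace")
}

#' Run time from start and end frames
#'
#' @param start_frame,end_frame Frame indices (`end_frame > start_frame`).
#' @param frame_interval Time between frames, s (> 0).
#' @return Run time in seconds: `(end_frame - start_frame) * frame_interval`.
#' @examples
#' run_time(3, 16, 0.2)  # 2.6
#' @export
run_time <- function(start_frame, end_frame, frame_interval) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (end_frame <= start_frame)
    stop("end_frame must be greater than start_frame")
  (end_frame - start_frame) * frame_interval
}

#' Run length as velocity times run time
#'
#' @param velocity Speed in um/s (>= 0).
#' @param run_time Run time in s (>= 0).
#' @return Run length in um.
#' @examples
#' run_length(1.2, 2.6)  # 3.12
#' @export
run_length <- function(velocity, run_time) {
  stopifnot(velocity >= 0, run_time >= 0)
  velocity * run_time
}

#' Measure velocity from a trace
#'
#' Default is the endpoint (start-to-end) slope, the kymograph "single
#' line" measurement: absolute net displacement divided by elapsed time.
#' A least-squares slope over all trace points is available as an option;
#' the two agree exactly for perfectly linear traces.
#'
#' @param trace A [kymo_trace()].
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param sample_step Kymograph sampling step in px (default 1).
#' @param method `"endpoint"` (default) or `"lsq"`.
#' @return Unsigned speed in um/s. The sign of the net displacement is
#'   attached as attribute `"direction"` (+1, -1, or 0).
#' @export
measure_velocity <- function(trace, pixel_size, frame_interval,
                             sample_step = 1,
                             method = c("endpoint", "lsq")) {
  stopifnot(inherits(trace, "kymo_trace"))
  method <- match.arg(method)
  elapsed <- (trace$frames[length(trace$frames)] - trace$frames[1]) *
    frame_interval
  if (elapsed <= 0) stop("trace spans zero elapsed time")
  if (method == "endpoint") {
    disp <- (trace$dist[length(trace$dist)] - trace$dist[1]) *
      sample_step * pixel_size
    v <- disp / elapsed
  } else {
    fit <- stats::lm.fit(cbind(1, trace$frames * frame_interval),
                         trace$dist * sample_step * pixel_size)
    v <- fit$coefficients[2]
  }
  structure(abs(v), direction = sign(unname(v)), names = NULL)
}

#' Measure velocity of a kymograph trace in physical units
#'
#' Convenience wrapper taking calibration from a [extract_kymograph()]
#' result.
#' @param trace A [kymo_trace()].
#' @param kymo A `kymograph`.
#' @param method Passed to [measure_velocity()].
#' @export
trace_velocity <- function(trace, kymo, method = "endpoint") {
  measure_velocity(trace, pixel_size = kymo$pixel_size,
                   frame_interval = kymo$frame_interval,
                   sample_step = kymo$sample_step, method = method)
}

# Drop first/last trace points whose step is grossly inconsistent with the
# trace's median step (spurious detections linked at the ends corrupt the
# endpoint slope). At most two points per end.
trim_endpoint_outliers <- function(frames, dist) {
  for (pass in 1:2) {
    n <- length(frames)
    if (n < 4) break
    steps <- abs(diff(dist) / diff(frames))
    med <- stats::median(steps)
    lim <- max(2, 3 * med)
    if (steps[1] > lim) { frames <- frames[-1]; dist <- dist[-1] }
    else if (steps[n - 1] > lim) { frames <- frames[-n]; dist <- dist[-n] }
    else break
  }
  list(frames = frames, dist = dist)
}

# Restrict a trace to its longest stretch of evident movement: central
# per-point slopes at or above `step_thr` (samples/frame), allowing
# internal pauses of up to `max_gap` points (covers the apex of a
# directional switch). This is the automated counterpart of defining the
# start and end frame of evident movement by eye, and it detaches runs
# from stationary puncta their trace may have been linked onto.
trim_to_motion <- function(frames, dist, step_thr, max_gap = 3) {
  n <- length(frames)
  if (n < 3) return(list(frames = frames, dist = dist))
  ip <- c(2:n, n); im <- c(1, 1:(n - 1))
  v <- (dist[ip] - dist[im]) / (frames[ip] - frames[im])
  moving <- which(abs(v) >= step_thr)
  if (!length(moving)) return(list(frames = frames[0], dist = dist[0]))
  # longest run of moving indices with gaps <= max_gap between them
  brk <- c(0, which(diff(moving) > max_gap + 1), length(moving))
  lens <- diff(brk)
  k <- which.max(lens)
  sel <- moving[(brk[k] + 1):brk[k + 1]]
  keep <- sel[1]:sel[length(sel)]
  list(frames = frames[keep], dist = dist[keep])
}

# Parabolic subpixel refinement of an argmax at index i of vector v.
refine_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(i)
  d <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  i + max(-0.5, min(0.5, d))
}

#' Detect traces on a kymograph
#'
#' Per-frame ridge candidates are local maxima exceeding
#' `median + snr_threshold * MAD` of the kymograph (robust background and
#' noise scale), with parabolic subpixel refinement. Candidates are linked
#' greedily frame to frame within a maximum per-frame displacement gate;
#' a trace may bridge up to `max_gap_frames` frames without a detection
#' (a dim punctum can drop below threshold for a single frame by shot
#' noise), after which a punctum that stays missing ends its trace --
#' censoring runs at photobleaching or field exit. Each linked trace is
#' then trimmed to
#' its evident movement: endpoint points whose step is grossly inconsistent
#' with the trace's median step are dropped, and the trace is restricted to
#' its longest stretch of sustained motion (instantaneous slope at or above
#' half of `min_speed`, allowing pauses of up to 3 points so the apex of a
#' directional switch is retained) -- the automated counterpart of scoring
#' the start and end frame of evident movement by eye, which also detaches
#' a run from a stationary punctum its trace drifted onto. Traces spanning
#' fewer than
#' `min_run_frames` frame intervals, or with endpoint speed below
#' `min_speed`, are discarded -- the automated stand-in for scoring only
#' evident motile puncta, and the filter that excludes the immobile
#' cortical pool.
#'
#' @param kymo A `kymograph`.
#' @param min_run_frames Minimum spanned frame intervals (default 3; 0.6 s
#'   at 5 fps).
#' @param min_speed Minimum endpoint speed in um/s (default 0.2).
#' @param snr_threshold Detection threshold in robust-noise units
#'   (default 4; high enough that isolated noise excursions rarely attach
#'   to the ends of real traces, while a single-fluorophore punctum is
#'   still well above threshold).
#' @param link_gate Maximum per-frame displacement for linking, in samples
#'   (default 4; about 2.6 um/s at 0.13 um/px and 5 fps).
#' @param min_reversal_length Arm threshold (um) used when judging the
#'   speed of a trace that contains a direction change: the speed filter
#'   uses the dominant-arm velocity (see [measure_trace()]), so a
#'   V-shaped switching run with near-zero net displacement is not
#'   mistaken for a stationary punctum.
#' @param max_gap_frames Frames a trace may go undetected before it is
#'   closed (default 1; the linking gate grows proportionally across a
#'   gap).
#' @return List of [kymo_trace()] objects (possibly empty).
#' @export
detect_traces <- function(kymo, min_run_frames = 3, min_speed = 0.2,
                          snr_threshold = 4, link_gate = 4,
                          min_reversal_length = 0.5, max_gap_frames = 1) {
  stopifnot(inherits(kymo, "kymograph"))
  V <- kymo$values
  if (length(V) == 0) return(list())
  thr <- stats::median(V) + snr_threshold * stats::mad(V)

  n_frames <- nrow(V); n_samples <- ncol(V)
  active <- list()   # each: list(frames, dist, last)
  done <- list()
  for (f in seq_len(n_frames)) {
    v <- V[f, ]
    cand <- which(v > thr)
    if (length(cand) && n_samples >= 3) {
      is_max <- vapply(cand, function(i) {
        (i == 1 || v[i] >= v[i - 1]) && (i == n_samples || v[i] >= v[i + 1])
      }, logical(1))
      cand <- cand[is_max]
    }
    # 0-based subpixel sample coordinate (column i holds arc sample i-1)
    cand_pos <- vapply(cand, function(i) refine_peak(v, i) - 1, numeric(1))

    matched_cand <- rep(FALSE, length(cand_pos))
    next_active <- list()
    if (length(active)) {
      # greedy nearest-pair assignment under the gate (gate scales with
      # the number of frames skipped across a gap)
      for (a in order(vapply(active, function(tr) tr$last, numeric(1)))) {
        tr <- active[[a]]
        skipped <- f - tr$frames[length(tr$frames)]
        if (length(cand_pos)) {
          dists <- abs(cand_pos - tr$last)
          dists[matched_cand] <- Inf
          j <- which.min(dists)
          if (length(j) && is.finite(dists[j]) &&
              dists[j] <= link_gate * skipped) {
            matched_cand[j] <- TRUE
            tr$frames <- c(tr$frames, f)
            tr$dist <- c(tr$dist, cand_pos[j])
            tr$last <- cand_pos[j]
            next_active[[length(next_active) + 1]] <- tr
            next
          }
        }
        if (skipped <= max_gap_frames) {
          next_active[[length(next_active) + 1]] <- tr
        } else {
          done[[length(done) + 1]] <- tr
        }
      }
    }
    for (j in which(!matched_cand)) {
      next_active[[length(next_active) + 1]] <-
        list(frames = f, dist = cand_pos[j], last = cand_pos[j])
    }
    active <- next_active
  }
  done <- c(done, active)

  # samples/frame corresponding to min_speed, used as the evident-motion
  # floor for trimming
  step_thr <- 0.5 * min_speed * kymo$frame_interval /
    (kymo$pixel_size * kymo$sample_step)
  out <- list()
  for (tr in done) {
    if (length(tr$frames) < 2) next
    tt <- trim_endpoint_outliers(tr$frames, tr$dist)
    tt <- trim_to_motion(tt$frames, tt$dist, step_thr)
    if (length(tt$frames) < 2) next
    span <- tt$frames[length(tt$frames)] - tt$frames[1]
    if (span < min_run_frames) next
    trace <- kymo_trace(tt$frames, tt$dist)
    speed <- measure_trace(trace, kymo,
                           min_reversal_length = min_reversal_length
                           )$velocity_um_s
    if (speed < min_speed) next
    out[[length(out) + 1]] <- trace
  }
  out
}

#' Count directional switches in a trace
#'
#' Counts sign changes of the displacement between monotone segments of the
#' trace where each flanking segment's net displacement is at least
#' `min_reversal_length`. Implemented as a hysteresis (zigzag) walk: a
#' switch is scored each time the position retreats from its running
#' extreme by at least the threshold, which guarantees both arms of every
#' counted switch meet the minimum length.
#'
#' @param trace A [kymo_trace()].
#' @param min_reversal_length Minimum arm length in um (default 0.5).
#' @param pixel_size um/px.
#' @param sample_step Kymograph sample step, px (default 1).
#' @return Integer switch count (>= 0).
#' @export
count_reversals <- function(trace, min_reversal_length = 0.5,
                            pixel_size, sample_step = 1) {
  stopifnot(inherits(trace, "kymo_trace"))
  pos <- trace$dist * sample_step * pixel_size
  length(zigzag_pivots(pos, min_reversal_length))
}

# Indices of confirmed direction-change pivots of a position series under a
# hysteresis threshold: a pivot is scored when the series retreats from its
# running extreme by >= thr, so both arms of every pivot have net
# displacement >= thr.
zigzag_pivots <- function(pos, thr) {
  pivots <- integer(0)
  dir <- 0L
  hi <- pos[1]; lo <- pos[1]
  hi_i <- 1L; lo_i <- 1L
  for (k in seq_along(pos)[-1]) {
    p <- pos[k]
    if (dir == 0L) {
      if (p > hi) { hi <- p; hi_i <- k }
      if (p < lo) { lo <- p; lo_i <- k }
      if (p - lo >= thr) { dir <- 1L; hi <- p; hi_i <- k }
      else if (hi - p >= thr) { dir <- -1L; lo <- p; lo_i <- k }
    } else if (dir == 1L) {
      if (p > hi) { hi <- p; hi_i <- k }
      if (hi - p >= thr) {
        pivots <- c(pivots, hi_i); dir <- -1L; lo <- p; lo_i <- k
      }
    } else {
      if (p < lo) { lo <- p; lo_i <- k }
      if (p - lo >= thr) {
        pivots <- c(pivots, lo_i); dir <- 1L; hi <- p; hi_i <- k
      }
    }
  }
  pivots
}

#' Measure one trace: velocity, run time, run length, switches
#'
#' Run time spans the whole trace (start to end of evident movement).
#' Velocity is the endpoint slope; for traces containing a direction
#' change it is measured on the dominant monotone arm (largest net
#' displacement between turning points), since the start-to-end net slope
#' of a V-shaped event is not the speed of either arm. Turning points for
#' measurement are found at half of `min_reversal_length`, so that a
#' switch whose second arm was censored just below the scoring threshold
#' still does not corrupt the speed; scoring of `n_reversals` uses the
#' full threshold. Run length is velocity times run time.
#'
#' @param trace A [kymo_trace()].
#' @param kymo The `kymograph` the trace was detected on.
#' @param min_reversal_length Minimum switch arm length for scoring a
#'   directional switch, um.
#' @return A one-row data frame: `velocity_um_s`, `direction`,
#'   `run_time_s`, `run_length_um`, `n_reversals`, `start_frame`,
#'   `end_frame`.
#' @export
measure_trace <- function(trace, kymo, min_reversal_length = 0.5) {
  stopifnot(inherits(trace, "kymo_trace"), inherits(kymo, "kymograph"))
  n <- length(trace$frames)
  pos_um <- trace$dist * kymo$sample_step * kymo$pixel_size
  seg_pivots <- zigzag_pivots(pos_um, min_reversal_length / 2)
  if (length(seg_pivots) == 0) {
    v <- trace_velocity(trace, kymo)
  } else {
    bounds <- c(1L, seg_pivots, n)
    arm_disp <- abs(diff(pos_um[bounds]))
    k <- which.max(arm_disp)
    seg <- bounds[k]:bounds[k + 1]
    v <- measure_velocity(kymo_trace(trace$frames[seg], trace$dist[seg]),
                          pixel_size = kymo$pixel_size,
                          frame_interval = kymo$frame_interval,
                          sample_step = kymo$sample_step)
  }
  rt <- run_time(trace$frames[1], trace$frames[n], kymo$frame_interval)
  data.frame(velocity_um_s = as.numeric(v),
             direction = attr(v, "direction"),
             run_time_s = rt,
             run_length_um = run_length(as.numeric(v), rt),
             n_reversals = length(zigzag_pivots(pos_um,
                                                min_reversal_length)),
             start_frame = trace$frames[1],
             end_frame = trace$frames[n])
}

#' Tabulate measured runs from traces
#'
#' @param traces List of [kymo_trace()] objects.
#' @param kymo The `kymograph` they came from (for calibration).
#' @param min_reversal_length Passed to [count_reversals()], um.
#' @return A data frame with one row per run: `velocity_um_s` (unsigned),
#'   `direction`, `run_time_s`, `run_length_um`, `n_reversals`,
#'   `start_frame`, `end_frame`.
#' @export
runs_table <- function(traces, kymo, min_reversal_length = 0.5) {
  rows <- lapply(traces, measure_trace, kymo = kymo,
                 min_reversal_length = min_reversal_length)
  if (!length(rows)) {
    return(data.frame(velocity_um_s = numeric(), direction = numeric(),
                      run_time_s = numeric(), run_length_um = numeric(),
                      n_reversals = integer(), start_frame = integer(),
                      end_frame = integer()))
  }
  do.call(rbind, rows)
}
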