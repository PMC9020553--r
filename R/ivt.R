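#' Fill short gaps of invalid samples by linear interpolation
#'
#' Gaps no longer than `max_gap` seconds are filled by linear
#' interpolation of x and y between the flanking valid samples; longer
#' gaps are left invalid and break velocity computation and event
#' classification.
#'
#' @param recording A [gaze_recording()].
#' @param max_gap Longest gap (seconds) to interpolate across.
#' @return A [gaze_recording()] with filled samples marked valid.
#' @export
fill_gaps <- function(recording, max_gap = 0.075) {
  valid <- recording$valid
  if (all(valid) || !any(valid)) return(recording)
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  x <- recording$x; y <- recording$y
  for (j in seq_along(r$values)) {
    if (r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    if (i0 == 1 || i1 == length(valid)) next   # leading/trailing gap
    span <- recording$t[i1 + 1] - recording$t[i0 - 1]
    if (span > max_gap) next
    ti <- recording$t[i0:i1]
    w <- (ti - recording$t[i0 - 1]) / span
    x[i0:i1] <- x[i0 - 1] + w * (x[i1 + 1] - x[i0 - 1])
    y[i0:i1] <- y[i0 - 1] + w * (y[i1 + 1] - y[i0 - 1])
    valid[i0:i1] <- TRUE
  }
  gaze_recording(recording$t, x, y, valid, rate = sampling_rate(recording))
}

# Running 3-sample median within each contiguous valid run (endpoints
# untouched).  Used as an optional pre-filter for noisy recordings.
median3 <- function(z) {
  n <- length(z)
  if (n < 3) return(z)
  a <- z[1:(n - 2)]; b <- z[2:(n - 1)]; cc <- z[3:n]
  out <- z
  out[2:(n - 1)] <- pmax(pmin(a, b), pmin(pmax(a, b), cc))
  out
}

#' 3-sample median pre-filter
#'
#' Applies a running 3-sample median to x and y within each contiguous
#' run of valid samples.  A light positional noise reduction recommended
#' for recordings with per-sample noise; leaves saccade timing intact to
#' within one sample.
#'
#' @param recording A [gaze_recording()].
#' @return The filtered [gaze_recording()].
#' @export
median_filter3 <- function(recording) {
  x <- recording$x; y <- recording$y
  r <- rle(recording$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    idx <- starts[j]:ends[j]
    x[idx] <- median3(x[idx])
    y[idx] <- median3(y[idx])
  }
  gaze_recording(recording$t, x, y, recording$valid,
                 rate = sampling_rate(recording))
}

#' Point-to-point angular velocity
#'
#' Central-difference speed: `v_i` is the angular distance between
#' samples `i - 1` and `i + 1` divided by their time span.  Endpoints of
#' each contiguous valid run use a one-sided difference.  Samples inside
#' or adjacent to unfilled gaps get `NA`.
#'
#' @param recording A [gaze_recording()] (fill gaps first if desired).
#' @return A data.frame with columns `t` and `v` (deg/s, `NA` where
#'   undefined), one row per sample.
#' @export
compute_velocity <- function(recording) {
  n <- nrow(recording)
  v <- rep(NA_real_, n)
  if (n == 0 || !any(recording$valid)) {
    return(data.frame(t = recording$t, v = v))
  }
  r <- rle(recording$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    i0 <- starts[j]; i1 <- ends[j]
    m <- i1 - i0 + 1
    if (m < 2) next
    idx <- i0:i1
    x <- recording$x[idx]; y <- recording$y[idx]; tt <- recording$t[idx]
    vv <- numeric(m)
    if (m >= 3) {
      mid <- 2:(m - 1)
      vv[mid] <- angular_distance(x[mid - 1], y[mid - 1],
                                  x[mid + 1], y[mid + 1]) /
        (tt[mid + 1] - tt[mid - 1])
    }
    vv[1] <- angular_distance(x[1], y[1], x[2], y[2]) / (tt[2] - tt[1])
    vv[m] <- angular_distance(x[m - 1], y[m - 1], x[m], y[m]) /
      (tt[m] - tt[m - 1])
    v[idx] <- vv
  }
  data.frame(t = recording$t, v = v)
}

#' I-VT fixation/saccade classification
#'
#' Samples whose point-to-point velocity strictly exceeds `threshold`
#' (default 30 deg/s) are labelled saccadic, all others fixational; runs
#' of equal labels become events.  Post-processing follows conventional
#' I-VT practice: gaps up to `max_gap` are interpolated first; saccade
#' events shorter than `min_sacc_dur` or with a start-to-end displacement
#' below `min_sacc_amp` are reclassified as fixation (suppressing
#' noise-driven velocity spikes, which have near-zero net displacement);
#' adjacent fixation events are merged; and fixations shorter than
#' `min_fix_dur` are discarded (left unclassified).
#'
#' @param recording A [gaze_recording()].
#' @param threshold Velocity threshold, deg/s; strictly greater-than.
#' @param min_fix_dur Minimum fixation duration, seconds.
#' @param min_sacc_dur Minimum saccade duration, seconds.
#' @param min_sacc_amp Minimum saccade displacement, degrees (default
#'   1.5, five times the per-sample noise displacement scale at the
#'   default noise level and far below analysis-relevant saccades).  Set to 0
#'   to disable the displacement gate.
#' @param max_gap Longest invalid-sample gap (seconds) to interpolate.
#' @param median_filter Apply [median_filter3()] before velocity
#'   computation (recommended for noisy recordings).
#' @return A data.frame of class `oculomotor_events` with columns `kind`
#'   (fixation/saccade), `onset`, `offset` (seconds; offset is the end of
#'   the last sample period), `duration`, `amplitude` (start-to-end
#'   angular displacement, deg), `peak_velocity` (deg/s), onset/offset
#'   positions, fixation centroids, and `n_samples`.  Events are
#'   time-ordered and non-overlapping.
#' @export
classify_ivt <- function(recording, threshold = 30,
                         min_fix_dur = 0.060, min_sacc_dur = 0.010,
                         min_sacc_amp = 1.5, max_gap = 0.075,
                         median_filter = FALSE) {
  if (threshold <= 0) stop("velocity threshold must be positive")
  rec <- fill_gaps(recording, max_gap = max_gap)
  if (median_filter) rec <- median_filter3(rec)
  vel <- compute_velocity(rec)
  dt <- 1 / sampling_rate(rec)

  lab <- ifelse(is.na(vel$v), NA_character_,
                ifelse(vel$v > threshold, "saccade", "fixation"))
  if (all(is.na(lab))) return(empty_events())

  runs <- run_table(lab)
  # displacement gate + minimum saccade duration
  dur <- rec$t[runs$end] - rec$t[runs$start] + dt
  amp <- angular_distance(rec$x[runs$start], rec$y[runs$start],
                          rec$x[runs$end], rec$y[runs$end])
  demote <- !is.na(runs$kind) & runs$kind == "saccade" &
    (dur < min_sacc_dur | amp < min_sacc_amp)
  runs$kind[demote] <- "fixation"
  lab2 <- rep(runs$kind, runs$end - runs$start + 1)
  runs <- run_table(lab2)
  # drop too-short fixations (leave unclassified)
  dur <- rec$t[runs$end] - rec$t[runs$start] + dt
  keep <- !is.na(runs$kind) & !(runs$kind == "fixation" & dur < min_fix_dur)
  runs <- runs[keep, , drop = FALSE]
  if (nrow(runs) == 0) return(empty_events())

  i0 <- runs$start; i1 <- runs$end
  seg_stat <- function(z, f) {
    vapply(seq_along(i0), function(j) f(z[i0[j]:i1[j]]), numeric(1))
  }
  is_fix <- runs$kind == "fixation"
  out <- data.frame(
    kind = runs$kind,
    onset = rec$t[i0],
    offset = rec$t[i1] + dt,
    duration = rec$t[i1] - rec$t[i0] + dt,
    amplitude = angular_distance(rec$x[i0], rec$y[i0],
                                 rec$x[i1], rec$y[i1]),
    peak_velocity = seg_stat(vel$v, function(z) max(z, na.rm = TRUE)),
    x_onset = rec$x[i0], y_onset = rec$y[i0],
    x_offset = rec$x[i1], y_offset = rec$y[i1],
    centroid_x = ifelse(is_fix, seg_stat(rec$x, mean), NA_real_),
    centroid_y = ifelse(is_fix, seg_stat(rec$y, mean), NA_real_),
    n_samples = i1 - i0 + 1L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("oculomotor_events", "data.frame")
  out
}

empty_events <- function() {
  out <- data.frame(kind = character(), onset = numeric(),
                    offset = numeric(), duration = numeric(),
                    amplitude = numeric(), peak_velocity = numeric(),
                    x_onset = numeric(), y_onset = numeric(),
                    x_offset = numeric(), y_offset = numeric(),
                    centroid_x = numeric(), centroid_y = numeric(),
                    n_samples = integer())
  class(out) <- c("oculomotor_events", "data.frame")
  out
}

# Run-length table over a label vector; NA labels separate runs.
run_table <- function(lab) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  data.frame(kind = r$values, start = ends - r$lengths + 1, end = ends,
             stringsAsFactors = FALSE)
}
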