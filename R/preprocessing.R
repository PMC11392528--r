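# Run-length segmentation of a logical vector (NA treated as FALSE).
# Returns a data.frame of start/end indices of maximal TRUE runs.
logical_runs <- function(x) {
  x <- !is.na(x) & x
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Fill short tracking gaps in a pose series
#'
#' Positions (head origin and body centroid) are linearly interpolated and
#' orientations spherically interpolated (geodesic in SO(3)) across runs of
#' missing frames no longer than `max_gap_s`; longer gaps remain missing.
#' Observed frames are never modified.
#'
#' @param series A [pose_series()].
#' @param max_gap_s Longest gap to fill, seconds (default 0.2).
#' @return The series with short gaps filled and the mask updated.
#' @export
fill_gaps <- function(series, max_gap_s = 0.2) {
  stopifnot(max_gap_s > 0)
  max_frames <- round(max_gap_s * series$rate)
  gaps <- logical_runs(!series$valid)
  n <- length(series$t)
  for (g in seq_len(nrow(gaps))) {
    a <- gaps$start[g]; b <- gaps$end[g]
    if (a == 1 || b == n) next            # no anchor on one side
    if (b - a + 1 > max_frames) next
    i0 <- a - 1; i1 <- b + 1
    if (!series$valid[i0] || !series$valid[i1]) next
    f <- (seq(a, b) - i0) / (i1 - i0)
    for (j in 1:3)
      series$origin[a:b, j] <- series$origin[i0, j] +
        f * (series$origin[i1, j] - series$origin[i0, j])
    if (!is.null(series$body) &&
        !anyNA(series$body[i0, ]) && !anyNA(series$body[i1, ])) {
      for (j in 1:3)
        series$body[a:b, j] <- series$body[i0, j] +
          f * (series$body[i1, j] - series$body[i0, j])
    }
    R0 <- series$rotation[, , i0]; R1 <- series$rotation[, , i1]
    for (k in seq_along(f))
      series$rotation[, , a + k - 1] <- slerp_rotmat(R0, R1, f[k])
    series$valid[a:b] <- TRUE
  }
  series
}

#' Mask frames with implausible motion
#'
#' A frame is masked when both of its adjacent steps exceed the translational
#' or rotational speed limit (the signature of a single-frame tracking spike).
#'
#' @param series A [pose_series()].
#' @param max_speed_mps Translational limit, m/s (default 20).
#' @param max_ang_speed Rotational limit, deg/s (default 3000).
#' @return The series with offending frames masked.
#' @export
mask_implausible <- function(series, max_speed_mps = 20, max_ang_speed = 3000) {
  n <- length(series$t)
  if (n < 3) return(series)
  step <- sqrt(rowSums(diff(series$origin)^2)) * series$rate # step i: (i, i+1)
  ang <- angular_speed(series)                               # ang[i]: (i-1, i)
  bad_in <- c(FALSE, step > max_speed_mps) | (!is.na(ang) & ang > max_ang_speed)
  bad_out <- c(step > max_speed_mps, FALSE) |
    c((!is.na(ang) & ang > max_ang_speed)[-1], FALSE)
  spike <- !is.na(bad_in) & !is.na(bad_out) & bad_in & bad_out
  spike[is.na(spike)] <- FALSE
  if (any(spike)) {
    series$valid[spike] <- FALSE
    series$origin[spike, ] <- NA_real_
    series$rotation[, , spike] <- NA_real_
    if (!is.null(series$body)) series$body[spike, ] <- NA_real_
  }
  series
}

#' Zero-phase moving-average smoothing of a pose series
#'
#' Positions are averaged over a centered window (shrinking at the endpoints
#' and around missing frames); orientations are averaged componentwise over
#' the same window and projected back onto SO(3). Invalid frames stay invalid.
#'
#' @param series A [pose_series()].
#' @param window_s Window length in seconds (default 0.1). Must be at least
#'   one sampling interval.
#' @return The smoothed series.
#' @export
smooth_series <- function(series, window_s = 0.1) {
  stopifnot(window_s >= 1 / series$rate)
  n <- length(series$t)
  h <- floor(round(window_s * series$rate) / 2)
  if (h < 1 || n < 2) return(series)

  win_mean <- function(x, valid) {
    x0 <- ifelse(valid, x, 0)
    cs <- c(0, cumsum(x0))
    cnt <- c(0, cumsum(as.numeric(valid)))
    i <- seq_len(n)
    lo <- pmax(i - h, 1); hi <- pmin(i + h, n)
    s <- cs[hi + 1] - cs[lo]
    m <- cnt[hi + 1] - cnt[lo]
    ifelse(m > 0, s / m, NA_real_)
  }
  v <- series$valid
  out <- series
  for (j in 1:3) out$origin[, j] <- ifelse(v, win_mean(series$origin[, j], v), NA_real_)
  if (!is.null(series$body)) {
    vb <- stats::complete.cases(series$body)
    for (j in 1:3) out$body[, j] <- ifelse(vb, win_mean(series$body[, j], vb), NA_real_)
  }
  Rm <- matrix(series$rotation, 9, n)
  Rs <- Rm
  for (j in 1:9) Rs[j, ] <- win_mean(Rm[j, ], v)
  for (i in which(v))
    out$rotation[, , i] <- project_so3(matrix(Rs[, i], 3, 3))
  out
}

#' Per-frame angular speed of the head
#'
#' Geodesic rotation angle between successive orientations divided by the
#' sampling interval; entry `i` refers to the step from frame `i - 1` to
#' frame `i`. NA at the first frame and wherever either frame is missing.
#'
#' @param series A [pose_series()].
#' @return Numeric vector of speeds, deg/s.
#' @export
angular_speed <- function(series) {
  n <- length(series$t)
  if (n < 2) return(rep(NA_real_, n))
  A <- matrix(series$rotation, 9, n)
  tr <- colSums(A[, -n, drop = FALSE] * A[, -1, drop = FALSE])
  ang <- acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
  speed <- c(NA_real_, ang * series$rate)
  speed[c(FALSE, !(series$valid[-n] & series$valid[-1]))] <- NA_real_
  speed
}

#' Detect head saccades
#'
#' A saccade is a maximal run of frames with angular speed above
#' `speed_threshold` whose duration is at least `min_duration_s` and whose net
#' rotation (geodesic angle between the orientations at the run's boundaries)
#' exceeds `min_amplitude_deg`. Fixations are the complementary intervals
#' (see [fixation_intervals()]).
#'
#' @param series A [pose_series()].
#' @param speed_threshold Angular speed threshold, deg/s (default 60).
#' @param min_duration_s Minimum duration, s (default 0.05).
#' @param min_amplitude_deg Minimum net rotation, degrees (default 5).
#' @return A data.frame with columns `t_start`, `t_end`, `amplitude`
#'   (degrees) and `peak_speed` (deg/s); zero rows when none found.
#' @export
detect_saccades <- function(series, speed_threshold = 60,
                            min_duration_s = 0.05, min_amplitude_deg = 5) {
  s <- angular_speed(series)
  runs <- logical_runs(s > speed_threshold)
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    amplitude = numeric(0), peak_speed = numeric(0))
  for (r in seq_len(nrow(runs))) {
    a <- runs$start[r]; b <- runs$end[r]
    dur <- (b - a + 1) / series$rate
    if (dur < min_duration_s - 1e-9) next
    amp <- geodesic_angle(series$rotation[, , a - 1], series$rotation[, , b])
    if (amp <= min_amplitude_deg) next
    out[nrow(out) + 1, ] <- c(series$t[a - 1], series$t[b], amp, max(s[a:b]))
  }
  out
}

#' Frames covered by saccades
#'
#' @param saccades Output of [detect_saccades()].
#' @param t Frame timestamps.
#' @return Logical vector: TRUE for frames inside any saccade interval
#'   (boundaries inclusive).
#' @export
saccade_frames <- function(saccades, t) {
  mask <- rep(FALSE, length(t))
  for (r in seq_len(nrow(saccades)))
    mask <- mask | (t >= saccades$t_start[r] - 1e-9 &
                    t <= saccades$t_end[r] + 1e-9)
  mask
}

#' Fixation (inter-saccadic) intervals
#'
#' Maximal runs of valid frames not covered by any saccade.
#'
#' @param series A [pose_series()].
#' @param saccades Output of [detect_saccades()] for the same series.
#' @return A data.frame with columns `t_start`, `t_end`.
#' @export
fixation_intervals <- function(series, saccades) {
  free <- series$valid & !saccade_frames(saccades, series$t)
  runs <- logical_runs(free)
  data.frame(t_start = series$t[runs$start], t_end = series$t[runs$end])
}
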