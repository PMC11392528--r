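#' Head-pose time series
#'
#' A fixed-rate time series of rigid head poses for one bird: per-frame origin
#' (head centroid, world m), world<-head rotation, a validity mask, and
#' optionally the per-frame body centroid (defined as 6 cm below the centroid
#' of the back-marker cluster).
#'
#' @param pigeon_id Identifier.
#' @param t Strictly increasing timestamps (s) at a constant sampling interval.
#' @param origin n x 3 matrix of head origins (m); NA on invalid frames.
#' @param rotation 3 x 3 x n array of rotations; NA slices on invalid frames.
#' @param valid Logical mask, length n.
#' @param body Optional n x 3 matrix of body centroids (m).
#' @param beak_local Optional length-3 beak-tip position in the head frame (m),
#'   used to reconstruct the world beak tip for peck detection.
#' @param rate Sampling rate in Hz (default inferred from `t`).
#' @return An object of class `pose_series`.
#' @export
pose_series <- function(pigeon_id, t, origin, rotation, valid = NULL,
                        body = NULL, beak_local = NULL, rate = NULL) {
  n <- length(t)
  stopifnot(n >= 1, nrow(origin) == n, dim(rotation)[3] == n)
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("timestamps must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6) stop("sampling interval must be constant")
  }
  if (is.null(rate)) rate <- if (n > 1) 1 / mean(diff(t)) else 60
  if (is.null(valid)) valid <- stats::complete.cases(origin)
  stopifnot(length(valid) == n)
  structure(list(pigeon_id = pigeon_id, rate = rate, t = as.numeric(t),
                 origin = as.matrix(origin), rotation = rotation,
                 valid = as.logical(valid), body = body,
                 beak_local = beak_local),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("Pose series '%s': %d frames at %.0f Hz (%.1f s), %.1f%% valid\n",
              x$pigeon_id, n, x$rate, n / x$rate, 100 * mean(x$valid)))
  invisible(x)
}

#' @export
length.pose_series <- function(x) length(x$t)

#' Fit a pose series from raw marker trajectories
#'
#' Runs the per-frame rigid registration ([fit_head_pose()]) of the head
#' calibration template on every frame, and derives the body centroid from the
#' back-marker cluster (6 cm below its centroid). Frames with fewer than 3
#' valid head markers are masked as missing.
#'
#' @param head_markers n x m x 3 array of head-marker world positions (m),
#'   marker order matching `calib$marker_template`; NA where untracked.
#' @param back_markers Optional n x k x 3 array of back-marker positions.
#' @param calib A [head_calibration()].
#' @param t Timestamps (s).
#' @param pigeon_id Identifier.
#' @param body_drop Vertical offset from back-cluster centroid to body
#'   centroid (m, default 0.06).
#' @return A [pose_series()] with per-frame rms residuals in attribute `rms`.
#' @export
fit_pose_series <- function(head_markers, back_markers = NULL, calib, t,
                            pigeon_id = "bird", body_drop = 0.06) {
  n <- dim(head_markers)[1]
  origin <- matrix(NA_real_, n, 3)
  rotation <- array(NA_real_, c(3, 3, n))
  rms <- rep(NA_real_, n)
  valid <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_head_pose(head_markers[i, , ], calib)
    if (fit$valid) {
      origin[i, ] <- fit$origin
      rotation[, , i] <- fit$rotation
      rms[i] <- fit$rms
      valid[i] <- TRUE
    }
  }
  body <- NULL
  if (!is.null(back_markers)) {
    body <- t(apply(back_markers, 1, function(m) {
      m <- matrix(m, ncol = 3)
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) == 0) rep(NA_real_, 3) else colMeans(m)
    }))
    body[, 3] <- body[, 3] - body_drop
  }
  beak_local <- as.numeric(crossprod(calib$axes, calib$beak_tip - calib$origin))
  out <- pose_series(pigeon_id, t, origin, rotation, valid, body, beak_local)
  attr(out, "rms") <- rms
  out
}

#' World-frame beak-tip positions of a pose series
#'
#' @param series A [pose_series()] carrying `beak_local`.
#' @return n x 3 matrix (m), NA on invalid frames.
#' @export
beak_positions <- function(series) {
  b <- series$beak_local
  if (is.null(b)) stop("series carries no beak calibration")
  R <- series$rotation
  out <- series$origin
  for (j in 1:3)
    out[, j] <- series$origin[, j] +
      R[j, 1, ] * b[1] + R[j, 2, ] * b[2] + R[j, 3, ] * b[3]
  out
}

#' Head pitch with extended range
#'
#' Pitch is the elevation of the head's forward (+Y) axis above the world
#' horizontal plane. The range is extended beyond +/-90 degrees using the
#' dorsal (+Z) axis: when the head is pitched past vertical (dorsal axis
#' pointing below the horizon), |pitch| > 90, with range (-180, 180]. This is
#' the convention under which a head strongly pointing down-and-back (breast
#' preening) has pitch < -100 degrees.
#'
#' @param series A [pose_series()].
#' @return Numeric vector of pitches, degrees; NA on invalid frames.
#' @export
head_pitch <- function(series) {
  R <- series$rotation
  fz <- R[3, 2, ]; fx <- R[1, 2, ]; fy <- R[2, 2, ]
  upz <- R[3, 3, ]
  raw <- atan2(fz, sqrt(fx^2 + fy^2)) * 180 / pi
  ifelse(upz >= 0, raw, ifelse(raw >= 0, 180 - raw, -180 - raw))
}

#' Head roll (lateral tilt)
#'
#' The elevation of the head's lateral (+X) axis out of the world horizontal
#' plane, degrees in \[-90, 90\]; 0 when the head is level, large in magnitude
#' when the head is tilted sideways (e.g. scratching with the foot).
#'
#' @param series A [pose_series()].
#' @return Numeric vector, degrees.
#' @export
head_roll <- function(series) {
  xz <- series$rotation[3, 1, ]
  asin(pmin(1, pmax(-1, xz))) * 180 / pi
}

# restrict a series to a frame index window (internal)
subset_series <- function(series, idx) {
  out <- series
  out$t <- series$t[idx]
  out$origin <- series$origin[idx, , drop = FALSE]
  out$rotation <- series$rotation[, , idx, drop = FALSE]
  out$valid <- series$valid[idx]
  if (!is.null(series$body)) out$body <- series$body[idx, , drop = FALSE]
  out
}
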