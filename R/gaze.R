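#' Egocentric angles of a target across a pose series
#'
#' Projects a world target (fixed point or per-frame trajectory, e.g. a
#' conspecific) into each frame's head-local frame.
#'
#' @param series A [pose_series()].
#' @param center Length-3 vector or n x 3 matrix of world positions (m).
#' @return A data.frame with columns `azimuth`, `elevation` (degrees; NA on
#'   invalid frames).
#' @export
egocentric_series <- function(series, center) {
  n <- length(series$t)
  if (is.null(dim(center))) center <- matrix(center, n, 3, byrow = TRUE)
  d <- center - series$origin
  R <- series$rotation
  # head-frame components: v = t(R) %*% d, vectorized over frames
  vx <- R[1, 1, ] * d[, 1] + R[2, 1, ] * d[, 2] + R[3, 1, ] * d[, 3]
  vy <- R[1, 2, ] * d[, 1] + R[2, 2, ] * d[, 2] + R[3, 2, ] * d[, 3]
  vz <- R[1, 3, ] * d[, 1] + R[2, 3, ] * d[, 2] + R[3, 3, ] * d[, 3]
  az <- atan2(vx, vy) * 180 / pi
  el <- atan2(vz, sqrt(vx^2 + vy^2)) * 180 / pi
  az[!series$valid] <- NA_real_
  el[!series$valid] <- NA_real_
  data.frame(azimuth = az, elevation = el)
}

#' Extract foveation events on an object
#'
#' Frames where the object's center satisfies the rectangular foveal test
#' ([is_foveated()]) for the requested eye(s) are collected; saccade frames
#' are removed first (visual processing is assumed suppressed during
#' saccades), so a saccade splits a foveation run. Maximal remaining runs
#' shorter than `min_duration_s` are dropped.
#'
#' @param series A [pose_series()].
#' @param center Object-center world position (vector or n x 3 matrix).
#' @param saccades Output of [detect_saccades()] for this series (or NULL).
#' @param eye `"either"` (default), `"left"` or `"right"`.
#' @param margin_deg Foveal-region half-width, degrees (default 10).
#' @param min_duration_s Minimum event duration (default 0.3).
#' @return A data.frame with columns `t_start`, `t_end`, `duration`, `eye`.
#' @export
extract_foveation_events <- function(series, center, saccades = NULL,
                                     eye = c("either", "left", "right"),
                                     margin_deg = 10, min_duration_s = 0.3) {
  eye <- match.arg(eye)
  ang <- egocentric_series(series, center)
  mask <- if (eye == "either")
    is_foveated(ang$azimuth, ang$elevation, margin_deg = margin_deg, either = TRUE)
  else is_foveated(ang$azimuth, ang$elevation, side = eye, margin_deg = margin_deg)
  mask[is.na(mask)] <- FALSE
  mask <- mask & series$valid
  if (!is.null(saccades) && nrow(saccades) > 0)
    mask <- mask & !saccade_frames(saccades, series$t)
  runs <- logical_runs(mask)
  out <- data.frame(t_start = numeric(0), t_end = numeric(0),
                    duration = numeric(0))
  for (r in seq_len(nrow(runs))) {
    dur <- (runs$end[r] - runs$start[r] + 1) / series$rate
    if (dur >= min_duration_s - 1e-9)
      out[nrow(out) + 1, ] <- c(series$t[runs$start[r]],
                                series$t[runs$end[r]], dur)
  }
  out$eye <- rep(eye, nrow(out))
  out
}

#' Latency to foveate on the predator cue
#'
#' The start time, relative to looming onset, of the first qualifying
#' foveation on any cue object (the active monitor or its hiding table).
#' Events starting within the first `onset_exclusion_s` of the looming period
#' do not qualify (the gaze may already have been crossing the cue; typical
#' reaction times exceed 200 ms). If the first qualifying foveation begins
#' only after looming offset (i.e. on the model predator), the case is
#' returned as NA and excluded downstream.
#'
#' @param events Foveation events on cue objects (rows of
#'   [extract_foveation_events()] output, possibly concatenated).
#' @param t_loom_on,t_loom_off Looming onset/offset times (s).
#' @param onset_exclusion_s Initial exclusion window (default 0.2).
#' @return Latency in seconds, or NA.
#' @export
latency_to_foveate <- function(events, t_loom_on, t_loom_off,
                               onset_exclusion_s = 0.2) {
  if (nrow(events) == 0) return(NA_real_)
  qual <- events$t_start >= t_loom_on + onset_exclusion_s - 1e-9
  if (!any(qual)) return(NA_real_)
  first <- min(events$t_start[qual])
  if (first > t_loom_off + 1e-9) return(NA_real_)
  first - t_loom_on
}

#' Escape latencies from a behavior timeline
#'
#' Onset (relative to looming onset) of the first running-away and flying
#' intervals after looming onset, and whether either began before looming
#' offset.
#'
#' @param timeline A `behavior_timeline` (see [compose_ethogram()]).
#' @param t_loom_on,t_loom_off Looming onset/offset (s).
#' @return List with `t_run`, `t_fly` (s or NA) and `escaped_before_offset`.
#' @export
escape_latencies <- function(timeline, t_loom_on, t_loom_off) {
  onset_of <- function(lab) {
    runs <- logical_runs(timeline$label == lab)
    if (nrow(runs) == 0) return(NA_real_)
    starts <- timeline$t[runs$start]
    starts <- starts[starts >= t_loom_on - 1e-9]
    if (length(starts) == 0) return(NA_real_)
    min(starts) - t_loom_on
  }
  t_run <- onset_of("running_away")
  t_fly <- onset_of("flying")
  both <- c(t_run, t_fly)
  escaped <- any(!is.na(both) & both < (t_loom_off - t_loom_on))
  list(t_run = t_run, t_fly = t_fly, escaped_before_offset = escaped)
}

#' Visual-field heatmap of an object
#'
#' Bins per-frame egocentric angles of an object center into 5 x 5 degree
#' cells over azimuth (-180, 180] x elevation \[-90, 90\] (72 x 36 grid,
#' left-closed bins) and normalizes the counts to unit sum. The foveal-region
#' frequency is the summed frequency inside the two rectangles 75 +/- 10 in
#' azimuth (either side), 0 +/- 10 in elevation, clipped to
#' `[eps, 1 - eps]` and logit-transformed.
#'
#' @param azimuth,elevation Per-frame angles, degrees (NA frames are skipped).
#' @param cell_deg Cell size (default 5).
#' @param margin_deg Foveal half-width (default 10).
#' @param fovea_azimuth Foveal azimuth magnitude (default 75).
#' @param eps Clipping constant for the logit (default 1e-4).
#' @return Object of class `visualfield_heatmap`: list with `freq` (72 x 36
#'   matrix), `n_frames`, `foveal_freq`, `foveal_logit`, and bin edges.
#' @export
visualfield_heatmap <- function(azimuth, elevation, cell_deg = 5,
                                margin_deg = 10, fovea_azimuth = 75,
                                eps = 1e-4) {
  ok <- !is.na(azimuth) & !is.na(elevation)
  az <- azimuth[ok]; el <- elevation[ok]
  n_az <- round(360 / cell_deg); n_el <- round(180 / cell_deg)
  ia <- pmin(floor((az + 180) / cell_deg) + 1, n_az)
  ie <- pmin(floor((el + 90) / cell_deg) + 1, n_el)
  counts <- matrix(0, n_az, n_el)
  for (k in seq_along(ia)) counts[ia[k], ie[k]] <- counts[ia[k], ie[k]] + 1
  total <- sum(counts)
  freq <- if (total > 0) counts / total else counts
  az_starts <- seq(-180, 180 - cell_deg, by = cell_deg)
  el_starts <- seq(-90, 90 - cell_deg, by = cell_deg)
  in_az <- (az_starts >= fovea_azimuth - margin_deg &
            az_starts < fovea_azimuth + margin_deg) |
           (az_starts >= -fovea_azimuth - margin_deg &
            az_starts < -fovea_azimuth + margin_deg)
  in_el <- el_starts >= -margin_deg & el_starts < margin_deg
  fov <- sum(freq[in_az, in_el])
  clipped <- min(max(fov, eps), 1 - eps)
  structure(list(freq = freq, n_frames = total, foveal_freq = fov,
                 foveal_logit = log(clipped / (1 - clipped)),
                 az_breaks = c(az_starts, 180), el_breaks = c(el_starts, 90)),
            class = "visualfield_heatmap")
}

#' @export
print.visualfield_heatmap <- function(x, ...) {
  cat(sprintf(paste0("Visual-field heatmap: %d frames, cell sum = %.3f, ",
                     "foveal-region frequency = %.3f (logit %.2f)\n"),
              x$n_frames, sum(x$freq), x$foveal_freq, x$foveal_logit))
  invisible(x)
}

#' @export
plot.visualfield_heatmap <- function(x, main = "Visual field", ...) {
  graphics::image(x$az_breaks, x$el_breaks, x$freq,
                  xlab = "Azimuth (deg)", ylab = "Elevation (deg)",
                  main = main, useRaster = TRUE, ...)
  for (s in c(-1, 1))
    graphics::rect(s * 75 - 10, -10, s * 75 + 10, 10, border = "red")
  invisible(x)
}

#' Before-cue behavioral metrics
#'
#' Summaries of the 2 min window preceding looming onset: proportion of time
#' head-up, peck rate, saccade rate, and proportions of time foveating on any
#' monitor and on any conspecific. Proportions are computed over valid
#' (non-missing) frames; rates over the window duration.
#'
#' @param timeline A `behavior_timeline`.
#' @param saccades Saccade table for the same bird.
#' @param fove_monitor Logical per-frame vector: any monitor foveated
#'   (either eye, saccade frames already excluded).
#' @param fove_conspecific Logical per-frame vector: any conspecific foveated.
#' @param t_loom_on Looming onset (s).
#' @param window_s Window length (default 120).
#' @return Named list of the five metrics plus `valid_frames`.
#' @export
before_cue_metrics <- function(timeline, saccades, fove_monitor,
                               fove_conspecific, t_loom_on, window_s = 120) {
  w <- timeline$t >= t_loom_on - window_s - 1e-9 & timeline$t < t_loom_on - 1e-9
  lab <- timeline$label[w]
  ok <- lab != "missing"
  prop <- function(x) if (any(ok)) mean(x[ok], na.rm = TRUE) else NA_real_
  n_pecks <- sum(timeline$pecks >= t_loom_on - window_s &
                 timeline$pecks < t_loom_on)
  n_sacc <- sum(saccades$t_start >= t_loom_on - window_s &
                saccades$t_start < t_loom_on)
  list(prop_head_up = prop(lab == "head_up"),
       peck_rate = n_pecks / window_s,
       saccade_rate = n_sacc / window_s,
       prop_fove_monitor = prop(fove_monitor[w]),
       prop_fove_conspecific = prop(fove_conspecific[w]),
       valid_frames = sum(ok))
}

#' Behavioral state at looming onset
#'
#' The timeline label at the frame closest to looming onset, collapsed to
#' `head_up`, `feeding` or `other` (grooming, courting, lone head-down and so
#' on, excluded from the head-up/feeding contrast downstream). `missing` when
#' the frame is untracked.
#'
#' @param timeline A `behavior_timeline`.
#' @param t_loom_on Looming onset (s).
#' @return One of `"head_up"`, `"feeding"`, `"other"`, `"missing"`.
#' @export
state_at_onset <- function(timeline, t_loom_on) {
  i <- which.min(abs(timeline$t - t_loom_on))
  lab <- timeline$label[i]
  if (lab %in% c("head_up", "feeding", "missing")) return(lab)
  "other"
}
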