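#' Head-down classification
#'
#' TRUE iff the head centroid is strictly lower (world z) than the body
#' centroid.
#'
#' @param head_z,body_z Numeric vectors (m).
#' @return Logical vector (NA where either input is NA).
#' @export
classify_head_down <- function(head_z, body_z) {
  ifelse(is.na(head_z) | is.na(body_z), NA, head_z < body_z)
}

#' Detect pecks from the beak-tip trajectory
#'
#' Within each maximal run of frames where the beak tip is below
#' `max_height_m` off the ground and the head pitch is above `min_pitch_deg`
#' (i.e. the beak is not oriented toward the body), one peck event is emitted
#' at the frame where the beak tip is closest to the ground (earliest frame on
#' ties).
#'
#' @param beak_z Beak-tip height series (m; ground plane z = 0).
#' @param pitch Head pitch series, degrees (see [head_pitch()]).
#' @param t Frame timestamps (s).
#' @param valid Logical frame mask.
#' @param max_height_m Beak height threshold (default 0.04).
#' @param min_pitch_deg Pitch floor (default -100).
#' @return Numeric vector of peck times (s).
#' @export
detect_pecks <- function(beak_z, pitch, t, valid = NULL,
                         max_height_m = 0.04, min_pitch_deg = -100) {
  if (is.null(valid)) valid <- !is.na(beak_z) & !is.na(pitch)
  low <- valid & beak_z < max_height_m & pitch > min_pitch_deg
  runs <- logical_runs(low)
  if (nrow(runs) == 0) return(numeric(0))
  vapply(seq_len(nrow(runs)), function(r) {
    idx <- runs$start[r]:runs$end[r]
    t[idx[which.min(beak_z[idx])]]
  }, numeric(1))
}

#' Feeding intervals from peck times
#'
#' Feeding is any time between two consecutive pecks spaced no more than
#' `max_gap_s` apart; chained pecks merge into a single interval.
#'
#' @param peck_times Sorted peck times (s).
#' @param max_gap_s Maximum inter-peck gap (default 6).
#' @return A data.frame with columns `t_start`, `t_end` (possibly zero rows).
#' @export
feeding_intervals <- function(peck_times, max_gap_s = 6) {
  out <- data.frame(t_start = numeric(0), t_end = numeric(0))
  if (length(peck_times) < 2) return(out)
  p <- sort(peck_times)
  brk <- which(diff(p) > max_gap_s)
  starts <- c(1, brk + 1); ends <- c(brk, length(p))
  keep <- ends > starts # a lone peck spans no time
  data.frame(t_start = p[starts[keep]], t_end = p[ends[keep]])
}

# angle (deg) between per-frame 3-vectors stored as n x 3 matrices
angle_between_rows <- function(a, b) {
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  acos(pmin(1, pmax(-1, num / den))) * 180 / pi
}

#' Per-frame grooming classification
#'
#' Fires when any of the posture sub-rules holds:
#' back preening (head pointing backward relative to the body-to-head axis by
#' more than 60 degrees with the beak within 10 cm of the body center, or by
#' more than 40 degrees with the beak within 10 cm and the head above the
#' body); breast preening (pitch below -100, or pitch below -80 with the
#' head-direction/body-head angle above 60); head scratching (|roll| above 50
#' with the head less than 3 cm above the body centroid).
#'
#' @param series A [pose_series()] with body centroids and beak calibration.
#' @return Logical vector per frame.
#' @export
detect_grooming <- function(series) {
  if (is.null(series$body)) stop("grooming rules need body centroids")
  fwd <- t(series$rotation[, 2, ])            # n x 3 forward axis
  bh <- series$origin - series$body           # body -> head
  ang <- angle_between_rows(fwd, bh)
  beak <- beak_positions(series)
  dist_bb <- sqrt(rowSums((beak - series$body)^2))
  pitch <- head_pitch(series)
  roll <- head_roll(series)
  dz <- series$origin[, 3] - series$body[, 3]
  back_a <- ang > 60 & dist_bb < 0.10
  back_b <- ang > 40 & dist_bb < 0.10 & dz > 0
  breast <- pitch < -100 | (pitch < -80 & ang > 60)
  scratch <- abs(roll) > 50 & dz < 0.03
  out <- back_a | back_b | breast | scratch
  out[!series$valid | is.na(out)] <- FALSE
  out
}

# bow events: pitch dips >= threshold below the rolling median that return
# within max_return_s; returns times of maximal dip
detect_bows <- function(pitch, t, rate, dip_threshold = 25,
                        median_window_s = 8, max_return_s = 2) {
  ok <- !is.na(pitch)
  if (sum(ok) < 3) return(numeric(0))
  base <- pitch
  k <- min(2 * floor(median_window_s * rate / 2) + 1, sum(ok))
  if (k %% 2 == 0) k <- k - 1
  filled <- pitch
  if (any(!ok)) filled[!ok] <- stats::median(pitch[ok])
  med <- stats::runmed(filled, k, endrule = "median")
  dip <- med - pitch
  runs <- logical_runs(ok & dip >= dip_threshold)
  if (nrow(runs) == 0) return(numeric(0))
  times <- numeric(0)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    if ((length(idx)) / rate > max_return_s) next # did not come back up in time
    times <- c(times, t[idx[which.max(dip[idx])]])
  }
  times
}

#' Courtship (bowing) classification for a flock
#'
#' A bird is courting when it performs at least two head bows within an 8 s
#' window while within 60 cm of another bird and oriented toward it within
#' 120 degrees (horizontal heading cone); episodes shorter than 1 s are
#' discarded. The targeted neighbor is flagged as courted. A bow is a pitch
#' dip of at least `dip_threshold` degrees below the bird's rolling median
#' pitch, returning within 2 s.
#'
#' @param series_list List of [pose_series()] for all flock members, on the
#'   same clock, with body centroids.
#' @param dip_threshold Bow amplitude threshold, degrees (default 25).
#' @param max_distance_m Proximity requirement (default 0.6).
#' @param max_angle_deg Maximum angle between the courter's horizontal heading
#'   and the direction to the neighbor (default 120).
#' @param bow_window_s Window within which two bows must fall (default 8).
#' @param min_episode_s Minimum episode duration (default 1).
#' @return List with logical matrices `courting` and `courted`
#'   (frames x birds).
#' @export
detect_courting <- function(series_list, dip_threshold = 25,
                            max_distance_m = 0.6, max_angle_deg = 120,
                            bow_window_s = 8, min_episode_s = 1) {
  nb <- length(series_list)
  n <- length(series_list[[1]]$t)
  t <- series_list[[1]]$t
  rate <- series_list[[1]]$rate
  courting <- matrix(FALSE, n, nb)
  courted <- matrix(FALSE, n, nb)
  if (nb < 2) return(list(courting = courting, courted = courted))
  bodies <- lapply(series_list, function(s) s$body)
  for (i in seq_len(nb)) {
    si <- series_list[[i]]
    bows <- detect_bows(head_pitch(si), t, rate, dip_threshold)
    if (length(bows) < 2) next
    # chain bows spaced <= bow_window_s into candidate episodes
    brk <- which(diff(bows) > bow_window_s)
    starts <- c(1, brk + 1); ends <- c(brk, length(bows))
    heading <- t(si$rotation[, 2, ]); heading[, 3] <- 0
    for (e in seq_along(starts)) {
      if (ends[e] - starts[e] + 1 < 2) next
      idx <- which(t >= bows[starts[e]] & t <= bows[ends[e]])
      if (length(idx) == 0) next
      # geometric condition per frame: some neighbor close and in front
      target <- rep(NA_integer_, length(idx))
      best <- rep(Inf, length(idx))
      for (j in seq_len(nb)) {
        if (j == i) next
        d <- bodies[[j]][idx, , drop = FALSE] - bodies[[i]][idx, , drop = FALSE]
        dist <- sqrt(rowSums(d^2))
        d[, 3] <- 0
        ang <- angle_between_rows(heading[idx, , drop = FALSE], d)
        hit <- !is.na(dist) & dist < max_distance_m & !is.na(ang) &
          ang < max_angle_deg & dist < best
        target[hit] <- j
        best[hit] <- dist[hit]
      }
      ok <- !is.na(target)
      if (sum(ok) / rate < min_episode_s) next
      courting[idx[ok], i] <- TRUE
      for (j in unique(target[ok]))
        courted[idx[ok][target[ok] == j], j] <- TRUE
    }
  }
  list(courting = courting, courted = courted)
}

# centrally differenced speed of an n x 3 position series, m/s
body_speed <- function(pos, rate) {
  n <- nrow(pos)
  sp <- rep(NA_real_, n)
  if (n < 3) return(sp)
  d <- pos[3:n, ] - pos[1:(n - 2), ]
  sp[2:(n - 1)] <- sqrt(rowSums(d^2)) * rate / 2
  sp[1] <- sp[2]; sp[n] <- sp[n - 1]
  sp
}

#' Detect running away from the monitor
#'
#' Maximal runs where the body moves faster than `speed_threshold` while the
#' distance to the active monitor increases faster than `radial_threshold`
#' and the bird is not courting or courted; runs shorter than `min_duration_s`
#' are dropped. Radial speed is centrally differenced over `radial_window_s`.
#'
#' @param series A [pose_series()] with body centroids.
#' @param monitor_center Length-3 world position of the active monitor (m).
#' @param courting_mask Optional logical vector (courting or courted frames).
#' @param speed_threshold m/s (default 0.6).
#' @param radial_threshold m/s (default 0.2).
#' @param min_duration_s Seconds (default 0.07).
#' @param radial_window_s Differencing window for the radial speed (default
#'   0.25).
#' @return A data.frame with columns `t_start`, `t_end`.
#' @export
detect_running_away <- function(series, monitor_center, courting_mask = NULL,
                                speed_threshold = 0.6, radial_threshold = 0.2,
                                min_duration_s = 0.07, radial_window_s = 0.25) {
  pos <- series$body
  if (is.null(pos)) stop("running rules need body centroids")
  n <- nrow(pos)
  sp <- body_speed(pos, series$rate)
  dist <- sqrt(rowSums(sweep(pos, 2, monitor_center)^2))
  h <- max(1, round(radial_window_s * series$rate / 2))
  rs <- rep(NA_real_, n)
  idx <- (h + 1):(n - h)
  rs[idx] <- (dist[idx + h] - dist[idx - h]) * series$rate / (2 * h)
  cond <- sp > speed_threshold & rs > radial_threshold & series$valid
  if (!is.null(courting_mask)) cond <- cond & !courting_mask
  interval_runs(cond, series$t, series$rate, min_duration_s)
}

#' Detect flying
#'
#' Maximal runs with body speed above `speed_threshold` (default 2 m/s, a
#' speed unattainable by running) lasting at least `min_duration_s`.
#'
#' @inheritParams detect_running_away
#' @param speed_threshold m/s (default 2).
#' @return A data.frame with columns `t_start`, `t_end`.
#' @export
detect_flying <- function(series, speed_threshold = 2, min_duration_s = 0.07) {
  if (is.null(series$body)) stop("flying rules need body centroids")
  sp <- body_speed(series$body, series$rate)
  interval_runs(sp > speed_threshold & series$valid, series$t, series$rate,
                min_duration_s)
}

interval_runs <- function(cond, t, rate, min_duration_s) {
  runs <- logical_runs(cond)
  out <- data.frame(t_start = numeric(0), t_end = numeric(0))
  for (r in seq_len(nrow(runs))) {
    dur <- (runs$end[r] - runs$start[r] + 1) / rate
    if (dur >= min_duration_s - 1e-9)
      out[nrow(out) + 1, ] <- c(t[runs$start[r]], t[runs$end[r]])
  }
  out
}

in_intervals <- function(t, intervals) {
  mask <- rep(FALSE, length(t))
  for (r in seq_len(nrow(intervals)))
    mask <- mask | (t >= intervals$t_start[r] - 1e-9 &
                    t <= intervals$t_end[r] + 1e-9)
  mask
}

#' Compose the per-frame ethogram for a flock
#'
#' Runs all behavior detectors on a common clock and resolves co-firing rules
#' by precedence: flying > running away > courting > grooming > feeding >
#' head-down > head-up (head-up is the residual state); invalid frames are
#' `missing`. Peck events are attached to each bird's timeline.
#'
#' @param series_list List of [pose_series()] for the flock (same clock).
#' @param monitor_center Active-monitor world position, used by the
#'   running-away rule.
#' @param courting Optional precomputed result of [detect_courting()];
#'   computed when NULL.
#' @return A list of `behavior_timeline` objects, one per bird: each has
#'   `pigeon_id`, `t`, `label` (character) and `pecks` (times).
#' @export
compose_ethogram <- function(series_list, monitor_center, courting = NULL) {
  if (is.null(courting)) courting <- detect_courting(series_list)
  lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    t <- s$t
    pitch <- head_pitch(s)
    beak <- beak_positions(s)
    pecks <- detect_pecks(beak[, 3], pitch, t, s$valid)
    feeding <- in_intervals(t, feeding_intervals(pecks))
    groom <- detect_grooming(s)
    court <- courting$courting[, i] | courting$courted[, i]
    run <- in_intervals(t, detect_running_away(s, monitor_center, court))
    fly <- in_intervals(t, detect_flying(s))
    down <- classify_head_down(s$origin[, 3], s$body[, 3])
    label <- rep("head_up", length(t))
    label[!is.na(down) & down] <- "head_down"
    label[feeding] <- "feeding"
    label[groom] <- "grooming"
    label[court] <- "courting"
    label[run] <- "running_away"
    label[fly] <- "flying"
    label[!s$valid] <- "missing"
    structure(list(pigeon_id = s$pigeon_id, t = t, rate = s$rate,
                   label = label, pecks = pecks),
              class = "behavior_timeline")
  })
}

#' @export
print.behavior_timeline <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("Behavior timeline '%s': %d frames, %d pecks\n",
              x$pigeon_id, length(x$t), length(x$pecks)))
  print(round(prop.table(tab), 3))
  invisible(x)
}
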