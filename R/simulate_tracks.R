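# Synthetic track generator: scripts full-session head/body kinematics for
# each bird (foraging bouts, scan fixations and saccades, pecking, grooming,
# cue detection, monitoring, running and flying), rasterizes them at the
# sampling rate, and emits marker-level motion-capture data plus complete
# ground truth.

wrap180 <- function(a) ((a + 180) %% 360) - 180

# world azimuth (deg) of the horizontal direction from `from` to `to`,
# matching the egocentric convention atan2(x, y)
world_bearing <- function(from, to) {
  atan2(to[1] - from[1], to[2] - from[2]) * 180 / pi
}

fold_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

# rotation array (3 x 3 x n) for yaw/pitch series:
# R = Rz(-yaw) %*% Rx(pitch), so a target at world azimuth a has egocentric
# azimuth a - yaw, and pitch is the elevation of the forward axis
yawpitch_rotation <- function(yaw_deg, pitch_deg) {
  n <- length(yaw_deg)
  cy <- cos(yaw_deg * pi / 180); sy <- sin(yaw_deg * pi / 180)
  cp <- cos(pitch_deg * pi / 180); sp <- sin(pitch_deg * pi / 180)
  R <- array(0, c(3, 3, n))
  R[1, 1, ] <- cy;       R[2, 1, ] <- -sy
  R[1, 2, ] <- sy * cp;  R[2, 2, ] <- cy * cp;  R[3, 2, ] <- sp
  R[1, 3, ] <- -sy * sp; R[2, 3, ] <- -cy * sp; R[3, 3, ] <- cp
  R
}

# body-position pass: heading random walk at walk_speed, overridden by
# straight run/fly bursts directly away from the monitor; keeps the bird
# inside the feeding area (or the room, once it has escaped)
simulate_body_path <- function(n, rate, p0, overrides, params, scene) {
  dt <- 1 / rate
  theta <- cumsum(stats::rnorm(n, 0, params$heading_sd * sqrt(dt))) +
    stats::runif(1, -pi, pi)
  vel <- params$walk_speed * cbind(cos(theta), sin(theta))
  room <- scene$room
  fc <- scene$feeding_center; fr2 <- scene$feeding_rect / 2
  pos <- matrix(NA_real_, n, 2)
  bounds_for <- function(p) {
    if (abs(p[1] - fc[1]) <= fr2[1] && abs(p[2] - fc[2]) <= fr2[2])
      rbind(fc - fr2, fc + fr2)
    else rbind(c(0.4, 0.4), c(room[1] - 0.4, room[2] - 0.4))
  }
  # segment boundaries from overrides (list of f0, f1, speed, monitor_xy)
  cur <- p0; f <- 1
  ov_end <- integer(0)
  ov <- overrides[order(vapply(overrides, `[[`, 0, "f0"))]
  for (o in c(ov, list(NULL))) {
    seg_end <- if (is.null(o)) n else o$f0 - 1
    if (seg_end >= f) {
      idx <- f:seg_end
      b <- bounds_for(cur)
      px <- fold_into(cur[1] + cumsum(vel[idx, 1]) * dt, b[1, 1], b[2, 1])
      py <- fold_into(cur[2] + cumsum(vel[idx, 2]) * dt, b[1, 2], b[2, 2])
      pos[idx, ] <- cbind(px, py)
      cur <- c(px[length(px)], py[length(py)])
      f <- seg_end + 1
    }
    if (is.null(o)) break
    idx <- o$f0:min(o$f1, n)
    dir <- cur - o$monitor_xy
    dir <- dir / sqrt(sum(dir^2))
    step <- cumsum(rep(o$speed * dt, length(idx)))
    px <- cur[1] + step * dir[1]
    py <- cur[2] + step * dir[2]
    # freeze at the room margin: the burst ends where the bird lands
    inside <- px >= 0.4 & px <= scene$room[1] - 0.4 &
      py >= 0.4 & py <= scene$room[2] - 0.4
    k_stop <- if (all(inside)) length(idx) else max(1, which(!inside)[1] - 1)
    if (k_stop < length(idx)) {
      px[(k_stop + 1):length(idx)] <- px[k_stop]
      py[(k_stop + 1):length(idx)] <- py[k_stop]
    }
    pos[idx, ] <- cbind(px, py)
    ov_end <- c(ov_end, idx[k_stop])
    cur <- c(px[length(px)], py[length(py)])
    f <- min(o$f1, n) + 1
  }
  list(pos = pos, theta = theta, ov_end = ov_end)
}

# head-kinematics script for one bird over one session; returns rasterized
# yaw/pitch/z plus the event logs that make up the ground truth
script_head <- function(n, rate, body_xy, events, resp, scene, params) {
  yaw <- numeric(n); pitch <- numeric(n); zh <- numeric(n)
  pecks <- numeric(0)
  sacc <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     amplitude = numeric(0), peak_speed = numeric(0))
  fove <- data.frame(t_start = numeric(0), t_end = numeric(0),
                     object = character(0))
  detections <- rep(NA_real_, length(events))
  tt <- (seq_len(n) - 1) / rate
  fidx <- function(x) pmin(n + 1, pmax(1, round(x * rate) + 1))
  monitors <- scene$monitor_centers

  fr <- 1
  cur_yaw <- stats::runif(1, -180, 180)
  cur_pitch <- 0
  cur_z <- params$z_scan
  last_bout <- sample(c("feed", "scan"), 1)

  fill <- function(f_end) { # constant posture up to (excluding) f_end
    if (f_end > fr) {
      idx <- fr:(f_end - 1)
      yaw[idx] <<- cur_yaw; pitch[idx] <<- cur_pitch; zh[idx] <<- cur_z
      fr <<- f_end
    }
  }
  ramp <- function(f_end_cap, tgt_yaw = cur_yaw, tgt_pitch = cur_pitch,
                   tgt_z = cur_z, speed = 300) {
    dy <- wrap180(tgt_yaw - cur_yaw); dp <- tgt_pitch - cur_pitch
    amp <- sqrt(dy^2 + dp^2)
    k <- max(1, round(amp / speed * rate))
    k <- min(k, max(1, f_end_cap - fr))
    if (fr + k - 1 > n) k <- n - fr + 1
    if (k < 1) return(invisible())
    idx <- fr:(fr + k - 1)
    f <- seq_len(k) / k
    yaw[idx] <<- cur_yaw + f * dy
    pitch[idx] <<- cur_pitch + f * dp
    zh[idx] <<- cur_z + f * (tgt_z - cur_z)
    if (amp > 1e-9 && fr > 1)
      sacc[nrow(sacc) + 1, ] <<- c(tt[fr - 1], tt[fr + k - 1], amp,
                                   amp / (k / rate))
    cur_yaw <<- cur_yaw + dy; cur_pitch <<- tgt_pitch; cur_z <<- tgt_z
    fr <<- fr + k
  }
  # TRUE iff neither monitor assembly sits near the foveal azimuth band
  # (65-85 deg, widened for drift; tables share the monitors' bearings) for
  # the whole segment [fr, f_until] under the known body path. Undirected
  # bouts keep cue objects out of the fovea; deliberate checks and
  # monitoring holds are the scripted exceptions.
  monitor_band_clear <- function(y, f_until = fr) {
    fs <- unique(pmin(c(fr, round((fr + f_until) / 2), f_until), n))
    for (m in monitors) {
      rel <- vapply(fs, function(f)
        wrap180(world_bearing(body_xy[f, ], m) - y), 0)
      if (any(abs(rel) >= 56 & abs(rel) <= 94)) return(FALSE)
      if (all(rel > 0) || all(rel < 0))
        if (min(abs(rel)) < 56 && max(abs(rel)) > 94) return(FALSE)
    }
    TRUE
  }
  yaw_clear_of_cues <- function(f_end) {
    if (monitor_band_clear(cur_yaw, f_end)) return(cur_yaw)
    for (try in 1:30) {
      cand <- stats::runif(1, -180, 180)
      if (monitor_band_clear(cand, f_end)) return(cand)
    }
    cur_yaw
  }
  monitor_elev <- function(m) {
    d <- sqrt(sum((m[1:2] - body_xy[min(fr, n), ])^2))
    atan2(m[3] - params$z_scan, d) * 180 / pi
  }

  do_feed <- function(f_end) {
    ramp(f_end, tgt_yaw = yaw_clear_of_cues(f_end),
         tgt_pitch = params$pitch_feed, tgt_z = params$z_feed,
         speed = 300)
    k_dip <- round(0.1 * rate)
    while (fr < f_end) {
      wait <- round(stats::runif(1, params$peck_gap[1], params$peck_gap[2]) * rate)
      if (fr + wait + 3 * k_dip >= f_end) { fill(f_end); break }
      fill(fr + wait)
      ramp(f_end, tgt_pitch = params$pitch_dip, tgt_z = params$z_dip,
           speed = 450)
      pecks <<- c(pecks, tt[fr])
      fill(fr + k_dip)
      ramp(f_end, tgt_pitch = params$pitch_feed, tgt_z = params$z_feed,
           speed = 450)
    }
  }
  do_scan <- function(f_end, allow_checks) {
    ramp(f_end, tgt_pitch = 0, tgt_z = params$z_scan, speed = 300)
    while (fr < f_end) {
      if (f_end - fr < round(0.3 * rate)) { fill(f_end); break }
      is_check <- FALSE
      check_obj <- NA_character_
      if (allow_checks && stats::runif(1) < params$check_prob) {
        pick <- sample(2, 1)
        m <- monitors[[pick]]
        if (abs(monitor_elev(m)) <= 8) {
          eye <- sample(c(-1, 1), 1)
          tgt <- world_bearing(body_xy[min(fr, n), ], m) - eye * 75
          is_check <- TRUE
          check_obj <- names(monitors)[pick]
        }
      }
      if (!is_check) {
        tgt <- cur_yaw
        f_until <- min(f_end, fr + round(1.2 * rate))
        for (try in 1:20) {
          cand <- cur_yaw + sample(c(-1, 1), 1) *
            stats::runif(1, params$saccade_amp[1], params$saccade_amp[2])
          if (monitor_band_clear(cand, f_until)) { tgt <- cand; break }
        }
      }
      ramp(f_end, tgt_yaw = tgt,
           speed = stats::runif(1, params$saccade_speed[1],
                                params$saccade_speed[2]))
      dur <- if (is_check)
        stats::runif(1, params$check_dur[1], params$check_dur[2])
      else stats::runif(1, params$fixation_dur[1], params$fixation_dur[2])
      f_fix_end <- min(f_end, fr + round(dur * rate))
      t_arrive <- tt[min(fr, n)]
      fill(f_fix_end)
      if (is_check && fr - 1 >= 1)
        fove[nrow(fove) + 1, ] <<- list(t_arrive, tt[fr - 1], check_obj)
    }
  }
  do_groom <- function(f_end) {
    ramp(f_end, tgt_yaw = yaw_clear_of_cues(f_end),
         tgt_pitch = params$pitch_groom, tgt_z = params$z_groom,
         speed = 400)
    exit <- round(0.35 * rate)
    fill(max(fr, f_end - exit))
    ramp(f_end, tgt_pitch = 0, tgt_z = params$z_scan, speed = 400)
  }
  forage <- function(f_end, allow_checks) {
    while (fr < f_end) {
      u <- stats::runif(1)
      if (u < params$groom_prob && last_bout != "groom" &&
          f_end - fr > round(3 * rate)) {
        # grooming bouts are never truncated short or chained back to back:
        # a cut-off entry dip would mimic a courtship bow
        len <- stats::runif(1, params$groom_bout[1], params$groom_bout[2])
        do_groom(min(f_end, fr + round(len * rate)))
        last_bout <<- "groom"
      } else if (last_bout == "scan" || last_bout == "groom") {
        last_bout <<- "feed"
        len <- stats::runif(1, params$feed_bout[1], params$feed_bout[2])
        do_feed(min(f_end, fr + round(len * rate)))
      } else {
        last_bout <<- "scan"
        len <- stats::runif(1, params$scan_bout[1], params$scan_bout[2])
        do_scan(min(f_end, fr + round(len * rate)), allow_checks)
      }
    }
  }
  hold_monitor <- function(f_end, m, eye, object) {
    if (f_end <= fr) return(NA_real_)
    # one combined reorienting saccade (>= 50 ms, <= ~0.3 s), so the entry
    # movement is always detectable and its frames excluded from foveation
    alpha0 <- world_bearing(body_xy[min(fr, n), ], m)
    tgt_yaw <- alpha0 - eye * 75
    amp <- sqrt(wrap180(tgt_yaw - cur_yaw)^2 + cur_pitch^2)
    ramp(f_end, tgt_yaw = tgt_yaw, tgt_pitch = 0, tgt_z = params$z_scan,
         speed = max(300, amp / 0.3))
    if (fr >= f_end) return(NA_real_)
    t_arrive <- tt[fr]
    idx <- fr:(f_end - 1)
    a <- atan2(m[1] - body_xy[idx, 1], m[2] - body_xy[idx, 2]) * 180 / pi
    raw <- a - eye * 75
    y <- cur_yaw + cumsum(c(wrap180(raw[1] - cur_yaw),
                            wrap180(diff(raw))))
    yaw[idx] <<- y; pitch[idx] <<- 0; zh[idx] <<- params$z_scan
    cur_yaw <<- y[length(y)]; cur_pitch <<- 0; cur_z <<- params$z_scan
    fr <<- f_end
    fove[nrow(fove) + 1, ] <<- list(t_arrive, tt[f_end - 1], object)
    t_arrive
  }
  do_burst <- function(f0, f1, m) { # head during run/fly: face away
    fill(f0)
    away <- world_bearing(m[1:2], body_xy[min(f0, n), ])
    ramp(f1, tgt_yaw = away, tgt_pitch = 0, tgt_z = params$z_scan,
         speed = 800)
    fill(f1)
  }

  for (e in seq_along(events)) {
    ev <- events[[e]]
    r <- resp[[e]]
    m <- monitors[[ev$side]]
    obj <- ev$side
    forage(fidx(ev$t_loom_on), TRUE)
    end_default <- ev$t_loom_off + 3
    resp_end <- ev$t_pred_off
    if (!is.na(r$det)) {
      forage(fidx(ev$t_loom_on + r$det), FALSE)
      h1_end <- if (!is.na(r$run)) ev$t_loom_on + r$run
      else if (!is.na(r$fly)) ev$t_loom_on + r$fly else end_default
      eye <- sample(c(-1, 1), 1)
      detections[e] <- hold_monitor(fidx(h1_end), m, eye, obj)
      if (!is.na(r$run)) {
        f1 <- fidx(ev$t_loom_on + r$run + r$run_dur)
        do_burst(fidx(ev$t_loom_on + r$run), f1, m)
        h2_end <- if (!is.na(r$fly)) ev$t_loom_on + r$fly else end_default
        if (fidx(h2_end) > fr) hold_monitor(fidx(h2_end), m, eye, obj)
      }
      if (!is.na(r$fly))
        do_burst(fidx(ev$t_loom_on + r$fly),
                 fidx(ev$t_loom_on + r$fly + params$fly_dur), m)
      resp_end <- max(resp_end, tt[min(fr, n)])
    } else if (!is.na(r$fly)) {
      forage(fidx(ev$t_loom_on + r$fly), FALSE)
      do_burst(fidx(ev$t_loom_on + r$fly),
               fidx(ev$t_loom_on + r$fly + params$fly_dur), m)
      resp_end <- max(resp_end, tt[min(fr, n)])
    } else {
      forage(fidx(ev$t_pred_off), FALSE)
    }
    pause <- stats::runif(1, params$alert_pause[1], params$alert_pause[2])
    # vigilance pause ends before the next event can start
    next_on <- if (e < length(events)) events[[e + 1]]$t_loom_on else Inf
    do_scan(fidx(min(max(resp_end, ev$t_pred_off) + pause, next_on)), FALSE)
    last_bout <- "scan"
  }
  forage(n + 1, TRUE)

  list(yaw = yaw, pitch = pitch, zh = zh, pecks = pecks,
       saccades = sacc, foveations = fove, detections = detections)
}

# ground-truth behavior labels from the scripted kinematics (same precedence
# as the classifier, applied to the noiseless script, not to fitted poses)
truth_labels <- function(tt, zh, pitch, pecks, run_iv, fly_iv, body_z) {
  lab <- rep("head_up", length(tt))
  lab[zh < body_z] <- "head_down"
  lab[in_intervals(tt, feeding_intervals(pecks))] <- "feeding"
  groom <- logical_runs(pitch < -100)
  for (g in seq_len(nrow(groom))) lab[groom$start[g]:groom$end[g]] <- "grooming"
  for (iv in run_iv) lab[tt >= iv[1] - 1e-9 & tt <= iv[2] + 1e-9] <- "running_away"
  for (iv in fly_iv) lab[tt >= iv[1] - 1e-9 & tt <= iv[2] + 1e-9] <- "flying"
  lab
}

#' Simulate one flock-session of the synthetic experiment
#'
#' Scripts and rasterizes full-session kinematics for every bird of one
#' flock: foraging (pecking bouts, head-up scanning with saccades and
#' occasional monitor checks, grooming), two predator presentation events
#' with per-bird detection, monitoring, running and flying responses (flight
#' timing governed by the contagion model), and emits motion-capture-style
#' marker data plus complete ground truth.
#'
#' @param design An [build_design()] result.
#' @param round Trial round.
#' @param flock `"A"` or `"B"`.
#' @param scene A [simulate_scene()] result.
#' @param params A [synth_params()] list.
#' @param seed RNG seed for this session.
#' @param markers Emit the marker-level data.frame (default TRUE; FALSE keeps
#'   only the ground truth, for fast statistical simulations).
#' @return Object of class `flock_session`.
#' @export
simulate_session <- function(design, round, flock, scene = simulate_scene(),
                             params = synth_params(), seed = 1,
                             markers = TRUE) {
  set.seed(seed)
  rate <- params$rate
  birds <- session_roster(design, round, flock)
  nb <- length(birds)
  sides <- design$events$side[design$events$trial == round &
                              design$events$flock == flock]

  loom_on1 <- stats::runif(1, params$feeding_s[1], params$feeding_s[2])
  loom_on1 <- round(loom_on1 * rate) / rate
  ev1 <- list(side = sides[1], t_loom_on = loom_on1,
              t_loom_off = loom_on1 + params$loom_dur,
              t_pred_on = loom_on1 + params$loom_dur,
              t_pred_off = loom_on1 + params$loom_dur + params$pred_dur)
  loom_on2 <- ev1$t_pred_off +
    stats::runif(1, params$feeding_s[1], params$feeding_s[2])
  loom_on2 <- round(loom_on2 * rate) / rate
  ev2 <- list(side = sides[2], t_loom_on = loom_on2,
              t_loom_off = loom_on2 + params$loom_dur,
              t_pred_on = loom_on2 + params$loom_dur,
              t_pred_off = loom_on2 + params$loom_dur + params$pred_dur)
  events <- list(ev1, ev2)
  t_end <- loom_on2 + params$tail_s
  n <- round(t_end * rate) + 1
  tt <- (seq_len(n) - 1) / rate

  # per-event responses (latencies from loom onset)
  resp <- lapply(events, function(ev) {
    det <- stats::rlnorm(nb, params$detect_meanlog, params$detect_sdlog)
    det[det > params$detect_cap] <- NA_real_
    fly0 <- ifelse(is.na(det), Inf,
                   det + stats::rlnorm(nb, params$fly_delay_meanlog,
                                       params$fly_delay_sdlog))
    fly <- couple_fly_times(fly0, params$coupling, params$kernel_mean)
    fly[!is.finite(fly) | fly > params$fly_cap] <- NA_real_
    # a bird swept into flight before its own detection acts as a non-detector
    nondet <- !is.na(fly) & !is.na(det) & fly < det + 1
    det[nondet] <- NA_real_
    run <- det + pmax(stats::rlnorm(nb, params$run_delay_meanlog,
                                    params$run_delay_sdlog), 1)
    run[is.na(det) | run > params$run_cap] <- NA_real_
    run[!is.na(fly) & !is.na(run) & fly <= run] <- NA_real_
    run_dur <- stats::runif(nb, params$run_dur[1], params$run_dur[2])
    lapply(seq_len(nb), function(i)
      list(det = det[i], run = run[i], fly = fly[i], run_dur = run_dur[i]))
  })

  calib <- default_head_calibration()
  back_tmpl <- back_marker_template()
  noise_seeds <- sample.int(.Machine$integer.max, nb)
  fc <- scene$feeding_center; fr2 <- scene$feeding_rect / 2
  truth <- list()
  marker_rows <- list()

  for (i in seq_len(nb)) {
    p0 <- c(stats::runif(1, fc[1] - fr2[1], fc[1] + fr2[1]),
            stats::runif(1, fc[2] - fr2[2], fc[2] + fr2[2]))
    overrides <- list()
    for (e in 1:2) {
      r <- resp[[e]][[i]]; ev <- events[[e]]
      mxy <- scene$monitor_centers[[ev$side]][1:2]
      if (!is.na(r$run)) {
        f0 <- round((ev$t_loom_on + r$run) * rate) + 1
        f1 <- round((ev$t_loom_on + r$run + r$run_dur) * rate)
        if (!is.na(r$fly)) f1 <- min(f1, round((ev$t_loom_on + r$fly) * rate))
        overrides[[length(overrides) + 1]] <-
          list(f0 = f0, f1 = f1, speed = params$run_speed, monitor_xy = mxy,
               type = "run")
      }
      if (!is.na(r$fly)) {
        f0 <- round((ev$t_loom_on + r$fly) * rate) + 1
        f1 <- round((ev$t_loom_on + r$fly + params$fly_dur) * rate)
        overrides[[length(overrides) + 1]] <-
          list(f0 = f0, f1 = f1, speed = params$fly_speed, monitor_xy = mxy,
               type = "fly")
      }
    }
    bp <- simulate_body_path(n, rate, p0, overrides, params, scene)
    run_iv <- list(); fly_iv <- list()
    for (k in seq_along(overrides)) { # chronological; bursts end at landing
      o <- overrides[[k]]
      iv <- c(tt[o$f0], tt[min(bp$ov_end[k], n)])
      if (o$type == "run") run_iv[[length(run_iv) + 1]] <- iv
      else fly_iv[[length(fly_iv) + 1]] <- iv
    }
    resp_i <- lapply(resp, `[[`, i)
    hs <- script_head(n, rate, bp$pos, events, resp_i, scene, params)

    u <- cbind(sin(hs$yaw * pi / 180), cos(hs$yaw * pi / 180))
    origin <- cbind(bp$pos + params$head_forward * u, hs$zh)
    body3 <- cbind(bp$pos, params$body_z)
    keep <- hs$saccades$amplitude > 5 & hs$saccades$peak_speed > 60 &
      (hs$saccades$t_end - hs$saccades$t_start) >= 0.05 - 1e-9
    ev_truth <- lapply(1:2, function(e) {
      ev <- events[[e]]; r <- resp[[e]][[i]]
      f_on <- round(ev$t_loom_on * rate) + 1
      mc <- scene$monitor_centers[[ev$side]]
      list(side = ev$side,
           detection = hs$detections[e] - ev$t_loom_on,
           det_drawn = r$det, t_run = r$run, t_fly = r$fly,
           dist_monitor = sqrt(sum((body3[f_on, ] - mc)^2)))
    })
    truth[[birds[i]]] <- list(
      origin = origin, yaw = hs$yaw, pitch = hs$pitch, body = body3,
      theta = bp$theta,
      label = truth_labels(tt, hs$zh, hs$pitch, hs$pecks, run_iv, fly_iv,
                           params$body_z),
      pecks = hs$pecks, saccades = hs$saccades[keep, , drop = FALSE],
      foveations = hs$foveations, events = ev_truth)

    if (markers) {
      R <- yawpitch_rotation(hs$yaw, hs$pitch)
      rows <- vector("list", 8)
      for (k in 1:4) {
        p <- calib$marker_template[k, ]
        w <- origin
        for (j in 1:3)
          w[, j] <- origin[, j] + R[j, 1, ] * p[1] + R[j, 2, ] * p[2] +
            R[j, 3, ] * p[3]
        rows[[k]] <- data.frame(time = tt, pigeon_id = birds[i],
                                marker = paste0("h", k),
                                x = w[, 1], y = w[, 2], z = w[, 3])
      }
      ct <- cos(bp$theta); st <- sin(bp$theta)
      for (k in 1:4) {
        ck <- back_tmpl[k, ]
        rows[[4 + k]] <- data.frame(
          time = tt, pigeon_id = birds[i], marker = paste0("b", k),
          x = bp$pos[, 1] + ck[1] * ct - ck[2] * st,
          y = bp$pos[, 2] + ck[1] * st + ck[2] * ct,
          z = params$back_z + ck[3])
      }
      mk <- do.call(rbind, rows)
      # noise/dropout use a detached RNG substream so the scripted ground
      # truth is identical whether or not markers are emitted
      main_rng <- .Random.seed
      set.seed(noise_seeds[i])
      if (params$noise_sd > 0) {
        mk$x <- mk$x + stats::rnorm(nrow(mk), 0, params$noise_sd)
        mk$y <- mk$y + stats::rnorm(nrow(mk), 0, params$noise_sd)
        mk$z <- mk$z + stats::rnorm(nrow(mk), 0, params$noise_sd)
      }
      if (params$head_dropout > 0) {
        drop <- stats::runif(n) < params$head_dropout
        head_rows <- mk$marker %in% paste0("h", 1:4) & drop[match(mk$time, tt)]
        mk$x[head_rows] <- NA; mk$y[head_rows] <- NA; mk$z[head_rows] <- NA
      }
      assign(".Random.seed", main_rng, envir = globalenv())
      marker_rows[[i]] <- mk
    }
  }

  events_df <- do.call(rbind, lapply(1:2, function(e) {
    ev <- events[[e]]
    data.frame(trial = round, flock = flock, event_index = e, side = ev$side,
               t_loom_on = ev$t_loom_on, t_loom_off = ev$t_loom_off,
               t_pred_on = ev$t_pred_on, t_pred_off = ev$t_pred_off)
  }))
  structure(list(trial = round, flock = flock, pigeons = birds, rate = rate,
                 t = tt, events = events_df, truth = truth,
                 markers = if (markers) do.call(rbind, marker_rows) else NULL,
                 calib = calib, scene = scene, params = params, seed = seed),
            class = "flock_session")
}

#' @export
print.flock_session <- function(x, ...) {
  cat(sprintf(paste0("Synthetic flock session (trial %s, flock %s): %d birds, ",
                     "%.0f s at %.0f Hz, events at %s s\n"),
              x$trial, x$flock, length(x$pigeons),
              max(x$t), x$rate,
              paste(round(x$events$t_loom_on, 1), collapse = " and ")))
  invisible(x)
}

#' Simulate the full synthetic experiment
#'
#' Runs [simulate_session()] for every (or a subset of) flock-session of the
#' design, with per-session seeds derived deterministically from `seed`.
#'
#' @inheritParams simulate_session
#' @param rounds Rounds to simulate (default: all in the design).
#' @param flocks Flocks to simulate (default both).
#' @return Object of class `flock_sim`: list with `sessions`, `design`,
#'   `scene`, `params`.
#' @export
simulate_flock <- function(design = NULL, scene = simulate_scene(),
                           params = synth_params(), seed = 1, rounds = NULL,
                           flocks = c("A", "B"), markers = TRUE) {
  if (is.null(design)) design <- build_design(seed)
  if (is.null(rounds)) rounds <- sort(unique(design$events$trial))
  sessions <- list()
  for (r in rounds) for (f in flocks) {
    s_seed <- (seed * 997L + r * 131L + ifelse(f == "A", 0L, 67L)) %%
      .Machine$integer.max
    sessions[[paste0("t", r, f)]] <-
      simulate_session(design, r, f, scene, params, s_seed, markers)
  }
  structure(list(sessions = sessions, design = design, scene = scene,
                 params = params, seed = seed), class = "flock_sim")
}
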