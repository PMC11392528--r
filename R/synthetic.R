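#' Generator parameters for the synthetic flock experiment
#'
#' All tunable constants of the synthetic motion-capture experiment, with
#' defaults describing the emulated experiment: a 15 x 7 m room, flocks of 10
#' birds foraging on a central feeding area, 60 Hz kinematics, alternating
#' fixations (0.3-0.8 s) and head saccades (10-60 degrees at 100-500 deg/s),
#' pecking bouts, a 10 s looming stimulus followed by a ~3 s predator run,
#' lognormal detection latencies (median 3 s) and an exponential contagion
#' kernel for flight responses.
#'
#' @param ... Named overrides of any default listed below.
#' @return A named list of parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    rate = 60,              # Hz
    noise_sd = 0.001,       # marker noise, m
    head_dropout = 0,       # per-frame probability of losing the head cluster
    # body movement
    walk_speed = 0.1,       # m/s
    heading_sd = 1.5,       # heading random walk, rad / sqrt(s)
    body_z = 0.14,          # body centroid height, m
    back_z = 0.20,          # back-plate center height, m
    head_forward = 0.06,    # horizontal head offset from body centroid, m
    # head posture script, m / degrees
    z_scan = 0.28, z_feed = 0.10, z_dip = 0.07, z_groom = 0.18,
    pitch_feed = -25, pitch_dip = -45, pitch_groom = -120,
    # gaze dynamics
    fixation_dur = c(0.3, 0.8),      # s
    saccade_amp = c(10, 60),         # deg
    saccade_speed = c(100, 500),     # deg/s
    check_prob = 0.12,               # monitor-check probability per fixation
    check_dur = c(0.4, 0.8),         # s
    # foraging bouts
    feed_bout = c(5, 15), scan_bout = c(3, 8),
    groom_prob = 0.15, groom_bout = c(3, 6),
    peck_gap = c(0.5, 2),            # inter-peck wait, s
    # trial time course
    feeding_s = c(120, 300),         # free-feeding before each loom, s
    loom_dur = 10, pred_dur = 3, tail_s = 40,
    # responses
    detect_meanlog = log(3), detect_sdlog = 0.5, detect_cap = 12,
    run_delay_meanlog = log(2), run_delay_sdlog = 0.5, run_cap = 30,
    run_dur = c(0.5, 1), run_speed = 1.0,
    fly_delay_meanlog = log(8), fly_delay_sdlog = 0.4, fly_cap = 30,
    fly_dur = 1.0, fly_speed = 3.0,
    coupling = 1, kernel_mean = 0.3, # contagion strength and kernel scale, s
    alert_pause = c(10, 30)          # post-event vigilance pause, s
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown)) stop("unknown parameters: ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

#' Default head calibration used by the generator
#'
#' Eyes 2.2 cm apart, beak tip 4.5 cm from the head centroid and 30 degrees
#' below the local horizon, and a 3 cm tetrahedral cluster of four head
#' markers — all expressed in a frame in which the derived head axes are the
#' identity, so scripted orientations are directly comparable to fitted ones.
#'
#' @return A [head_calibration()].
#' @export
default_head_calibration <- function() {
  d <- 0.045
  head_calibration(
    eye_left = c(-0.011, 0, 0),
    eye_right = c(0.011, 0, 0),
    beak_tip = c(0, d * cos(-pi / 6), d * sin(-pi / 6)),
    marker_template = rbind(c(0.015, 0, 0.020),
                            c(-0.015, 0, 0.020),
                            c(0, 0.015, 0.035),
                            c(0, -0.015, 0.035)))
}

# back-plate marker template (7 x 3.5 cm styrofoam plate corners), body frame
back_marker_template <- function() {
  rbind(c(0.035, 0.0175, 0), c(0.035, -0.0175, 0),
        c(-0.035, -0.0175, 0), c(-0.035, 0.0175, 0))
}

#' Synthetic experimental scene
#'
#' A 15 x 7 m room with a predator hiding table and a monitor at each of two
#' opposite corners (labelled North and South) and a central feeding area.
#' Objects are spheres; default radii: monitor 0.35 m, hiding table 0.65 m
#' (conspecifics are represented by their body centroids with a 0.15 m
#' radius at projection time).
#'
#' @param room Room dimensions (m), width x depth x height.
#' @return A list with `objects` (named list of [scene_object()]), `room`,
#'   `feeding_center`, `feeding_rect` (length x width, m) and
#'   `monitor_centers` (per side).
#' @export
simulate_scene <- function(room = c(15, 7, 4)) {
  table_h <- 0.75
  monitor_c <- table_h + 0.185
  n_xy <- c(0.8, 0.8); s_xy <- c(room[1] - 0.8, room[2] - 0.8)
  objects <- list(
    monitor_N = scene_object("monitor_N", "monitor", c(n_xy, monitor_c), 0.35),
    monitor_S = scene_object("monitor_S", "monitor", c(s_xy, monitor_c), 0.35),
    table_N = scene_object("table_N", "hiding_table", c(n_xy, table_h / 2), 0.65),
    table_S = scene_object("table_S", "hiding_table", c(s_xy, table_h / 2), 0.65),
    feeding_area = scene_object("feeding_area", "feeding_area",
                                c(room[1] / 2, room[2] / 2, 0), 2.8))
  list(objects = objects, room = room,
       feeding_center = c(room[1] / 2, room[2] / 2),
       feeding_rect = c(4.2, 3.6),
       monitor_centers = list(North = objects$monitor_N$center,
                              South = objects$monitor_S$center))
}

#' Build the experimental design roster
#'
#' Twenty birds, six trial rounds; in each round the birds are split into two
#' flocks of ten (so 12 flock-sessions in total), under the constraint that
#' every pair of birds shares a flock in at least one round. Each session
#' receives two predator presentation events, one per side, with side order
#' counterbalanced across flocks within a round: 24 events and 240
#' bird-by-event observations in total. The partition is found by randomized
#' search with local repair (two birds never sharing a flock must have
#' complementary membership vectors; a targeted swap removes the violation).
#'
#' @param seed RNG seed.
#' @param n_pigeons,flock_size,n_rounds Design dimensions.
#' @param max_restarts Restarts of the randomized search.
#' @return Object of class `experiment_design`: `assignment` (birds x rounds
#'   flock matrix, values "A"/"B"), `events` (data.frame: trial, flock,
#'   event_index, side), `pigeons`, and counts `n_trials`, `n_events`,
#'   `n_observations`.
#' @export
build_design <- function(seed = 1, n_pigeons = 20, flock_size = 10,
                         n_rounds = 6, max_restarts = 50) {
  stopifnot(n_pigeons == 2 * flock_size)
  set.seed(seed)
  pigeons <- sprintf("p%02d", seq_len(n_pigeons))

  uncovered <- function(M) {
    # pairs never sharing a flock = complementary membership vectors
    out <- NULL
    for (i in 1:(n_pigeons - 1)) for (j in (i + 1):n_pigeons)
      if (all(M[i, ] != M[j, ])) out <- rbind(out, c(i, j))
    out
  }
  best <- NULL
  for (restart in seq_len(max_restarts)) {
    M <- vapply(seq_len(n_rounds), function(r) {
      a <- rep(FALSE, n_pigeons); a[sample(n_pigeons, flock_size)] <- TRUE; a
    }, logical(n_pigeons))
    for (iter in seq_len(200)) {
      un <- uncovered(M)
      if (is.null(un)) break
      pr <- un[sample(nrow(un), 1), ]
      r <- sample(n_rounds, 1)
      # move pr[2] into pr[1]'s flock by swapping with a same-flock bird
      mates <- setdiff(which(M[, r] == M[pr[1], r]), pr[1])
      k <- mates[sample(length(mates), 1)]
      M[c(pr[2], k), r] <- M[c(k, pr[2]), r]
    }
    if (is.null(uncovered(M))) { best <- M; break }
    if (is.null(best)) best <- M
  }
  if (!is.null(uncovered(best)))
    warning("pairing constraint not fully satisfied; returning best attempt")
  assignment <- ifelse(best, "A", "B")
  dimnames(assignment) <- list(pigeons, paste0("round", seq_len(n_rounds)))

  events <- do.call(rbind, lapply(seq_len(n_rounds), function(r) {
    first_a <- if (r %% 2 == 1) c("North", "South") else c("South", "North")
    rbind(data.frame(trial = r, flock = "A", event_index = 1:2, side = first_a),
          data.frame(trial = r, flock = "B", event_index = 1:2,
                     side = rev(first_a)))
  }))
  structure(list(assignment = assignment, events = events, pigeons = pigeons,
                 n_trials = n_rounds * 2, n_events = nrow(events),
                 n_observations = n_pigeons * n_rounds * 2),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(paste0("Experiment design: %d birds, %d flock-sessions, ",
                     "%d events, %d observations\n"),
              length(x$pigeons), x$n_trials, x$n_events, x$n_observations))
  invisible(x)
}

#' Roster of one flock-session
#'
#' @param design An `experiment_design`.
#' @param round Trial round (1-based).
#' @param flock `"A"` or `"B"`.
#' @return Character vector of pigeon ids.
#' @export
session_roster <- function(design, round, flock) {
  rownames(design$assignment)[design$assignment[, round] == flock]
}

# contagion kernel: after the earliest flyer, each remaining bird flies at
# the first flight time plus an exponential delay, truncated at (i.e. never
# later than) its own independent draw
couple_fly_times <- function(fly0, coupling, kernel_mean) {
  if (coupling <= 0 || all(!is.finite(fly0))) return(fly0)
  first <- min(fly0)
  out <- fly0
  others <- setdiff(seq_along(fly0), which.min(fly0))
  soc <- first + stats::rexp(length(others), rate = coupling / kernel_mean)
  out[others] <- pmin(fly0[others], soc)
  out
}

#' Latency model for detection and flight with social contagion
#'
#' Detection latencies are lognormal (median 3 s by default); each bird's
#' independent flight time is its detection plus a lognormal delay. With
#' coupling `c > 0`, after the earliest flyer every remaining bird flies at
#' the first flight time plus an Exp(mean `kernel_mean / c`) delay, truncated
#' at its own independent draw; `c = 0` leaves flight times i.i.d.
#' Latencies are measured from looming onset.
#'
#' @param n Flock size.
#' @param coupling Contagion strength `c >= 0`.
#' @param seed Optional RNG seed.
#' @param params A [synth_params()] list.
#' @return List with numeric vectors `detection` and `fly` (s; NA when capped
#'   as a non-response).
#' @export
simulate_latency_model <- function(n, coupling = 0, seed = NULL,
                                   params = synth_params()) {
  stopifnot(coupling >= 0)
  if (!is.null(seed)) set.seed(seed)
  detection <- stats::rlnorm(n, params$detect_meanlog, params$detect_sdlog)
  detection[detection > params$detect_cap] <- NA_real_
  fly0 <- ifelse(is.na(detection), Inf,
                 detection + stats::rlnorm(n, params$fly_delay_meanlog,
                                           params$fly_delay_sdlog))
  fly <- couple_fly_times(fly0, coupling, params$kernel_mean)
  fly[!is.finite(fly) | fly > params$fly_cap] <- NA_real_
  list(detection = detection, fly = fly)
}
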