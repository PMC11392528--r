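#' Analyse one session of marker data
#'
#' The full per-session chain: per-bird rigid pose fitting, gap filling,
#' implausible-motion masking, optional smoothing, saccade detection, the
#' rule-based ethogram, foveation events on the scene objects and
#' conspecifics, and per-bird-per-event latency and before-cue records.
#'
#' @param markers Long marker data.frame (see [read_markers()]).
#' @param events Data.frame with one row per predator presentation event:
#'   `trial`, `flock`, `event_index`, `side`, `t_loom_on`, `t_loom_off`,
#'   `t_pred_on`, `t_pred_off`.
#' @param scene A [simulate_scene()]-shaped scene description.
#' @param calib A [head_calibration()] (shared across birds, or a named list
#'   per bird).
#' @param cfg A [run_config()] list.
#' @return List with `latency` (tidy per-bird-per-event data.frame),
#'   `heat_angles` (pooled egocentric angles per object class),
#'   `series` and `saccades` (per bird), `foveation_events`.
#' @export
analyze_session <- function(markers, events, scene, calib,
                            cfg = run_config()) {
  pigeons <- sort(unique(markers$pigeon_id))
  nb <- length(pigeons)
  series <- list(); saccades <- list()
  for (pid in pigeons) {
    arr <- marker_arrays(markers, pid)
    cal <- if (inherits(calib, "head_calibration")) calib else calib[[pid]]
    ps <- fit_pose_series(arr$head, arr$back, cal, arr$t, pid)
    ps <- fill_gaps(ps, cfg$max_gap_s)
    ps <- mask_implausible(ps)
    if (!is.null(cfg$smooth_window_s))
      ps <- smooth_series(ps, cfg$smooth_window_s)
    series[[pid]] <- ps
    saccades[[pid]] <- detect_saccades(ps)
  }
  t <- series[[1]]$t
  n <- length(t)
  courting <- detect_courting(series)

  # per-frame foveation masks (saccade frames removed) and foveation events
  mon_names <- names(scene$monitor_centers)
  fove_mask_monitor <- list(); fove_events_cue <- list()
  fove_mask_consp <- list(); nn_idx <- list(); nn_dist <- list()
  ego <- list()
  for (i in seq_len(nb)) {
    pid <- pigeons[i]
    s <- series[[pid]]
    sac_mask <- saccade_frames(saccades[[pid]], t)
    per_mon <- list()
    for (mn in mon_names) {
      a <- egocentric_series(s, scene$monitor_centers[[mn]])
      per_mon[[mn]] <- a
    }
    ego[[pid]] <- per_mon
    mm <- Reduce(`|`, lapply(per_mon, function(a) {
      z <- is_foveated(a$azimuth, a$elevation, margin_deg = cfg$margin_deg,
                       fovea_azimuth = cfg$fovea_azimuth, either = TRUE)
      z[is.na(z)] <- FALSE; z
    }))
    fove_mask_monitor[[pid]] <- mm & !sac_mask & s$valid

    # conspecifics: nearest-neighbor bookkeeping and any-bird foveation
    cm <- rep(FALSE, n); bi <- s$body
    nnd <- rep(Inf, n); nni <- rep(NA_integer_, n)
    for (j in seq_len(nb)) {
      if (j == i) next
      bj <- series[[pigeons[j]]]$body
      a <- egocentric_series(s, bj)
      z <- is_foveated(a$azimuth, a$elevation, margin_deg = cfg$margin_deg,
                       fovea_azimuth = cfg$fovea_azimuth, either = TRUE)
      z[is.na(z)] <- FALSE
      cm <- cm | z
      d <- sqrt(rowSums((bj - bi)^2))
      upd <- !is.na(d) & d < nnd
      nnd[upd] <- d[upd]; nni[upd] <- j
    }
    fove_mask_consp[[pid]] <- cm & !sac_mask & s$valid
    nn_idx[[pid]] <- nni; nn_dist[[pid]] <- nnd
  }

  rows <- list(); heat <- list(active = NULL, other = NULL,
                               conspecific = NULL)
  fove_events_all <- list()
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    side <- ev$side
    other_side <- setdiff(mon_names, side)
    mon_c <- scene$monitor_centers[[side]]
    table_c <- scene$objects[[paste0("table_", substr(side, 1, 1))]]$center
    timelines <- compose_ethogram(series, mon_c, courting)
    for (i in seq_len(nb)) {
      pid <- pigeons[i]
      s <- series[[pid]]
      sac <- saccades[[pid]]
      cue_ev <- rbind(
        extract_foveation_events(s, mon_c, sac, margin_deg = cfg$margin_deg,
                                 min_duration_s = cfg$min_foveation_s),
        extract_foveation_events(s, table_c, sac, margin_deg = cfg$margin_deg,
                                 min_duration_s = cfg$min_foveation_s))
      fove_events_all[[paste(pid, e)]] <- cue_ev
      t_fove <- latency_to_foveate(cue_ev, ev$t_loom_on, ev$t_loom_off,
                                   cfg$onset_exclusion_s)
      esc <- escape_latencies(timelines[[i]], ev$t_loom_on, ev$t_loom_off)
      bc <- before_cue_metrics(timelines[[i]], sac, fove_mask_monitor[[pid]],
                               fove_mask_consp[[pid]], ev$t_loom_on,
                               cfg$before_cue_window_s)
      f_on <- which.min(abs(t - ev$t_loom_on))
      dist_mon <- sqrt(sum((s$body[f_on, ] - mon_c)^2))
      rows[[length(rows) + 1]] <- data.frame(
        trial = ev$trial, flock = ev$flock, event_index = ev$event_index,
        side = side, pigeon_id = pid,
        t_foveate = t_fove, t_run = esc$t_run, t_fly = esc$t_fly,
        escaped_before_offset = esc$escaped_before_offset,
        response_delay = esc$t_fly - t_fove,
        state_onset = state_at_onset(timelines[[i]], ev$t_loom_on),
        dist_monitor = dist_mon, dist_nn = nn_dist[[pid]][f_on],
        prop_head_up = bc$prop_head_up, peck_rate = bc$peck_rate,
        saccade_rate = bc$saccade_rate,
        prop_fove_monitor = bc$prop_fove_monitor,
        prop_fove_conspecific = bc$prop_fove_conspecific)

      # heatmap window: looming period, truncated at the first escape response
      esc_on <- suppressWarnings(min(esc$t_run, esc$t_fly, na.rm = TRUE))
      w_end <- min(ev$t_loom_off,
                   if (is.finite(esc_on)) ev$t_loom_on + esc_on else Inf)
      sel <- t >= ev$t_loom_on & t <= w_end & s$valid &
        !saccade_frames(sac, t)
      if (any(sel)) {
        aa <- ego[[pid]][[side]]
        heat$active <- rbind(heat$active, cbind(aa$azimuth[sel],
                                                aa$elevation[sel]))
        ao <- ego[[pid]][[other_side]]
        heat$other <- rbind(heat$other, cbind(ao$azimuth[sel],
                                              ao$elevation[sel]))
        nni <- nn_idx[[pid]]
        for (j in unique(nni[sel][!is.na(nni[sel])])) {
          idx <- which(sel & !is.na(nni) & nni == j)
          a <- egocentric_series(subset_series(s, idx),
                                 series[[pigeons[j]]]$body[idx, , drop = FALSE])
          heat$conspecific <- rbind(heat$conspecific,
                                    cbind(a$azimuth, a$elevation))
        }
      }
    }
  }
  list(latency = do.call(rbind, rows), heat_angles = heat,
       series = series, saccades = saccades, courting = courting,
       foveation_events = fove_events_all)
}

#' Run the full pipeline on a synthetic experiment
#'
#' Generates (or accepts) a synthetic flock experiment, analyses every
#' session ([analyze_session()]), pools the latency table, builds the
#' visual-field heatmaps per object class, and runs the contagion permutation
#' tests for escape and flight responses with and without the
#' distance-overlap control. When `cfg$out_dir` is set, writes the latency
#' table and heatmaps as CSV, the permutation results as JSON, and a run log.
#'
#' @param cfg A [run_config()] list.
#' @param params A [synth_params()] list for the generator.
#' @param sim Optionally a precomputed [simulate_flock()] result (overrides
#'   `cfg$rounds`/`cfg$flocks`).
#' @return Object of class `flockgaze_run`: `latency`, `heatmaps`,
#'   `contagion` (list of four `contagion_test`s), `design`, `cfg`.
#' @export
run_pipeline <- function(cfg = run_config(), params = synth_params(),
                         sim = NULL) {
  if (is.null(sim)) {
    design <- build_design(cfg$seed)
    sim <- simulate_flock(design, simulate_scene(), params, cfg$seed,
                          rounds = cfg$rounds, flocks = cfg$flocks)
  }
  res <- lapply(sim$sessions, function(ss)
    analyze_session(ss$markers, ss$events, ss$scene, ss$calib, cfg))
  latency <- do.call(rbind, lapply(res, `[[`, "latency"))
  rownames(latency) <- NULL

  heatmaps <- list()
  for (obj in c("active", "other", "conspecific")) {
    ang <- do.call(rbind, lapply(res, function(r) r$heat_angles[[obj]]))
    heatmaps[[obj]] <- if (is.null(ang)) NULL
    else visualfield_heatmap(ang[, 1], ang[, 2],
                             margin_deg = cfg$margin_deg,
                             fovea_azimuth = cfg$fovea_azimuth)
  }

  contagion <- list()
  k <- 0
  for (response in c("escape", "fly")) for (ctrl in c(FALSE, TRUE)) {
    k <- k + 1
    pairs <- contagion_pairs(latency, response)
    contagion[[paste0(response, if (ctrl) "_distctrl" else "")]] <-
      tryCatch(aggregate_contagion(pairs, n_perm = cfg$n_perm,
                                   seed = cfg$seed + k,
                                   control_distance = ctrl),
               error = function(e) NULL)
  }

  bundle <- structure(list(latency = latency, heatmaps = heatmaps,
                           contagion = contagion, design = sim$design,
                           cfg = cfg, params = params),
                      class = "flockgaze_run")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$latency, file.path(out_dir, "latency_table.csv"),
                   row.names = FALSE)
  hm <- NULL
  for (obj in names(bundle$heatmaps)) {
    h <- bundle$heatmaps[[obj]]
    if (is.null(h)) next
    grid <- expand.grid(az_bin = h$az_breaks[-length(h$az_breaks)],
                        el_bin = h$el_breaks[-length(h$el_breaks)])
    grid$freq <- as.vector(h$freq)
    grid$object <- obj
    hm <- rbind(hm, grid)
  }
  if (!is.null(hm))
    utils::write.csv(hm, file.path(out_dir, "heatmaps.csv"),
                     row.names = FALSE)
  cj <- lapply(bundle$contagion, function(x) {
    if (is.null(x)) return(NULL)
    list(observed_mean_gap = x$observed_mean_gap, p_value = x$p_value,
         n_perm = x$n_perm, n_pairs = x$n_pairs)
  })
  jsonlite::write_json(cj, file.path(out_dir, "contagion.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log <- c(sprintf("flockgaze run %s", format(Sys.time())),
           sprintf("seed: %d", bundle$cfg$seed),
           sprintf("n_perm: %d", bundle$cfg$n_perm),
           sprintf("observations: %d", nrow(bundle$latency)))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.flockgaze_run <- function(x, ...) {
  cat(sprintf("flockgaze pipeline run: %d bird-by-event observations\n",
              nrow(x$latency)))
  cat(sprintf("  foveated on cue: %d; ran: %d; flew: %d\n",
              sum(!is.na(x$latency$t_foveate)),
              sum(!is.na(x$latency$t_run)), sum(!is.na(x$latency$t_fly))))
  for (nm in names(x$contagion))
    if (!is.null(x$contagion[[nm]]))
      cat(sprintf("  contagion %-16s p = %.4g (obs gap %.3f s)\n", nm,
                  x$contagion[[nm]]$p_value,
                  x$contagion[[nm]]$observed_mean_gap))
  invisible(x)
}

#' Summary plots for a pipeline run
#'
#' Latency histograms, the visual-field heatmaps per object class, and the
#' permutation null distributions with the observed statistic.
#'
#' @param bundle A `flockgaze_run`.
#' @param file Optional PDF path; plots go to the active device when NULL.
#' @export
report <- function(bundle, file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 8, height = 6)
    on.exit(grDevices::dev.off())
  }
  lt <- bundle$latency
  graphics::par(mfrow = c(1, 2))
  if (any(!is.na(lt$t_foveate)))
    graphics::hist(lt$t_foveate, breaks = 20, col = "darkseagreen",
                   main = "Latency to foveate", xlab = "s from loom onset")
  if (any(!is.na(lt$t_fly)))
    graphics::hist(lt$t_fly, breaks = 20, col = "indianred",
                   main = "Latency to fly", xlab = "s from loom onset")
  graphics::par(mfrow = c(1, 1))
  for (obj in names(bundle$heatmaps))
    if (!is.null(bundle$heatmaps[[obj]]))
      plot(bundle$heatmaps[[obj]], main = paste("Visual field:", obj))
  for (nm in names(bundle$contagion))
    if (!is.null(bundle$contagion[[nm]]))
      plot(bundle$contagion[[nm]], main = paste("Contagion:", nm))
  invisible(bundle)
}
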