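# series holding a fixed object in/out of the foveal region
hold_series <- function(az_seq, rate = 60) {
  # object at 5 m straight north of the origin; yaw places it at each azimuth
  make_series(-az_seq + 0, rep(0, length(az_seq)), rate = rate)
}
obj_north <- c(0, 5, 0.05) # low elevation target

test_that("foveation events respect the 300 ms minimum and saccade removal", {
  # 1 s hold at azimuth 75 (right fovea), no saccades
  ps <- hold_series(rep(75, 90))
  ev <- extract_foveation_events(ps, obj_north, saccades = NULL)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$duration, 1)

  # 250 ms crossing is dropped
  ps2 <- hold_series(c(rep(0, 30), rep(75, 15), rep(0, 30)))
  expect_equal(nrow(extract_foveation_events(ps2, obj_north, NULL)), 0)

  # 1 s foveation split by a 100 ms mid-saccade into two 450 ms halves
  ps3 <- hold_series(rep(75, 60))
  sac <- data.frame(t_start = 27 / 60, t_end = 32 / 60, amplitude = 10,
                    peak_speed = 200)
  ev3 <- extract_foveation_events(ps3, obj_north, sac)
  expect_equal(nrow(ev3), 2)
  expect_true(all(ev3$duration >= 0.3))
  # and the same split below the minimum drops both halves
  sac2 <- data.frame(t_start = 17 / 60, t_end = 45 / 60, amplitude = 10,
                     peak_speed = 200)
  expect_equal(nrow(extract_foveation_events(ps3, obj_north, sac2)), 0)
})

test_that("cue-foveation latency applies the onset and offset exclusions", {
  ev <- function(starts, dur = 0.5)
    data.frame(t_start = starts, t_end = starts + dur,
               duration = rep(dur, length(starts)))
  expect_equal(latency_to_foveate(ev(11.5), 10, 20), 1.5)
  # an event already crossing the cue at onset does not qualify
  expect_equal(latency_to_foveate(ev(c(10.1, 12.0)), 10, 20), 2.0)
  expect_true(is.na(latency_to_foveate(ev(numeric(0)), 10, 20)))
  # first qualifying foveation after looming offset -> excluded case
  expect_true(is.na(latency_to_foveate(ev(21.0), 10, 20)))
})

fake_timeline <- function(n, rate = 60, runs = NULL, flies = NULL) {
  t <- (seq_len(n) - 1) / rate
  lab <- rep("head_up", n)
  for (iv in runs) lab[t >= iv[1] & t <= iv[2]] <- "running_away"
  for (iv in flies) lab[t >= iv[1] & t <= iv[2]] <- "flying"
  structure(list(pigeon_id = "x", t = t, rate = rate, label = lab,
                 pecks = numeric(0)), class = "behavior_timeline")
}

test_that("escape latencies and the before-offset flag follow the timeline", {
  tl <- fake_timeline(40 * 60, runs = list(c(28, 29)), flies = list(c(31, 32)))
  esc <- escape_latencies(tl, 20, 30)
  expect_equal(esc$t_run, 8)
  expect_equal(esc$t_fly, 11)
  expect_true(esc$escaped_before_offset) # run at +8 < 10 s loom

  tl2 <- fake_timeline(40 * 60, flies = list(c(32, 33)))
  esc2 <- escape_latencies(tl2, 20, 30)
  expect_true(is.na(esc2$t_run))
  expect_equal(esc2$t_fly, 12)
  expect_false(esc2$escaped_before_offset)

  esc3 <- escape_latencies(fake_timeline(40 * 60), 20, 30)
  expect_true(is.na(esc3$t_run) && is.na(esc3$t_fly))
  expect_false(esc3$escaped_before_offset)
})

test_that("visual-field heatmaps normalize to unit sum with logit fovea", {
  h <- visualfield_heatmap(rep(75, 100), rep(0, 100))
  expect_equal(sum(h$freq), 1)
  expect_equal(max(h$freq), 1) # single cell
  expect_equal(h$foveal_freq, 1)
  expect_equal(h$foveal_logit, log((1 - 1e-4) / 1e-4))

  h2 <- visualfield_heatmap(rep(0, 100), rep(0, 100))
  expect_equal(h2$foveal_freq, 0)
  expect_equal(h2$foveal_logit, log(1e-4 / (1 - 1e-4)))

  h3 <- visualfield_heatmap(c(rep(75, 50), rep(0, 50)), rep(0, 100))
  expect_equal(h3$foveal_freq, 0.5)
  expect_equal(h3$foveal_logit, 0)

  # unit sum for arbitrary angle clouds, including boundary angles
  set.seed(8)
  h4 <- visualfield_heatmap(runif(500, -180, 180) , runif(500, -90, 90))
  expect_equal(sum(h4$freq), 1)
  expect_equal(dim(h4$freq), c(72, 36))
  h5 <- visualfield_heatmap(c(-180, 180, 0), c(-90, 90, 0))
  expect_equal(sum(h5$freq), 1)
})

test_that("before-cue metrics summarize the 2-minute window", {
  tl <- fake_timeline(130 * 60)
  sac <- data.frame(t_start = numeric(0), t_end = numeric(0))
  m <- before_cue_metrics(tl, sac, rep(FALSE, 130 * 60), rep(FALSE, 130 * 60),
                          t_loom_on = 125)
  expect_equal(m$prop_head_up, 1)
  expect_equal(m$peck_rate, 0)

  tl$pecks <- seq(10, 124, length.out = 24)
  m2 <- before_cue_metrics(tl, sac, rep(FALSE, 130 * 60),
                           rep(FALSE, 130 * 60), t_loom_on = 125)
  expect_equal(m2$peck_rate, 0.2)
})

test_that("state at looming onset collapses to head-up/feeding/other", {
  tl <- fake_timeline(600)
  tl$label[301] <- "feeding"
  expect_equal(state_at_onset(tl, 300 / 60), "feeding")
  tl$label[301] <- "grooming"
  expect_equal(state_at_onset(tl, 300 / 60), "other")
  tl$label[301] <- "head_up"
  expect_equal(state_at_onset(tl, 300 / 60), "head_up")
})

test_that("recovered response delays match the scripted delay distribution", {
  # event-logic check at scale: scripted foveations and behavior timelines
  # from the generator's fast path, pushed through the latency extraction
  design <- build_design(3)
  p <- synth_params(feeding_s = c(10, 14), tail_s = 20, coupling = 1)
  rec <- c(); scripted <- c()
  for (r in 1:6) for (fl in c("A", "B")) {
    ss <- simulate_session(design, r, fl, simulate_scene(), p,
                           seed = 100 + 10 * r + (fl == "B"), markers = FALSE)
    for (pid in ss$pigeons) {
      tr <- ss$truth[[pid]]
      tl <- structure(list(pigeon_id = pid, t = ss$t, rate = ss$rate,
                           label = tr$label, pecks = tr$pecks),
                      class = "behavior_timeline")
      for (e in 1:2) {
        ev <- ss$events[e, ]
        fv <- tr$foveations[tr$foveations$object == ev$side, , drop = FALSE]
        names(fv) <- c("t_start", "t_end", "object")
        tf <- latency_to_foveate(fv, ev$t_loom_on, ev$t_loom_off)
        esc <- escape_latencies(tl, ev$t_loom_on, ev$t_loom_off)
        gt <- tr$events[[e]]
        if (!is.na(tf) && !is.na(esc$t_fly)) rec <- c(rec, esc$t_fly - tf)
        if (!is.na(gt$detection) && !is.na(gt$t_fly))
          scripted <- c(scripted, gt$t_fly - gt$detection)
      }
    }
  }
  expect_gte(length(rec), 100)
  ks <- suppressWarnings(stats::ks.test(rec, scripted))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(rec > 0))
})
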