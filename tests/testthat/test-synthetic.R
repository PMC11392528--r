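test_that("the design replica has the stated dimensions and pairing", {
  d <- build_design(1)
  expect_equal(d$n_trials, 12)
  expect_equal(d$n_events, 24)
  expect_equal(d$n_observations, 240)
  expect_equal(nrow(d$events), 24)
  # every bird in exactly one flock of 10 per round
  expect_true(all(colSums(d$assignment == "A") == 10))
  # pairing constraint: no pair of birds always separated
  M <- d$assignment
  for (i in 1:19) for (j in (i + 1):20)
    expect_true(any(M[i, ] == M[j, ]))
  # sides counterbalanced: each trial x side has one event per flock
  tab <- table(d$events$trial, d$events$side, d$events$flock)
  expect_true(all(tab == 1))
  # scaled-down accounting: n birds x rounds x events per session
  d2 <- build_design(5, n_pigeons = 4, flock_size = 2, n_rounds = 3)
  expect_equal(d2$n_observations, 4 * 3 * 2)
})

test_that("the scene matches the room geometry", {
  sc <- simulate_scene()
  m <- sc$monitor_centers
  expect_gt(sqrt(sum((m$North - m$South)^2)), 12)
  dN <- sqrt(sum((sc$feeding_center - m$North[1:2])^2))
  dS <- sqrt(sum((sc$feeding_center - m$South[1:2])^2))
  expect_lt(abs(dN - dS), 0.5)
  for (ob in sc$objects) {
    expect_gt(ob$radius, 0)
    expect_true(ob$center[3] >= 0 && ob$center[3] <= 4)
  }
})

test_that("the latency model couples flight times as specified", {
  set.seed(31)
  # c = 0: flight latencies are independent detection + delay draws
  l0 <- simulate_latency_model(10, 0)
  expect_true(all(is.na(l0$fly) | l0$fly > l0$detection, na.rm = TRUE))
  # strong coupling collapses the gaps after the first flyer
  lc <- simulate_latency_model(200, 50, seed = 5)
  g <- diff(sort(lc$fly[!is.na(lc$fly)]))
  expect_lt(mean(g), 0.05)
  # mean gap strictly smaller under coupling (Monte Carlo at n = 10)
  gap_mean <- function(cc) {
    mean(replicate(300, {
      f <- simulate_latency_model(10, cc)$fly
      f <- f[!is.na(f)]
      if (length(f) < 2) NA else mean(diff(sort(f)))
    }), na.rm = TRUE)
  }
  set.seed(37)
  expect_lt(gap_mean(1), gap_mean(0))
  expect_error(simulate_latency_model(5, -1), "coupling")
})

test_that("same seed gives identical sessions, markers included", {
  d <- build_design(1)
  p <- synth_params(feeding_s = c(8, 10), tail_s = 18)
  s1 <- simulate_session(d, 2, "B", simulate_scene(), p, seed = 9)
  s2 <- simulate_session(d, 2, "B", simulate_scene(), p, seed = 9)
  expect_identical(s1$markers, s2$markers)
  expect_identical(s1$truth, s2$truth)
  # and the scripted truth does not depend on marker emission
  s3 <- simulate_session(d, 2, "B", simulate_scene(), p, seed = 9,
                         markers = FALSE)
  expect_identical(s1$truth, s3$truth)
  expect_null(s3$markers)
})

test_that("ground truth and emitted kinematics are mutually consistent", {
  ss <- small_session()
  rate <- ss$rate
  for (pid in ss$pigeons[1:4]) {
    tr <- ss$truth[[pid]]
    sp <- sqrt(rowSums(diff(tr$body[, 1:2])^2)) * rate # step speed
    # frames labelled flying move faster than 2 m/s (interior of each run;
    # bursts may end early when the bird reaches the room margin and lands)
    runs <- rle(tr$label == "flying")
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    for (k in which(runs$values & runs$lengths > 2)) {
      inner <- (starts[k] + 1):(ends[k] - 1)
      expect_gt(min(sp[inner - 1]), 2)
    }
    for (e in 1:2) {
      gt <- tr$events[[e]]
      if (!is.na(gt$detection))
        expect_gte(gt$detection, 0.2) # detections respect the reaction floor
    }
    # scripted intervals lie within the session time span
    expect_true(all(tr$saccades$t_end <= max(ss$t) + 1e-9))
    expect_true(all(tr$pecks <= max(ss$t)))
  }
})

test_that("emitted markers round-trip through preprocessing cleanly", {
  ss <- small_session()
  arr <- marker_arrays(ss$markers, ss$pigeons[1])
  ps <- fit_pose_series(arr$head, arr$back, ss$calib, arr$t, ss$pigeons[1])
  expect_true(mean(ps$valid) > 0.99)
  masked <- mask_implausible(fill_gaps(ps))
  expect_lt(mean(ps$valid) - mean(masked$valid), 0.01) # < 1% flagged
  # zero-noise poses reproduce the scripted orientations
  tr <- ss$truth[[ss$pigeons[1]]]
  for (i in c(10, 500, 2000)) {
    R_gt <- rot_z_ref(-tr$yaw[i]) %*% rot_x_ref(tr$pitch[i])
    expect_lt(geodesic_angle(R_gt, ps$rotation[, , i]), 1e-4)
  }
  expect_lt(max(abs(ps$body[2, ] - tr$body[2, ])), 1e-9)
})
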