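test_that("gap filling interpolates short gaps and leaves long ones", {
  yaw <- c(rep(0, 10), rep(NA, 3), rep(30, 10))
  ps <- make_series(yaw)
  ps$origin[11:13, ] <- NA
  filled <- fill_gaps(ps)
  expect_true(all(filled$valid))
  got <- sapply(11:13, function(i) geodesic_angle(diag(3),
                                                  filled$rotation[, , i]))
  expect_equal(got, c(7.5, 15, 22.5), tolerance = 1e-6)
  expect_equal(filled$origin[11:13, 1], rep(0, 3))

  # constant endpoints -> constant fill
  yaw2 <- c(rep(10, 5), rep(NA, 3), rep(10, 5))
  f2 <- fill_gaps(make_series(yaw2))
  expect_true(all(f2$valid))
  expect_lt(geodesic_angle(f2$rotation[, , 6], f2$rotation[, , 1]), 1e-9)

  # 30-frame gap exceeds the 0.2 s default
  yaw3 <- c(rep(0, 10), rep(NA, 30), rep(30, 10))
  f3 <- fill_gaps(make_series(yaw3))
  expect_true(all(!f3$valid[11:40]))
})

test_that("gap filling never modifies observed frames", {
  set.seed(2)
  yaw <- cumsum(rnorm(50))
  ps <- make_series(yaw)
  ps$valid[20:22] <- FALSE; ps$rotation[, , 20:22] <- NA
  ps$origin[20:22, ] <- NA
  filled <- fill_gaps(ps)
  obs <- setdiff(1:50, 20:22)
  expect_identical(filled$origin[obs, ], ps$origin[obs, ])
  expect_identical(filled$rotation[, , obs], ps$rotation[, , obs])
})

test_that("smoothing attenuates spikes and oscillations predictably", {
  ps <- make_series(rep(0, 50))
  expect_equal(smooth_series(ps, 0.1)$origin, ps$origin) # constant unchanged

  ps$origin[25, 1] <- 0.05
  sm <- smooth_series(ps, 5 / 60) # 5-frame window: spike / 5
  expect_lte(max(abs(sm$origin[, 1])), 0.01 + 1e-12)

  # 15 Hz sine at 60 Hz through a 3-frame average: gain (1 + 2 cos(pi/2))/3
  n <- 240; t <- (0:(n - 1)) / 60
  ps2 <- make_series(rep(0, n))
  ps2$origin[, 1] <- sin(2 * pi * 15 * t)
  sm2 <- smooth_series(ps2, 3 / 60)
  mid <- 30:(n - 30)
  gain <- max(abs(sm2$origin[mid, 1])) / 1
  expect_equal(gain, 1 / 3, tolerance = 0.02)
})

test_that("angular speed matches scripted rotation rates", {
  ps <- make_series(rep(5, 20))
  expect_true(all(angular_speed(ps)[-1] < 1e-9))

  yaw <- seq(0, by = 2, length.out = 100) # 120 deg/s at 60 Hz
  s <- angular_speed(make_series(yaw))
  expect_equal(s[-1], rep(120, 99), tolerance = 1e-6)

  # mixed yaw+pitch steps: compare against the closed-form geodesic angle
  ps3 <- make_series(c(0, 3), c(0, 4))
  R1 <- rot_z_ref(0); R2 <- rot_z_ref(-3) %*% rot_x_ref(4)
  tr <- sum(diag(crossprod(R1, R2)))
  expected <- acos((tr - 1) / 2) * 180 / pi * 60
  expect_equal(angular_speed(ps3)[2], expected, tolerance = 1e-9)
})

test_that("saccade detection applies the amplitude/duration/speed rules", {
  expect_equal(nrow(detect_saccades(make_series(rep(0, 100)))), 0)

  # 20 degrees at 120 deg/s (~167 ms)
  yaw <- c(rep(0, 50), seq(2, 20, by = 2), rep(20, 50))
  sac <- detect_saccades(make_series(yaw))
  expect_equal(nrow(sac), 1)
  expect_equal(sac$amplitude, 20, tolerance = 1e-6)
  expect_equal(sac$t_end - sac$t_start, 10 / 60, tolerance = 1e-9)

  # 3 degrees at 90 deg/s: fast enough but below the 5-degree amplitude
  yaw2 <- c(rep(0, 50), seq(1.5, 3, by = 1.5), rep(3, 50))
  expect_equal(nrow(detect_saccades(make_series(yaw2))), 0)
})

test_that("saccades and fixations partition the valid frames", {
  set.seed(4)
  # random scripted saccade/fixation sequence
  yaw <- numeric(0)
  cur <- 0
  for (k in 1:15) {
    yaw <- c(yaw, rep(cur, sample(20:50, 1)))
    amp <- runif(1, 6, 40) * sample(c(-1, 1), 1)
    speed <- runif(1, 70, 500)
    steps <- max(3, round(abs(amp) / speed * 60))
    yaw <- c(yaw, cur + seq_len(steps) / steps * amp)
    cur <- cur + amp
  }
  ps <- make_series(yaw)
  sac <- detect_saccades(ps)
  fix <- fixation_intervals(ps, sac)
  in_sac <- saccade_frames(sac, ps$t)
  in_fix <- in_intervals_ref(ps$t, fix)
  expect_true(all(xor(in_sac, in_fix)))

  # recall: every scripted saccade (amp 6-40 at 70-500 deg/s) is recovered
  expect_equal(nrow(sac), 15)
})

test_that("saccade detection is invariant to a global rigid world rotation", {
  set.seed(5)
  yaw <- c(rep(0, 40), seq(3, 30, by = 3), rep(30, 40))
  ps <- make_series(yaw)
  Q <- random_rotation()
  ps2 <- ps
  for (i in seq_along(ps$t)) ps2$rotation[, , i] <- Q %*% ps$rotation[, , i]
  ps2$origin <- t(Q %*% t(ps$origin))
  expect_equal(detect_saccades(ps), detect_saccades(ps2), tolerance = 1e-9)
})

test_that("implausible single-frame spikes are masked", {
  ps <- make_series(rep(0, 60))
  ps$origin[30, 1] <- 2 # 2 m jump within one frame: 120 m/s in and out
  masked <- mask_implausible(ps)
  expect_false(masked$valid[30])
  expect_true(all(masked$valid[-30]))
})
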