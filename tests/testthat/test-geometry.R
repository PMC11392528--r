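test_that("local head axes invert the 30-degree beak offset", {
  # beak placed 30 degrees below the horizon -> forward axis is horizontal
  ax <- build_local_axes(c(-1, 0, 0), c(1, 0, 0),
                         c(0, cos(-pi / 6), sin(-pi / 6)))
  expect_equal(ax[, 1], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ax[, 2], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(ax[, 3], c(0, 0, 1), tolerance = 1e-12)

  # horizontal beak -> forward axis tilted 30 degrees up
  ax2 <- build_local_axes(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(ax2[, 2], c(0, cos(pi / 6), sin(pi / 6)), tolerance = 1e-12)
  expect_true(abs(det(ax2) - 1) < 1e-9)
})

test_that("local axes are equivariant under rigid motions of the keypoints", {
  set.seed(101)
  el <- c(-0.011, 0.002, 0.001); er <- c(0.012, 0, -0.001)
  bk <- c(0.002, 0.04, -0.02)
  base <- build_local_axes(el, er, bk)
  for (k in 1:10) {
    Q <- random_rotation(); tr <- rnorm(3)
    moved <- build_local_axes(as.numeric(Q %*% el + tr),
                              as.numeric(Q %*% er + tr),
                              as.numeric(Q %*% bk + tr))
    expect_lt(max(abs(moved - Q %*% base)), 1e-9)
  }
})

test_that("degenerate calibration geometry is rejected", {
  expect_error(build_local_axes(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0)),
               "eyes")
  expect_error(build_local_axes(c(-1, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "collinear")
  expect_error(head_calibration(c(-1, 0, 0), c(1, 0, 0), c(0, 1, 0),
                                rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("rigid head-pose fit recovers applied transforms", {
  cal <- default_head_calibration()
  f <- fit_head_pose(cal$marker_template, cal)
  expect_true(f$valid)
  expect_lt(f$rms, 1e-12)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-9)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-12)

  set.seed(7)
  for (k in 1:10) {
    Q <- random_rotation(); tr <- rnorm(3)
    obs <- sweep(cal$marker_template %*% t(Q), 2, -tr)
    f2 <- fit_head_pose(obs, cal)
    expect_lt(max(abs(f2$rotation - Q %*% cal$axes)), 1e-9)
    expect_lt(max(abs(f2$origin - (as.numeric(Q %*% cal$origin) + tr))), 1e-9)
  }
})

test_that("pose fit degrades gracefully with missing markers", {
  cal <- default_head_calibration()
  obs <- cal$marker_template
  obs[4, ] <- NA # 3 exact markers still determine the pose
  f <- fit_head_pose(obs, cal)
  expect_true(f$valid)
  expect_lt(f$rms, 1e-12)
  expect_lt(max(abs(f$rotation - diag(3))), 1e-9)

  obs[3, ] <- NA
  f2 <- fit_head_pose(obs, cal)
  expect_false(f2$valid)
  expect_true(all(is.na(f2$origin)))
})

test_that("egocentric projection follows the az/el conventions", {
  expect_equal(unname(world_to_head(c(0, 5, 0), c(0, 0, 0), diag(3))),
               c(0, 0), tolerance = 1e-12)
  expect_equal(unname(world_to_head(c(5, 0, 0), c(0, 0, 0), diag(3))),
               c(90, 0), tolerance = 1e-12)
  expect_equal(unname(world_to_head(c(0, 0, 3), c(0, 0, 0), diag(3))[2]), 90,
               tolerance = 1e-12)
  expect_error(world_to_head(c(0, 0, 0), c(0, 0, 0), diag(3)), "coincides")
})

test_that("a head foveating one monitor sees the opposite monitor at -105", {
  scene <- simulate_scene()
  mA <- scene$monitor_centers$North; mB <- scene$monitor_centers$South
  mid <- (mA + mB) / 2
  # yaw that puts monitor A at azimuth +75
  alpha <- atan2(mA[1] - mid[1], mA[2] - mid[2]) * 180 / pi
  R <- rot_z_ref(-(alpha - 75))
  expect_equal(unname(world_to_head(mA, mid, R)["azimuth"]), 75,
               tolerance = 1e-9)
  expect_equal(unname(world_to_head(mB, mid, R)["azimuth"]), -105,
               tolerance = 1e-9)
})

test_that("world/head round trip preserves directions", {
  set.seed(33)
  for (k in 1:20) {
    R <- random_rotation(); o <- rnorm(3); p <- rnorm(3, sd = 3)
    if (sqrt(sum((p - o)^2)) < 1e-3) next
    a <- world_to_head(p, o, R)
    d <- head_to_world(a["azimuth"], a["elevation"], R)
    expect_lt(max(abs(d - unit_ref(p - o))), 1e-9)
  }
})

test_that("foveal offset and rectangular foveation behave as specified", {
  expect_equal(offset_from_fovea(75, 0, "right"), 0, tolerance = 1e-12)
  expect_equal(offset_from_fovea(-75, 0, "left"), 0, tolerance = 1e-12)
  expect_equal(offset_from_fovea(75, 10, "right"), 10, tolerance = 0.01)
  expect_true(offset_from_fovea(80, 5, "right") > 0)

  expect_true(is_foveated(75, 0, "right"))
  expect_false(is_foveated(64.9, 0, "right"))
  expect_true(is_foveated(80, -10, "right")) # inclusive boundary
  expect_true(is_foveated(-75, 0, "left"))
  expect_true(is_foveated(-75, 0, either = TRUE))
})

test_that("marker noise maps onto orientation error at the cluster scale", {
  # with a ~3 cm marker cluster, 1 mm of isotropic noise leaves a few
  # degrees of per-frame orientation error; 5 mm is crippling relative to
  # the 10-degree foveal margin
  cal <- default_head_calibration()
  err_at <- function(sd, n = 400) {
    mean(vapply(seq_len(n), function(i) {
      obs <- cal$marker_template + matrix(rnorm(12, 0, sd), 4, 3)
      f <- fit_head_pose(obs, cal)
      geodesic_angle(f$rotation, diag(3))
    }, 0))
  }
  set.seed(12)
  e1 <- err_at(0.001); e5 <- err_at(0.005)
  expect_gt(e1, 0.5); expect_lt(e1, 5)
  expect_gt(e5, 3)
  expect_gt(e5, 2 * e1)
})

test_that("mirror symmetry swaps left/right foveation verdicts", {
  set.seed(9)
  az <- runif(200, -180, 180); el <- runif(200, -90, 90)
  expect_identical(is_foveated(az, el, "right"), is_foveated(-az, el, "left"))
})
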