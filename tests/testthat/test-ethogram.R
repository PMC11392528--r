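test_that("head-down uses a strict vertical comparison", {
  expect_true(classify_head_down(0.10, 0.14))
  expect_false(classify_head_down(0.14, 0.14))
  expect_true(is.na(classify_head_down(NA, 0.14)))
})

test_that("peck detection finds the beak-height minimum of each dip", {
  t <- (0:99) / 60
  beak <- rep(0.06, 100)
  beak[40:49] <- c(0.03, 0.02, 0.015, 0.012, 0.011, 0.010, 0.012, 0.015,
                   0.02, 0.03)
  pitch <- rep(-40, 100)
  pecks <- detect_pecks(beak, pitch, t)
  expect_equal(pecks, t[45]) # argmin frame

  expect_length(detect_pecks(rep(0.05, 100), pitch, t), 0)

  # two dips separated by a rise above 4 cm -> two pecks
  beak2 <- rep(0.06, 200)
  beak2[30:35] <- 0.01; beak2[130:135] <- 0.01
  pecks2 <- detect_pecks(beak2, rep(-40, 200), (0:199) / 60)
  expect_length(pecks2, 2)
  expect_equal(pecks2, c(29, 129) / 60) # earliest frame on ties

  # beak oriented toward the body (pitch <= -100) never pecks
  expect_length(detect_pecks(beak, rep(-120, 100), t), 0)
})

test_that("feeding intervals chain pecks no more than 6 s apart", {
  expect_equal(feeding_intervals(c(0, 3, 5)),
               data.frame(t_start = 0, t_end = 5))
  expect_equal(nrow(feeding_intervals(c(0, 10))), 0)
  expect_equal(feeding_intervals(c(0, 5, 12, 14)),
               data.frame(t_start = c(0, 12), t_end = c(5, 14)))
  expect_equal(nrow(feeding_intervals(numeric(0))), 0)
})

grooming_series <- function(pitch_deg, head_z = 0.18, body_xy_off = 0.06) {
  n <- 20
  body <- cbind(rep(0, n), rep(0, n), rep(0.14, n))
  origin <- cbind(rep(0, n), rep(body_xy_off, n), rep(head_z, n))
  make_series(rep(0, n), rep(pitch_deg, n), origin = origin, body = body,
              beak_local = c(0, 0.039, -0.0225))
}

test_that("grooming posture rules fire on breast-preening pitches", {
  expect_true(all(detect_grooming(grooming_series(-110))))   # pitch < -100
  # pitch -85 with the head-direction/body-head angle above 60 degrees:
  # head straight above the body looking down
  s <- grooming_series(-85, head_z = 0.30, body_xy_off = 0)
  expect_true(all(detect_grooming(s)))
  # upright scanning posture
  expect_false(any(detect_grooming(grooming_series(-10, head_z = 0.28))))
})

courting_pair <- function(dist_m, n_bows, pitch_amp = 35) {
  rate <- 60; n <- 20 * rate
  pitch_a <- rep(0, n)
  # bows: 0.5 s dips spaced 2 s apart, starting at 6 s
  for (b in seq_len(n_bows)) {
    f0 <- (6 + 2 * (b - 1)) * rate
    pitch_a[f0:(f0 + 15)] <- -pitch_amp * seq(1, 15, length.out = 16) / 15
    pitch_a[(f0 + 16):(f0 + 30)] <- -pitch_amp * seq(14, 0, length.out = 15) / 15
  }
  body_a <- cbind(rep(0, n), rep(0, n), rep(0.14, n))
  body_b <- cbind(rep(0, n), rep(dist_m, n), rep(0.14, n))
  # bird a faces +y (toward b); bird b faces away
  sa <- make_series(rep(0, n), pitch_a, origin = body_a + rep(c(0, 0, 0.12),
                                                             each = n),
                    body = body_a, beak_local = c(0, 0.039, -0.0225))
  sb <- make_series(rep(180, n), rep(0, n),
                    origin = body_b + rep(c(0, 0, 0.12), each = n),
                    body = body_b, beak_local = c(0, 0.039, -0.0225))
  list(sa, sb)
}

test_that("courtship needs repeated bows, proximity and orientation", {
  res <- detect_courting(courting_pair(0.4, 3))
  expect_true(any(res$courting[, 1]))
  expect_true(any(res$courted[, 2]))
  expect_false(any(res$courting[, 2])) # the courted bird is not courting

  res_far <- detect_courting(courting_pair(1.0, 3))
  expect_false(any(res_far$courting[, 1])) # proximity rule

  res_single <- detect_courting(courting_pair(0.4, 1))
  expect_false(any(res_single$courting[, 1])) # rate rule
})

run_series <- function(speed, radial = TRUE, n = 120) {
  # body moving at `speed` m/s; monitor on the -y axis so +y motion is radial
  rate <- 60
  dir <- if (radial) c(0, 1) else c(1, 0)
  xy0 <- c(5, 5)
  pos <- cbind(xy0[1] + dir[1] * speed * (0:(n - 1)) / rate,
               xy0[2] + dir[2] * speed * (0:(n - 1)) / rate, 0.14)
  make_series(rep(0, n), rep(0, n),
              origin = pos + rep(c(0, 0.06, 0.14), each = n), body = pos,
              beak_local = c(0, 0.039, -0.0225))
}

test_that("running away needs speed, radial motion and no courtship", {
  monitor <- c(5, -8, 0.9)
  iv <- detect_running_away(run_series(1.0), monitor)
  expect_equal(nrow(iv), 1)
  expect_gte(iv$t_end - iv$t_start, 0.5)

  # tangential motion: distance from the monitor barely grows
  expect_equal(nrow(detect_running_away(run_series(1.0, radial = FALSE,
                                                   n = 90), monitor)), 0)
  # courting exclusion
  mask <- rep(TRUE, 120)
  expect_equal(nrow(detect_running_away(run_series(1.0), monitor, mask)), 0)
  # slow walking
  expect_equal(nrow(detect_running_away(run_series(0.4), monitor)), 0)
})

test_that("flying needs > 2 m/s for at least 70 ms", {
  expect_equal(nrow(detect_flying(run_series(3.0))), 1)
  expect_equal(nrow(detect_flying(run_series(1.9))), 0)
  s <- run_series(0.05, n = 60)
  s$body[30:32, 2] <- s$body[30:32, 2] + c(0.05, 0.10, 0.15) # 50 ms burst
  expect_equal(nrow(detect_flying(s)), 0)
})

test_that("ethogram labels resolve by precedence and partition frames", {
  ss <- small_session()
  res <- small_analysis()
  mon <- ss$scene$monitor_centers[[ss$events$side[1]]]
  tl <- compose_ethogram(res$series, mon, res$courting)
  lab <- tl[[1]]$label
  expect_true(all(lab %in% c("flying", "running_away", "courting", "grooming",
                             "feeding", "head_down", "head_up", "missing")))
  expect_length(lab, length(res$series[[1]]$t))
  # a frame qualifying as feeding and head-down is labelled feeding
  s1 <- res$series[[1]]
  feed <- in_intervals_ref(tl[[1]]$t, feeding_intervals(tl[[1]]$pecks))
  down <- s1$origin[, 3] < s1$body[, 3]
  both <- which(feed & down & s1$valid & lab != "grooming" &
                lab != "courting" & lab != "running_away" & lab != "flying")
  expect_true(length(both) > 0)
  expect_true(all(lab[both] == "feeding"))
  # masked frames are missing
  s1$valid[10] <- FALSE
  tl2 <- compose_ethogram(stats::setNames(list(s1), s1$pigeon_id), mon)
  expect_equal(tl2[[1]]$label[10], "missing")
})
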