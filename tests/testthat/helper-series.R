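# Test helpers: independent construction of rotation series (explicit
# Rz(-yaw) %*% Rx(pitch) products, not the package's own builders), small
# fixture sessions, and a one-way agreement ICC.

rot_z_ref <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
rot_x_ref <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# pose series with scripted yaw/pitch (degrees), optional origins
make_series <- function(yaw, pitch = rep(0, length(yaw)),
                        origin = matrix(0, length(yaw), 3), rate = 60,
                        valid = NULL, body = NULL, beak_local = NULL,
                        id = "test") {
  n <- length(yaw)
  R <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n))
    if (!is.na(yaw[i]))
      R[, , i] <- rot_z_ref(-yaw[i]) %*% rot_x_ref(pitch[i])
  if (is.null(valid)) valid <- !is.na(yaw)
  pose_series(id, (seq_len(n) - 1) / rate, origin, R, valid, body = body,
              beak_local = beak_local, rate = rate)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

unit_ref <- function(v) v / sqrt(sum(v^2))

in_intervals_ref <- function(t, iv) {
  out <- rep(FALSE, length(t))
  for (r in seq_len(nrow(iv)))
    out <- out | (t >= iv$t_start[r] - 1e-9 & t <= iv$t_end[r] + 1e-9)
  out
}

# one-way agreement ICC between two measurement vectors
icc_oneway <- function(x, y) {
  d <- data.frame(v = c(x, y), subj = factor(rep(seq_along(x), 2)))
  ms <- suppressWarnings(anova(stats::aov(v ~ subj, data = d)))
  msb <- ms$`Mean Sq`[1]; msw <- ms$`Mean Sq`[2]
  (msb - msw) / (msb + msw)
}

# shared small zero-noise session fixture (built once per test run)
.fixtures <- new.env()
small_session <- function() {
  if (is.null(.fixtures$ss)) {
    design <- build_design(1)
    p <- synth_params(feeding_s = c(12, 18), tail_s = 22, noise_sd = 0)
    .fixtures$design <- design
    .fixtures$params <- p
    .fixtures$ss <- simulate_session(design, 1, "A", simulate_scene(), p,
                                     seed = 42)
  }
  .fixtures$ss
}

# cached zero-noise analysis of the fixture session (no smoothing)
small_analysis <- function() {
  if (is.null(.fixtures$res)) {
    ss <- small_session()
    .fixtures$res <- analyze_session(ss$markers, ss$events, ss$scene,
                                     ss$calib, run_config(smooth_window_s = NULL))
  }
  .fixtures$res
}
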