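#' Head calibration: eyes, beak tip and marker template in the cluster frame
#'
#' Bundles the per-bird keypoints measured once per individual: the two eye
#' centers, the beak tip and the rigid template of head markers, all expressed
#' in the same (arbitrary) head-marker-cluster coordinate frame, in meters.
#' The head-local frame derived from these keypoints has its origin at the
#' head centroid (midpoint of the eyes), X pointing to the bird's right
#' (left eye to right eye), Y forward and Z up, with the local horizon set
#' `horizon_offset_deg` above the principal axis of the beak (default 30
#' degrees, the typical standing posture).
#'
#' @param eye_left,eye_right,beak_tip Length-3 numeric vectors (m).
#' @param marker_template Numeric matrix, one marker per row, 3 columns (m).
#' @return An object of class `head_calibration`.
#' @seealso [build_local_axes()], [fit_head_pose()]
#' @export
head_calibration <- function(eye_left, eye_right, beak_tip, marker_template) {
  stopifnot(length(eye_left) == 3, length(eye_right) == 3, length(beak_tip) == 3)
  marker_template <- as.matrix(marker_template)
  if (ncol(marker_template) != 3 || nrow(marker_template) < 3)
    stop("marker_template must have >= 3 rows and 3 columns")
  if (sqrt(sum((eye_right - eye_left)^2)) < 1e-9)
    stop("degenerate calibration: eyes coincide")
  axes <- build_local_axes(eye_left, eye_right, beak_tip) # errors if collinear
  centered <- sweep(marker_template, 2, colMeans(marker_template))
  if (svd(centered)$d[2] < 1e-9)
    stop("degenerate calibration: marker template is collinear")
  structure(list(eye_left = as.numeric(eye_left),
                 eye_right = as.numeric(eye_right),
                 beak_tip = as.numeric(beak_tip),
                 marker_template = marker_template,
                 axes = axes,
                 origin = (as.numeric(eye_left) + as.numeric(eye_right)) / 2),
            class = "head_calibration")
}

#' @export
print.head_calibration <- function(x, ...) {
  cat("Head calibration:", nrow(x$marker_template), "markers;",
      "inter-eye distance",
      format(sqrt(sum((x$eye_right - x$eye_left)^2)), digits = 3), "m\n")
  invisible(x)
}

#' Build the head-local coordinate axes from eye and beak keypoints
#'
#' X is the unit vector from the left eye to the right eye. Y (forward) is the
#' beak principal axis (head centroid to beak tip, orthogonalized against X)
#' rotated upward about X by `horizon_offset_deg`, so that the beak points
#' `horizon_offset_deg` below the local horizon. Z = X x Y completes a proper
#' right-handed rotation.
#'
#' @inheritParams head_calibration
#' @param horizon_offset_deg Elevation of the local horizon above the beak
#'   principal axis, degrees (default 30).
#' @return 3 x 3 rotation matrix whose columns are the X, Y, Z head axes
#'   expressed in the keypoints' coordinate frame.
#' @export
build_local_axes <- function(eye_left, eye_right, beak_tip,
                             horizon_offset_deg = 30) {
  X <- eye_right - eye_left
  if (sqrt(sum(X^2)) < 1e-12) stop("degenerate geometry: eyes coincide")
  X <- unit(X)
  centroid <- (eye_left + eye_right) / 2
  b <- beak_tip - centroid
  b_perp <- b - sum(b * X) * X
  if (sqrt(sum(b_perp^2)) < 1e-9)
    stop("degenerate geometry: beak tip collinear with the eye-eye axis")
  b_hat <- unit(b_perp)
  a <- horizon_offset_deg * pi / 180
  # rotate the beak axis upward about X (right-hand rule: +Y toward +Z)
  Y <- cos(a) * b_hat + sin(a) * cross3(X, b_hat)
  Z <- cross3(X, Y)
  R <- cbind(X, Y, Z, deparse.level = 0)
  dimnames(R) <- NULL
  R
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rigid head-pose fit from observed markers
#'
#' Least-squares rigid registration (orthogonal Procrustes / Kabsch) of the
#' calibration marker template onto the observed world-frame markers, composed
#' with the calibrated head axes. Markers with any missing coordinate are
#' dropped; fewer than 3 valid markers yields a missing pose rather than an
#' error, so per-frame dropouts propagate as masked frames.
#'
#' @param observed_markers Matrix of observed marker positions (world, m), rows
#'   matching `calib$marker_template`; rows may contain `NA`.
#' @param calib A [head_calibration()].
#' @return A list with `valid` (logical), and when valid: `origin` (head
#'   centroid in world), `rotation` (world <- head proper rotation), `rms`
#'   (root-mean-square marker residual, m).
#' @export
fit_head_pose <- function(observed_markers, calib) {
  obs <- as.matrix(observed_markers)
  ok <- stats::complete.cases(obs)
  if (sum(ok) < 3)
    return(list(valid = FALSE, origin = rep(NA_real_, 3), rotation = NULL,
                rms = NA_real_))
  tmpl <- calib$marker_template[ok, , drop = FALSE]
  obs <- obs[ok, , drop = FALSE]
  ct <- colMeans(tmpl); co <- colMeans(obs)
  A <- sweep(tmpl, 2, ct)
  B <- sweep(obs, 2, co)
  s <- svd(crossprod(A, B)) # t(A) %*% B
  d <- sign(det(s$v %*% t(s$u)))
  R_fit <- s$v %*% diag(c(1, 1, d)) %*% t(s$u) # world <- template frame
  fitted <- A %*% t(R_fit)
  rms <- sqrt(mean(rowSums((fitted - B)^2)))
  origin <- as.numeric(co + R_fit %*% (calib$origin - ct))
  list(valid = TRUE, origin = origin,
       rotation = R_fit %*% calib$axes, rms = rms)
}

#' Project a world point into egocentric (azimuth, elevation) angles
#'
#' Azimuth is the signed angle of the target direction projected onto the
#' head's local XY plane, measured from the forward (+Y) axis, positive toward
#' the bird's right (+X); range (-180, 180]. Elevation is the angle above the
#' local horizon (XY plane); range \[-90, 90\].
#'
#' @param p Length-3 world point (m).
#' @param origin Head origin in world (m).
#' @param rotation World <- head rotation matrix.
#' @return Named numeric vector `c(azimuth, elevation)` in degrees.
#' @export
world_to_head <- function(p, origin, rotation) {
  d <- as.numeric(p) - as.numeric(origin)
  if (sqrt(sum(d^2)) < 1e-12) stop("target coincides with the head origin")
  v <- as.numeric(crossprod(rotation, d))
  c(azimuth = atan2(v[1], v[2]) * 180 / pi,
    elevation = atan2(v[3], sqrt(v[1]^2 + v[2]^2)) * 180 / pi)
}

#' Unit world direction for egocentric angles
#'
#' Inverse of [world_to_head()] up to distance: returns the unit vector, in
#' world coordinates, pointing from the head origin toward the given azimuth
#' and elevation.
#'
#' @param azimuth,elevation Degrees.
#' @param rotation World <- head rotation matrix.
#' @return Length-3 unit vector.
#' @export
head_to_world <- function(azimuth, elevation, rotation) {
  az <- azimuth * pi / 180; el <- elevation * pi / 180
  v <- c(cos(el) * sin(az), cos(el) * cos(az), sin(el))
  as.numeric(rotation %*% v)
}

#' Angular offset from the foveal axis
#'
#' Great-circle angular distance between an egocentric direction and the
#' foveal axis of the given eye (azimuth +75 degrees for the right eye, -75
#' for the left; elevation 0). Intended for diagnostics; the foveation test
#' itself ([is_foveated()]) uses a rectangular region in angle space.
#'
#' @param azimuth,elevation Egocentric angles, degrees (vectorized).
#' @param side `"left"` or `"right"`.
#' @param fovea_azimuth Magnitude of the foveal azimuth, degrees (default 75).
#' @return Great-circle distance in degrees, `[0, 180]`.
#' @export
offset_from_fovea <- function(azimuth, elevation, side = c("right", "left"),
                              fovea_azimuth = 75) {
  side <- match.arg(side)
  az_f <- if (side == "right") fovea_azimuth else -fovea_azimuth
  cosd <- cos(elevation * pi / 180) * cos((azimuth - az_f) * pi / 180)
  acos(pmin(1, pmax(-1, cosd))) * 180 / pi
}

#' Rectangular foveal-region test
#'
#' TRUE iff the direction lies within `margin_deg` of the foveal axis in both
#' azimuth and elevation (a rectangle in angle space, the convention used for
#' visual-field heatmap foveal regions: 75 +/- 10 degrees azimuth, 0 +/- 10
#' elevation by default). Boundaries are inclusive.
#'
#' @inheritParams offset_from_fovea
#' @param margin_deg Half-width of the region, degrees (default 10).
#' @param either If TRUE ignore `side` and accept either eye's region.
#' @return Logical vector.
#' @export
is_foveated <- function(azimuth, elevation, side = c("right", "left"),
                        margin_deg = 10, fovea_azimuth = 75, either = FALSE) {
  stopifnot(margin_deg > 0)
  if (either)
    return(is_foveated(azimuth, elevation, "right", margin_deg, fovea_azimuth) |
           is_foveated(azimuth, elevation, "left", margin_deg, fovea_azimuth))
  side <- match.arg(side)
  az_f <- if (side == "right") fovea_azimuth else -fovea_azimuth
  abs(azimuth - az_f) <= margin_deg & abs(elevation) <= margin_deg
}

#' Scene object (sphere) in world coordinates
#'
#' Objects of interest (monitors, predator hiding tables, conspecifics, the
#' feeding area) are modelled as spheres; the foveation test projects the
#' sphere center into the visual field.
#'
#' @param id Label.
#' @param kind One of `"monitor"`, `"hiding_table"`, `"conspecific"`,
#'   `"feeding_area"`.
#' @param center Length-3 world point (m).
#' @param radius Sphere radius (m), > 0.
#' @return An object of class `scene_object`.
#' @export
scene_object <- function(id, kind = c("monitor", "hiding_table", "conspecific",
                                      "feeding_area"),
                         center, radius) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3, radius > 0)
  structure(list(id = id, kind = kind, center = as.numeric(center),
                 radius = radius), class = "scene_object")
}
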