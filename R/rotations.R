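#' Elementary rotation matrices
#'
#' Construct proper rotation matrices about the coordinate axes. Angles are in
#' degrees; rotations follow the right-hand rule in a right-handed frame
#' (X right, Y forward, Z up).
#'
#' @param deg Rotation angle in degrees.
#' @return A 3 x 3 rotation matrix.
#' @name rotations
NULL

#' @rdname rotations
#' @export
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotations
#' @export
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotations
#' @export
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis (Rodrigues formula)
#'
#' @param axis Length-3 axis vector (need not be unit length).
#' @param deg Rotation angle in degrees, right-hand rule about `axis`.
#' @return A 3 x 3 rotation matrix.
#' @export
rot_axis <- function(axis, deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis has zero length")
  k <- axis / n
  a <- deg * pi / 180
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Geodesic angle between two rotations
#'
#' The rotation angle (degrees) of the relative rotation `t(R1) %*% R2`,
#' i.e. the length of the shortest path in SO(3) between the two orientations.
#'
#' @param R1,R2 3 x 3 rotation matrices.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
geodesic_angle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  # clamp for numerical safety
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# axis-angle (degrees) of a rotation matrix; axis is unit length, angle >= 0
rotmat_to_axisangle <- function(R) {
  tr <- sum(diag(R))
  ang <- acos(min(1, max(-1, (tr - 1) / 2)))
  if (ang < 1e-12) return(list(axis = c(1, 0, 0), angle = 0))
  if (pi - ang < 1e-6) {
    # near 180 degrees: extract axis from R + I
    M <- (R + diag(3)) / 2
    ax <- sqrt(pmax(diag(M), 0))
    i <- which.max(ax)
    if (ax[i] > 0) {
      ax <- M[, i] / ax[i]
      ax <- ax / sqrt(sum(ax^2))
    } else ax <- c(1, 0, 0)
    return(list(axis = ax, angle = ang * 180 / pi))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  list(axis = ax, angle = ang * 180 / pi)
}

# spherical linear interpolation between rotation matrices, f in [0, 1]
slerp_rotmat <- function(R1, R2, f) {
  rel <- rotmat_to_axisangle(crossprod(R1, R2))
  R1 %*% rot_axis(rel$axis, f * rel$angle)
}

# project an arbitrary 3x3 matrix onto SO(3) (nearest proper rotation)
project_so3 <- function(M) {
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}
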