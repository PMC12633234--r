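#' Rotations on SO(3) as unit quaternions
#'
#' A `cryosim_rotation` stores a unit quaternion in scalar-first order
#' `(w, x, y, z)`. Quaternions `q` and `-q` describe the same physical
#' rotation and are treated as equal everywhere in the package. Rotations act
#' *actively*: they rotate body-frame vectors into the lab frame.
#'
#' @param w,x,y,z Quaternion components (scalar first). The quaternion is
#'   normalized on construction; the zero quaternion is rejected.
#' @return A `cryosim_rotation` object (numeric length-4 vector with class).
#' @examples
#' r <- rotation_from_euler(90, 0, 0)
#' apply_rotation(r, c(1, 0, 0))  # ~ (0, 1, 0)
#' @export
rotation <- function(w, x, y, z) {
  q <- c(w, x, y, z)
  if (length(q) != 4 || !all(is.finite(q)))
    stopf("a rotation needs 4 finite quaternion components")
  n <- sqrt(sum(q^2))
  if (n < 1e-12) stopf("zero quaternion does not define a rotation")
  structure(q / n, class = "cryosim_rotation", names = c("w", "x", "y", "z"))
}

#' @export
print.cryosim_rotation <- function(x, ...) {
  cat(sprintf("<rotation> q = (%.6f, %.6f, %.6f, %.6f)\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

#' Identity rotation
#' @return The identity `cryosim_rotation`.
#' @export
rotation_identity <- function() rotation(1, 0, 0, 0)

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation about a coordinate axis
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @param angle_deg Rotation angle in degrees (right-handed).
#' @return A `cryosim_rotation`.
#' @export
rotation_about_axis <- function(axis = c("x", "y", "z"), angle_deg) {
  axis <- match.arg(axis)
  if (!is.finite(angle_deg)) stopf("angle must be finite")
  h <- angle_deg * pi / 360  # half-angle in radians
  u <- switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  rotation(cos(h), sin(h) * u[1], sin(h) * u[2], sin(h) * u[3])
}

#' Rotation from z-y-z Euler angles
#'
#' Builds the active rotation `Rz(psi) Ry(theta) Rz(phi)`: the first Euler
#' rotation `phi` is about the z-axis, then `theta` about the y-axis, and
#' finally `psi` about the z-axis, applied in that order to body-frame
#' coordinates. This is the standard single-particle cryo-EM convention.
#'
#' @param phi,theta,psi Euler angles in degrees.
#' @return A `cryosim_rotation`.
#' @export
rotation_from_euler <- function(phi, theta, psi) {
  if (!all(is.finite(c(phi, theta, psi)))) stopf("Euler angles must be finite")
  q <- quat_multiply(unclass(rotation_about_axis("z", psi)),
                     quat_multiply(unclass(rotation_about_axis("y", theta)),
                                   unclass(rotation_about_axis("z", phi))))
  rotation(q[1], q[2], q[3], q[4])
}

#' Apply a rotation to 3-vectors
#'
#' Rotates vectors by the quaternion sandwich product `q v q*`. Norms and
#' pairwise distances are preserved.
#'
#' @param r A `cryosim_rotation`.
#' @param v A length-3 vector or an N x 3 matrix of row vectors (Angstrom or
#'   any consistent unit).
#' @return Rotated vector(s), same shape as `v`.
#' @export
apply_rotation <- function(r, v) {
  R <- rotation_to_matrix(r)
  if (is.matrix(v)) {
    if (ncol(v) != 3) stopf("expected an N x 3 matrix of vectors")
    v %*% t(R)
  } else {
    if (length(v) != 3) stopf("expected a 3-vector")
    drop(R %*% v)
  }
}

#' Invert a rotation
#' @param r A `cryosim_rotation`.
#' @return The conjugate quaternion, i.e. the inverse rotation.
#' @export
invert_rotation <- function(r) {
  stopifnot(inherits(r, "cryosim_rotation"))
  rotation(r[1], -r[2], -r[3], -r[4])
}

#' Compose two rotations
#'
#' `compose_rotations(a, b)` applies `b` first, then `a`:
#' `apply_rotation(compose_rotations(a, b), v)` equals
#' `apply_rotation(a, apply_rotation(b, v))`.
#'
#' @param a,b `cryosim_rotation` objects.
#' @return A `cryosim_rotation`.
#' @export
compose_rotations <- function(a, b) {
  q <- quat_multiply(unclass(a), unclass(b))
  rotation(q[1], q[2], q[3], q[4])
}

#' Convert a rotation to its 3 x 3 matrix
#' @param r A `cryosim_rotation`.
#' @return A 3 x 3 orthonormal matrix acting on column vectors.
#' @export
rotation_to_matrix <- function(r) {
  stopifnot(inherits(r, "cryosim_rotation"))
  w <- r[1]; x <- r[2]; y <- r[3]; z <- r[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a 3 x 3 rotation matrix to a quaternion
#' @param R A 3 x 3 orthonormal matrix with determinant +1.
#' @return A `cryosim_rotation`.
#' @export
rotation_from_matrix <- function(R) {
  if (!is.matrix(R) || any(dim(R) != 3)) stopf("expected a 3 x 3 matrix")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  # Shepperd's method: pick the largest diagonal pivot for stability.
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  rotation(q[1], q[2], q[3], q[4])
}

#' Recover z-y-z Euler angles from a rotation
#'
#' Inverse of [rotation_from_euler()]. At gimbal lock (`theta` equal to 0 or
#' 180 degrees, where `phi` and `psi` are not separately identifiable) the
#' canonical solution with `psi = 0` is returned.
#'
#' @param r A `cryosim_rotation`.
#' @return Named numeric vector `(phi, theta, psi)` in degrees, with
#'   `theta` in `[0, 180]` and `phi`, `psi` in `[0, 360)`.
#' @export
euler_from_rotation <- function(r) {
  R <- rotation_to_matrix(r)
  # R = Rz(psi) Ry(theta) Rz(phi):
  #   R[3,3] = cos(theta); R[1,3] = sin(theta) cos(psi); R[2,3] = sin(theta) sin(psi)
  #   R[3,1] = -sin(theta) cos(phi); R[3,2] = sin(theta) sin(phi)
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct)
  if (sin(theta) > 1e-9) {
    psi <- atan2(R[2, 3], R[1, 3])
    phi <- atan2(R[3, 2], -R[3, 1])
  } else {
    # theta = 0 (or 180): only the sum (resp. difference) of phi and psi is
    # identifiable; with psi = 0 both cases give phi = atan2(R[2,1], R[2,2]).
    psi <- 0
    phi <- atan2(R[2, 1], R[2, 2])
  }
  deg <- c(phi, theta, psi) * 180 / pi
  deg[c(1, 3)] <- deg[c(1, 3)] %% 360
  names(deg) <- c("phi", "theta", "psi")
  deg
}

#' Test whether two rotations are the same physical rotation
#'
#' Treats `q` and `-q` as equal (quaternion double cover).
#'
#' @param a,b `cryosim_rotation` objects.
#' @param tol Per-component tolerance.
#' @return Logical scalar.
#' @export
rotations_equal <- function(a, b, tol = 1e-9) {
  qa <- unclass(a); qb <- unclass(b)
  max(abs(qa - qb)) < tol || max(abs(qa + qb)) < tol
}

#' Draw a uniformly random rotation
#'
#' Samples a unit quaternion uniformly on the 3-sphere (Haar measure on SO(3)).
#'
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A `cryosim_rotation`.
#' @export
random_rotation <- function(seed = NULL) {
  q <- with_seed(seed, stats::rnorm(4))
  rotation(q[1], q[2], q[3], q[4])
}
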