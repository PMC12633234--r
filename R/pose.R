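#' Particle poses: rotation plus in-plane translation
#'
#' A pose carries the rigid-body orientation `R` of the particle and an
#' in-plane translation `t = (tx, ty, 0)` in Angstrom, the two quantities the
#' linear contrast model needs besides the volume and the CTF. Two
#' parametrizations are provided; both convert to the same unit-quaternion
#' [rotation()] internally, so they are interchangeable everywhere a pose is
#' accepted.
#'
#' @param phi,theta,psi z-y-z Euler angles in degrees (see
#'   [rotation_from_euler()] for the convention).
#' @param tx,ty In-plane translation in Angstrom.
#' @return A `cryosim_pose` object.
#' @examples
#' p1 <- euler_pose(10, 20, 30)
#' p2 <- quaternion_pose(pose_rotation(p1), tx = 0, ty = 0)
#' rotations_equal(pose_rotation(p1), pose_rotation(p2))
#' @export
euler_pose <- function(phi = 0, theta = 0, psi = 0, tx = 0, ty = 0) {
  if (!all(is.finite(c(phi, theta, psi, tx, ty))))
    stopf("pose parameters must be finite")
  structure(list(rotation = rotation_from_euler(phi, theta, psi),
                 angles = c(phi = phi, theta = theta, psi = psi),
                 tx = tx, ty = ty, parametrization = "euler"),
            class = "cryosim_pose")
}

#' @rdname euler_pose
#' @param q A `cryosim_rotation` or a length-4 scalar-first quaternion
#'   `(w, x, y, z)`; normalized on entry.
#' @export
quaternion_pose <- function(q, tx = 0, ty = 0) {
  if (!inherits(q, "cryosim_rotation")) {
    if (length(q) != 4) stopf("q must be a rotation or 4 quaternion components")
    q <- rotation(q[1], q[2], q[3], q[4])
  }
  if (!all(is.finite(c(tx, ty)))) stopf("pose parameters must be finite")
  structure(list(rotation = q, angles = NULL, tx = tx, ty = ty,
                 parametrization = "quaternion"),
            class = "cryosim_pose")
}

#' @rdname euler_pose
#' @param pose A `cryosim_pose`.
#' @export
pose_rotation <- function(pose) {
  stopifnot(inherits(pose, "cryosim_pose"))
  pose$rotation
}

#' @export
print.cryosim_pose <- function(x, ...) {
  cat(sprintf("<pose, %s> t = (%.2f, %.2f) A\n", x$parametrization, x$tx, x$ty))
  print(x$rotation)
  invisible(x)
}

as_pose <- function(pose) {
  if (inherits(pose, "cryosim_pose")) return(pose)
  if (inherits(pose, "cryosim_rotation")) return(quaternion_pose(pose))
  stopf("expected a cryosim_pose or cryosim_rotation")
}
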