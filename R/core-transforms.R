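#' Rigid-body transforms and Euler-angle algebra
#'
#' A \code{rigid_transform} couples a proper 3x3 rotation matrix with a
#' translation vector in Angstrom.  The Euler convention used throughout the
#' package is intrinsic ZXZ in degrees, right-handed: the matrix is
#' \code{Rz(phi) \%*\% Rx(theta) \%*\% Rz(psi)}, the standard convention of the
#' subtomogram-averaging ecosystem.  Rotations of volumes are taken about the
#' center voxel \code{floor(n/2)} (0-based).
#'
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric, Angstrom.
#' @return An object of class \code{rigid_transform} with elements
#'   \code{rotation} and \code{translation}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation matrix determinant is ", format(det(rotation)),
         ", not +1: not a proper rotation")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal within 1e-9")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  eul <- matrix_to_euler(x$rotation)
  cat(sprintf("rigid_transform: ZXZ Euler (%.3f, %.3f, %.3f) deg, t = (%.3f, %.3f, %.3f) A\n",
              eul[1], eul[2], eul[3],
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Convert intrinsic ZXZ Euler angles (degrees) to a rotation matrix
#'
#' @param phi,theta,psi rotations (degrees) about z, then the new x, then the
#'   new z.  A single length-3 vector may be given as \code{phi}.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(phi, theta = NULL, psi = NULL) {
  if (is.null(theta)) {
    psi <- phi[3]; theta <- phi[2]; phi <- phi[1]
  }
  rot_z(phi) %*% rot_x(theta) %*% rot_z(psi)
}

#' Recover ZXZ Euler angles (degrees) from a rotation matrix
#'
#' At the gimbal-locked poles (theta = 0 or 180) psi is set to 0 and the full
#' in-plane angle reported as phi.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length 3: \code{c(phi, theta, psi)} in degrees.
#' @export
matrix_to_euler <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  theta <- acos(ct) * 180 / pi
  if (abs(ct) > 1 - 1e-12) {
    # gimbal lock: only phi +/- psi observable; report it all as phi
    phi <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    return(c(phi, theta, 0))
  }
  phi <- atan2(R[1, 3], -R[2, 3]) * 180 / pi
  psi <- atan2(R[3, 1], R[3, 2]) * 180 / pi
  c(phi, theta, psi)
}

#' Compose two rigid transforms (apply b, then a)
#'
#' @param a,b \code{rigid_transform} objects.
#' @return \code{rigid_transform} equal to \code{a(b(x))}.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param t \code{rigid_transform}.
#' @return the inverse \code{rigid_transform}.
#' @export
invert_transform <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% t$translation))
}

#' Apply a rigid transform to 3D points
#'
#' @param t \code{rigid_transform}.
#' @param x n x 3 matrix (or length-3 vector) of coordinates in Angstrom.
#' @return transformed coordinates, same shape as \code{x}.
#' @export
apply_transform <- function(t, x) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  y <- x %*% t(t$rotation) +
    matrix(t$translation, nrow(x), 3, byrow = TRUE)
  if (vec) as.numeric(y) else y
}

#' Angular distance between two rotations
#'
#' @param Ra,Rb rotation matrices.
#' @return geodesic angle in degrees.
#' @export
rotation_distance <- function(Ra, Rb) {
  tr <- sum(diag(crossprod(Ra, Rb)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Rotation about an arbitrary axis
#'
#' @param axis length-3 direction (normalized internally).
#' @param deg rotation angle in degrees.
#' @return 3x3 rotation matrix (Rodrigues formula).
#' @export
axis_angle_matrix <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
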