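# Rigid (and magnified) transforms. Rotations are parameterized by an
# axis-angle 3-vector (radians times unit axis) and converted with the
# Rodrigues formula; the magnified variant adds a scalar magnification.

#' Construct a rigid transform
#'
#' @param rotation axis-angle 3-vector in radians (direction = axis, norm =
#'   angle), or a 3x3 proper rotation matrix.
#' @param translation translation in Angstrom (length 3).
#' @param magnification scalar relative magnification (1 = none).
#' @return object of class \code{rigid_transform} with the rotation matrix
#'   \code{R}, \code{translation}, \code{magnification} and the axis-angle
#'   vector \code{axis_angle}.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            magnification = 1) {
  if (is.matrix(rotation)) {
    R <- rotation
    aa <- matrix_to_axis_angle(R)
  } else {
    aa <- as.numeric(rotation)
    R <- axis_angle_to_matrix(aa)
  }
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9) {
    stop("rigid_transform: rotation is not a proper rotation matrix")
  }
  if (magnification <= 0) stop("rigid_transform: magnification must be > 0")
  structure(
    list(R = R, translation = as.numeric(translation),
      magnification = magnification, axis_angle = aa),
    class = "rigid_transform"
  )
}

#' Rodrigues rotation matrix from an axis-angle vector
#' @param aa axis-angle 3-vector (radians).
#' @return 3x3 rotation matrix.
#' @export
axis_angle_to_matrix <- function(aa) {
  th <- sqrt(sum(aa^2))
  if (th < 1e-12) return(diag(3))
  k <- aa / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Axis-angle vector from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return axis-angle 3-vector (radians).
#' @export
matrix_to_axis_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(max(ct, -1), 1)
  th <- acos(ct)
  if (th < 1e-12) return(c(0, 0, 0))
  if (abs(pi - th) < 1e-6) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- B[, i] / axis[i]
      axis <- axis / sqrt(sum(axis^2))
    }
    return(th * axis)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(th))
  th * axis
}

#' Rotation angle of a transform in degrees
#' @param t a \code{rigid_transform}.
#' @return angle in degrees.
#' @export
rotation_angle_deg <- function(t) {
  sqrt(sum(t$axis_angle^2)) * 180 / pi
}

#' Apply a transform to atomic coordinates
#'
#' Positions map as \code{x -> mag * R (x - c) + c + t} with \code{c} the
#' rotation centre used by the map fit (normally the grid centre in
#' Angstrom).
#'
#' @param atoms data.frame from [read_atoms()].
#' @param t a \code{rigid_transform}.
#' @param center rotation centre in Angstrom.
#' @return the atoms with transformed x, y, z.
#' @export
apply_transform_to_atoms <- function(atoms, t, center = c(0, 0, 0)) {
  pos <- cbind(atoms$x, atoms$y, atoms$z)
  pos <- sweep(pos, 2, center, "-")
  pos <- t$magnification * (pos %*% t(t$R))
  pos <- sweep(pos, 2, center + t$translation, "+")
  atoms$x <- pos[, 1]; atoms$y <- pos[, 2]; atoms$z <- pos[, 3]
  atoms
}

#' Invert a rigid transform
#' @param t a \code{rigid_transform}.
#' @return the inverse transform (same rotation centre convention).
#' @export
invert_transform <- function(t) {
  Rinv <- t(t$R)
  rigid_transform(Rinv, -(Rinv %*% t$translation) / t$magnification,
    1 / t$magnification)
}

# grid centre in voxel units (rotation centre for all map operations)
grid_center_vox <- function(shape) floor(shape / 2)

# left Jacobian of SO(3) at rotation vector aa:
# d/dt exp([aa(t)]x) = [J_l(aa) aa'(t)]x exp([aa]x)
so3_left_jacobian <- function(aa) {
  th <- sqrt(sum(aa^2))
  K <- matrix(c(0, aa[3], -aa[2], -aa[3], 0, aa[1], aa[2], -aa[1], 0), 3, 3)
  if (th < 1e-8) return(diag(3) + K / 2)
  diag(3) + ((1 - cos(th)) / th^2) * K + ((th - sin(th)) / th^3) * (K %*% K)
}
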