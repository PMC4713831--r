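# Rotation helpers: Tait-Bryan angles, axis-angle conversion.
#
# Convention (fixed throughout the package): intrinsic yaw-pitch-roll,
# R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll), applied to head-frame coordinates.
# In the head frame the body extends along +x from the snout (x increases
# caudally), +z is dorsal and +y is the fish's left; yaw and pitch are the
# azimuth/elevation of the snout-to-tail axis in the world frame, with
# positive pitch dipping the tail below the snout.

#' Rotation matrix from Tait-Bryan angles
#'
#' @param roll,pitch,yaw angles in radians; composition is intrinsic
#'   yaw (about z), then pitch (about the new y), then roll (about the new x).
#' @return 3x3 rotation matrix.
#' @export
taitBryanMatrix <- function(roll, pitch, yaw) {
  cr <- cos(roll); sr <- sin(roll)
  cp <- cos(pitch); sp <- sin(pitch)
  cy <- cos(yaw); sy <- sin(yaw)
  Rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cp, 0, -sp, 0, 1, 0, sp, 0, cp), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cr, sr, 0, -sr, cr), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Axis-angle (rotation vector) from a rotation matrix
#'
#' Returns the rotation vector (unit axis times angle, radians). Used for the
#' head-orientation error metric: the distance between the tips of two
#' rotation vectors.
#' @param R 3x3 rotation matrix.
#' @export
rotationVector <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-12) return(c(0, 0, 0))
  if (abs(pi - ang) < 1e-6) {
    # near pi: extract axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    if (axis[1] > 0) {
      axis[2] <- sign(B[1, 2] + 1e-300) * abs(axis[2])
      axis[3] <- sign(B[1, 3] + 1e-300) * abs(axis[3])
    } else if (axis[2] > 0) {
      axis[3] <- sign(B[2, 3] + 1e-300) * abs(axis[3])
    }
    return(ang * axis / sqrt(sum(axis^2)))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  ang * v / (2 * sin(ang))
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @param w rotation vector (axis * angle, radians).
#' @keywords internal
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
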