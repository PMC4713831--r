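# Inverse dynamics of a deforming body from a matched triangulated surface
# sequence: exact polyhedral mass properties, angular momentum of the
# piecewise-linear velocity field, resultant force and torque.
#
# All volume integrals are reduced to sums over signed tetrahedra (one per
# surface triangle, apex at a reference point), which is exact for
# polynomial integrands: volume and first/second moments are polynomial,
# and the velocity field is interpolated linearly within each tetrahedron,
# so the angular-momentum integrand is quadratic and integrates in closed
# form. For a rigid body the velocity field is itself linear in position,
# making the rigid-body limit L = I w exact up to the surface tessellation.
#
# Geometry is in mm; rho in kg/m^3. Reported mass is kg, force N, angular
# momentum kg m^2/s, torque N m (conversion factors 1e-9 for mm^3 -> m^3
# and 1e-15 for mm^5 -> m^5).

#' Mass properties of a closed triangulated surface
#'
#' Exact divergence-theorem evaluation of volume, centre of mass and the
#' inertia tensor of a watertight, consistently oriented mesh with uniform
#' density.
#'
#' @param mesh a \code{\linkS4class{SurfaceMesh}} (vertices in mm), or a
#'   vertex matrix with \code{tri} supplied.
#' @param rho density in kg/m^3 (water, 1000, by default).
#' @param tri triangle index matrix when \code{mesh} is a vertex matrix.
#' @return list: volume (mm^3), mass (kg), com (mm), inertia (3x3, kg m^2,
#'   about the CoM).
#' @export
massProperties <- function(mesh, rho = 1000, tri = NULL) {
  if (is(mesh, "SurfaceMesh")) {
    V <- mesh@vertices; tri <- mesh@triangles
    if (!isWatertight(mesh)) stop("mesh is not watertight")
  } else V <- mesh
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  cc <- V[tri[, 3], , drop = FALSE]
  vt <- (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
         a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
         a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  vol <- sum(vt)
  if (abs(vol) < 1e-12) stop("mesh has (near) zero volume")
  com <- unname(colSums(vt * (a + b + cc))) / (4 * vol)
  # second moment matrix S = integral x x^T dV per signed tetrahedron
  S <- matrix(0, 3, 3)
  s <- a + b + cc
  for (i in 1:3) for (j in i:3) {
    S[i, j] <- S[j, i] <- sum(vt / 20 *
      (a[, i] * a[, j] + b[, i] * b[, j] + cc[, i] * cc[, j] +
       s[, i] * s[, j]))
  }
  Sc <- S - vol * tcrossprod(com)          # shift to CoM
  Imat <- (sum(diag(Sc)) * diag(3) - Sc) * rho * 1e-15
  list(volume = vol, mass = rho * vol * 1e-9, com = com, inertia = Imat)
}

#' Angular momentum of a deforming body about its CoM
#'
#' Evaluates L = rho * integral over the body of r* x v* dV, with r* and
#' v* relative to the CoM frame, by exact integration of the linearly
#' interpolated vertex velocity field over signed tetrahedra (apex at the
#' CoM, where the relative position and velocity vanish).
#'
#' @param V vertex matrix (mm) at one frame.
#' @param vel matched per-vertex velocity matrix (mm/s).
#' @param tri triangle index matrix.
#' @param rho density (kg/m^3).
#' @param com CoM position (mm); \code{vcom} CoM velocity (mm/s).
#' @return angular momentum vector, kg m^2/s.
#' @export
angularMomentum <- function(V, vel, tri, rho, com, vcom) {
  if (nrow(V) != nrow(vel)) stop("mesh/velocity topology mismatch")
  r1 <- sweep(V[tri[, 1], , drop = FALSE], 2, com)
  r2 <- sweep(V[tri[, 2], , drop = FALSE], 2, com)
  r3 <- sweep(V[tri[, 3], , drop = FALSE], 2, com)
  u1 <- sweep(vel[tri[, 1], , drop = FALSE], 2, vcom)
  u2 <- sweep(vel[tri[, 2], , drop = FALSE], 2, vcom)
  u3 <- sweep(vel[tri[, 3], , drop = FALSE], 2, vcom)
  vt <- (r1[, 1] * (r2[, 2] * r3[, 3] - r2[, 3] * r3[, 2]) -
         r1[, 2] * (r2[, 1] * r3[, 3] - r2[, 3] * r3[, 1]) +
         r1[, 3] * (r2[, 1] * r3[, 2] - r2[, 2] * r3[, 1])) / 6
  crossM <- function(p, q)
    cbind(p[, 2] * q[, 3] - p[, 3] * q[, 2],
          p[, 3] * q[, 1] - p[, 1] * q[, 3],
          p[, 1] * q[, 2] - p[, 2] * q[, 1])
  term <- crossM(r1, u1) + crossM(r2, u2) + crossM(r3, u3) +
    crossM(r1 + r2 + r3, u1 + u2 + u3)
  colSums(vt / 20 * term) * rho * 1e-15
}

#' Resultant force from CoM acceleration
#'
#' Newton's second law F = m a; acceleration given in mm/s^2 is converted
#' to SI internally.
#' @param acom n x 3 CoM acceleration (mm/s^2).
#' @param mass body mass (kg).
#' @return n x 3 force (N).
#' @export
resultantForce <- function(acom, mass) {
  mass * acom * 1e-3
}

#' Resultant torque from the angular-momentum series
#'
#' Second-order finite difference of L(t).
#' @param L n x 3 angular-momentum series (kg m^2/s).
#' @param dt frame interval (s).
#' @return n x 3 torque (N m).
#' @export
resultantTorque <- function(L, dt) {
  differentiate(L, dt, 1L)
}

# per-frame fish coordinate axes from the deformed section geometry:
# x_fish along the local moment-of-inertia-weighted mean body angle in the
# deformation plane (pointing rostrally), z_fish normal to the deformation
# plane, y_fish completing the right-handed frame.
.fishAxes <- function(pre, kappa, angles, position, com) {
  thSec <- drop(pre$Asec %*% kappa)
  thMid <- drop(pre$Amid %*% kappa)
  px <- c(0, cumsum(pre$dsl * cos(thMid)))
  py <- c(0, cumsum(pre$dsl * sin(thMid)))
  M <- pre$M
  # section areas as mass weights (polygon area per ring)
  areas <- vapply(seq_len(M), function(i) {
    if (i == 1L || i == M) return(0)
    p <- which(pre$ringIdx == i)
    y <- pre$Y[p]; z <- pre$Z[p]
    n <- length(y)
    abs(sum(y * z[c(2:n, 1)] - y[c(2:n, 1)] * z)) / 2
  }, numeric(1))
  R <- taitBryanMatrix(angles[1], angles[2], angles[3])
  centres <- cbind(px, py, 0) %*% t(R)
  centres <- sweep(centres, 2, position, "+")
  d2 <- rowSums(sweep(centres, 2, com)^2)
  w <- areas * d2
  if (sum(w) < 1e-12) w <- areas + 1e-12
  phi <- sum(w * thSec) / sum(w)
  xf <- drop(R %*% c(-cos(phi), -sin(phi), 0))   # rostral direction
  zf <- drop(R %*% c(0, 0, 1))
  yf <- c(zf[2] * xf[3] - zf[3] * xf[2],
          zf[3] * xf[1] - zf[1] * xf[3],
          zf[1] * xf[2] - zf[2] * xf[1])
  cbind(x = xf, y = yf, z = zf)
}

#' Inverse dynamics of a matched mesh sequence
#'
#' Core post-processor: takes per-frame vertex positions with fixed
#' topology, computes CoM and mass by polyhedral integrals, differentiates
#' (second-order finite differences) for CoM velocity/acceleration and
#' per-vertex velocities, and evaluates resultant force, angular momentum
#' and resultant torque.
#'
#' @param Varr array n_frames x n_vertices x 3 of vertex positions (mm).
#' @param tri triangle index matrix.
#' @param fps frame rate (1/s).
#' @param rho density (kg/m^3).
#' @return list with time, com, vcom, acom, mass, force, L, torque.
#' @export
meshDynamics <- function(Varr, tri, fps, rho = 1000) {
  n <- dim(Varr)[1]
  dt <- 1 / fps
  com <- matrix(0, n, 3)
  masses <- numeric(n)
  for (i in seq_len(n)) {
    mp <- massProperties(Varr[i, , ], rho = rho, tri = tri)
    com[i, ] <- mp$com
    masses[i] <- mp$mass
  }
  mass <- mean(masses)
  if (diff(range(masses)) > 0.005 * mass)
    warning("mesh volume drifts by more than 0.5% across the sequence")
  vcom <- differentiate(com, dt, 1L)
  acom <- differentiate(com, dt, 2L)
  force <- resultantForce(acom, mass)
  # matched per-vertex velocities, second-order differences in time
  nv <- dim(Varr)[2]
  L <- matrix(0, n, 3)
  vel <- array(0, dim = dim(Varr))
  for (k in 1:3) vel[, , k] <- differentiate(Varr[, , k], dt, 1L)
  for (i in seq_len(n))
    L[i, ] <- angularMomentum(Varr[i, , ], vel[i, , ], tri, rho,
                              com[i, ], vcom[i, ])
  torque <- resultantTorque(L, dt)
  list(time = (seq_len(n) - 1) * dt, com = com, vcom = vcom, acom = acom,
       mass = mass, masses = masses, force = force, L = L, torque = torque)
}

#' Full post-processing of tracked kinematics
#'
#' Smooths the raw tracked parameters with the Whittaker smoother (penalty
#' weight per column by GCV unless given), rebuilds the body surface per
#' frame, and runs the inverse-dynamics chain, including the fish-frame
#' decomposition of force and torque and the "forward" force component
#' along the CoM velocity.
#'
#' @param track a \code{\linkS4class{TrackResult}} (or a state matrix with
#'   \code{time} supplied).
#' @param model the \code{\linkS4class{BodyModel}} used for tracking.
#' @param fps frame rate (1/s).
#' @param lambda smoothing weight: NULL (default) = the cutoff-frequency
#'   rule \code{\link{cutoffLambda}(fps)}; NA = per-column GCV; a number
#'   = fixed weight. Tracking errors are strongly autocorrelated, which
#'   makes GCV undersmooth by orders of magnitude, so the bandwidth-based
#'   default is preferred.
#' @param rho density (kg/m^3).
#' @param trim edge frames flagged at each end (default 5).
#' @param kappaS control-point positions (taken from \code{track} if a
#'   TrackResult).
#' @param time frame times when \code{track} is a plain matrix.
#' @return a \code{\linkS4class{DynamicsSeries}}.
#' @export
computeDynamics <- function(track, model, fps, lambda = NULL, rho = 1000,
                            trim = 5, kappaS = NULL, time = NULL) {
  if (is.null(lambda)) lambda <- cutoffLambda(fps)
  if (is(track, "TrackResult")) {
    states <- track@states
    kappaS <- track@kappaS
    time <- track@time
  } else {
    states <- track
    if (is.null(kappaS))
      kappaS <- seq(model@stiffFraction, 1,
                    length.out = ncol(states) - 6L)
    if (is.null(time)) time <- (seq_len(nrow(states)) - 1) / fps
  }
  sm <- smoothStates(states, lambda)
  states <- sm$states
  n <- nrow(states)
  pre <- makeDeformer(model, kappaS)
  Varr <- array(0, dim = c(n, pre$nv, 3))
  for (i in seq_len(n))
    Varr[i, , ] <- deformVertices(pre, states[i, -(1:6)],
                                  states[i, 4:6], states[i, 1:3])
  dyn <- meshDynamics(Varr, pre$triangles, fps, rho)
  axes <- array(0, dim = c(3, 3, n))
  forceFish <- matrix(0, n, 3)
  torqueFish <- matrix(0, n, 3)
  forward <- numeric(n)
  for (i in seq_len(n)) {
    A <- .fishAxes(pre, states[i, -(1:6)], states[i, 4:6], states[i, 1:3],
                   dyn$com[i, ])
    axes[, , i] <- A
    forceFish[i, ] <- drop(crossprod(A, dyn$force[i, ]))
    torqueFish[i, ] <- drop(crossprod(A, dyn$torque[i, ]))
    nv <- sqrt(sum(dyn$vcom[i, ]^2))
    forward[i] <- if (nv > 1e-9) sum(dyn$force[i, ] * dyn$vcom[i, ]) / nv
                  else NA_real_
  }
  new("DynamicsSeries", time = time, states = states, com = dyn$com,
      vcom = dyn$vcom, acom = dyn$acom, mass = dyn$mass, force = dyn$force,
      forceFish = forceFish, forward = forward, L = dyn$L,
      torque = dyn$torque, torqueFish = torqueFish, axes = axes,
      lambda = sm$lambda, trim = trim)
}
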