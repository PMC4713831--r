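# Kinematics: curvature -> centreline -> section placement -> rigid motion.
#
# Deformation happens in the head frame (snout at the origin, x increasing
# caudally along the undeformed body, z dorsal), as pure planar bending in
# the head-frame x-y plane: the local tangent angle is the analytic integral
# of the curvature spline, sections stay planar and perpendicular to the
# deformed centreline, and arclength is conserved by construction (each
# centreline segment keeps its undeformed length and is rotated by the
# tangent angle at its midpoint).  The posed mesh is the head-frame surface
# rotated by R(roll, pitch, yaw) and translated to the snout position.

#' Interpolate curvature control points to arbitrary stations
#'
#' Natural cubic spline through the (kappaS, kappa) control pairs, with
#' values over the stiff head fraction forced to zero.
#'
#' @param state a \code{\linkS4class{FishState}}.
#' @param sGrid sorted arclength stations in [0, 1].
#' @param stiffFraction anterior fraction with zero curvature.
#' @return curvature (1/mm) at the stations.
#' @export
interpolateCurvature <- function(state, sGrid, stiffFraction = 0.1) {
  sp <- naturalSpline(state@kappaS, state@kappa)
  k <- evalSpline(sp, sGrid)
  k[sGrid < stiffFraction] <- 0
  k
}

#' Integrate the curvature spline into the deformed centreline
#'
#' The curvature spline is a third-order piecewise polynomial; its exact
#' per-piece antiderivative gives the local tangent angle
#' theta(s) = ell * integral_0^s kappa(u) du. Centreline points follow by
#' marching segments of conserved length rotated by the midpoint tangent
#' angle (planar deformation).
#'
#' @param state a \code{\linkS4class{FishState}}.
#' @param ell body length (mm).
#' @param nSamples number of arclength samples.
#' @param stiffFraction anterior zero-curvature fraction.
#' @return data.frame with s, kappa (1/mm), theta (rad), x, y (mm, head
#'   frame, deformation plane).
#' @export
integrateCenterline <- function(state, ell, nSamples = 200,
                                stiffFraction = 0.1) {
  s <- seq(0, 1, length.out = nSamples)
  sp <- naturalSpline(state@kappaS, state@kappa)
  kap <- evalSpline(sp, s)
  kap[s < stiffFraction] <- 0
  I0 <- integrateSpline(sp, stiffFraction)
  thetaAt <- function(u)
    ifelse(u <= stiffFraction, 0,
           ell * (integrateSpline(sp, u) - I0))
  theta <- thetaAt(s)
  smid <- (s[-1] + s[-nSamples]) / 2
  thmid <- thetaAt(smid)
  ds <- diff(s) * ell
  x <- c(0, cumsum(ds * cos(thmid)))
  y <- c(0, cumsum(ds * sin(thmid)))
  data.frame(s = s, kappa = kap, theta = theta, x = x, y = y)
}

#' Precompute the deformation machinery for a model
#'
#' Curvature interpolation and its analytic integral are linear in the
#' control-point values, so both are precomputed as matrices; the per-call
#' work in \code{\link{deformVertices}} is a handful of small matrix
#' products. Used heavily by the tracker objective.
#'
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param kappaS curvature control-point positions.
#' @return opaque list used by \code{\link{deformVertices}}.
#' @export
makeDeformer <- function(model, kappaS = seq(model@stiffFraction, 1,
                                             length.out = 7)) {
  d <- dim(model@sections)
  P <- d[1]; M <- d[3]
  sSt <- model@sValues
  ell <- model@length
  stiff <- model@stiffFraction
  K <- length(kappaS)

  # theta basis: column k = analytic curvature integral of the unit spline
  unitTheta <- function(sEval) {
    out <- matrix(0, length(sEval), K)
    for (k in seq_len(K)) {
      ek <- numeric(K); ek[k] <- 1
      sp <- naturalSpline(kappaS, ek)
      I0 <- integrateSpline(sp, stiff)
      v <- ell * (integrateSpline(sp, pmax(sEval, stiff)) - I0)
      v[sEval <= stiff] <- 0
      out[, k] <- v
    }
    out
  }
  smid <- (sSt[-1] + sSt[-M]) / 2
  Asec <- unitTheta(sSt)          # tangent angle at stations
  Amid <- unitTheta(smid)         # tangent angle at segment midpoints
  dsl <- diff(sSt) * ell

  # vertex bookkeeping: apex + full rings 2..M-1 + apex
  nv <- 2L + (M - 2L) * P
  ringIdx <- c(1L, rep(2:(M - 1L), each = P), M)
  Y <- c(0, as.vector(model@sections[, 1, 2:(M - 1)]), 0)
  Z <- c(0, as.vector(model@sections[, 2, 2:(M - 1)]), 0)

  idx <- function(i, j) 1L + (i - 2L) * P + ((j - 1L) %% P) + 1L
  tris <- matrix(0L, 2L * P * (M - 2L), 3L)
  r <- 0L
  for (j in 1:P) {
    r <- r + 1L; tris[r, ] <- c(1L, idx(2L, j + 1L), idx(2L, j))
  }
  for (i in 2:(M - 2L)) for (j in 1:P) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    cc <- idx(i + 1L, j + 1L); dd <- idx(i + 1L, j)
    tris[r + 1L, ] <- c(a, b, cc)
    tris[r + 2L, ] <- c(a, cc, dd)
    r <- r + 2L
  }
  for (j in 1:P) {
    r <- r + 1L; tris[r, ] <- c(nv, idx(M - 1L, j), idx(M - 1L, j + 1L))
  }

  pre <- list(P = P, M = M, K = K, ell = ell, stiff = stiff,
              kappaS = kappaS, sStations = sSt, Asec = Asec, Amid = Amid,
              dsl = dsl, ringIdx = ringIdx, Y = Y, Z = Z, nv = nv,
              triangles = tris)
  # fix outward orientation once, on the straight pose
  v0 <- deformVertices(pre, rep(0, K), c(0, 0, 0), c(0, 0, 0))
  if (.meshSignedVolume(v0, tris) < 0)
    pre$triangles <- tris[, c(1L, 3L, 2L)]
  pre
}

# signed volume of a triangulated surface (divergence theorem)
.meshSignedVolume <- function(V, tri) {
  a <- V[tri[, 1], , drop = FALSE]
  b <- V[tri[, 2], , drop = FALSE]
  cc <- V[tri[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Deformed, posed vertex positions (fast path)
#'
#' @param pre deformer from \code{\link{makeDeformer}}.
#' @param kappa curvature control values (1/mm).
#' @param angles Tait-Bryan (roll, pitch, yaw), rad.
#' @param position snout position (mm).
#' @return nv x 3 matrix of world-frame vertices.
#' @export
deformVertices <- function(pre, kappa, angles, position) {
  thSec <- drop(pre$Asec %*% kappa)
  thMid <- drop(pre$Amid %*% kappa)
  px <- c(0, cumsum(pre$dsl * cos(thMid)))
  py <- c(0, cumsum(pre$dsl * sin(thMid)))
  r <- pre$ringIdx
  sn <- sin(thSec)[r]; cs <- cos(thSec)[r]
  Vh <- cbind(px[r] - sn * pre$Y, py[r] + cs * pre$Y, pre$Z)
  R <- taitBryanMatrix(angles[1], angles[2], angles[3])
  V <- Vh %*% t(R)
  V[, 1] <- V[, 1] + position[1]
  V[, 2] <- V[, 2] + position[2]
  V[, 3] <- V[, 3] + position[3]
  V
}

#' Deform and pose a body model
#'
#' Places every cross-section perpendicular to the deformed centreline at
#' its arclength station (pure bending in the head-frame x-y plane), then
#' applies the rigid head rotation and snout translation of the state.
#'
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param state a \code{\linkS4class{FishState}}.
#' @param pre optional precomputed deformer (must match \code{state@kappaS}).
#' @return a \code{\linkS4class{SurfaceMesh}}.
#' @export
deformAndPose <- function(model, state, pre = NULL) {
  if (is.null(pre)) pre <- makeDeformer(model, state@kappaS)
  V <- deformVertices(pre, state@kappa, state@angles, state@position)
  new("SurfaceMesh", vertices = V, triangles = pre$triangles)
}

#' Straight-pose mesh of a body model
#' @param model a \code{\linkS4class{BodyModel}}.
#' @return a \code{\linkS4class{SurfaceMesh}} in the head frame.
#' @export
bodyMesh <- function(model) {
  K <- 7L
  st <- fishState(kappa = numeric(K),
                  stiffFraction = model@stiffFraction)
  deformAndPose(model, st)
}
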