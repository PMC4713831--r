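# Polyhedral mass properties, angular momentum of deforming bodies, and
# the inverse-dynamics chain.

test_that("mass properties of a unit cube match closed forms", {
  V <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  tri <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7, 1, 2, 6, 1, 6, 5,
                  3, 7, 8, 3, 8, 4, 1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6),
                ncol = 3, byrow = TRUE)
  mp <- massProperties(V, 1000, tri)
  expect_equal(mp$volume, 1)
  expect_equal(mp$mass, 1e-6)        # 1 mm^3 of water
  expect_equal(mp$com, c(0.5, 0.5, 0.5), ignore_attr = TRUE)
  expect_equal(diag(mp$inertia), rep(mp$mass / 6 * (1e-3)^2, 3),
               tolerance = 1e-12)
})

test_that("cylinder inertia matches closed forms at fixture tessellation", {
  mesh <- cylinderMesh(1.25, 5, nCirc = 64, nAxial = 21)
  expect_true(isWatertight(mesh))
  mp <- massProperties(mesh)
  expect_equal(mp$volume, pi * 0.625^2 * 5, tolerance = 0.005)
  m <- mp$mass
  r <- 0.625e-3
  L <- 5e-3
  expect_equal(mp$inertia[1, 1], m * r^2 / 2, tolerance = 0.005)
  expect_equal(mp$inertia[2, 2], m * (3 * r^2 + L^2) / 12,
               tolerance = 0.005)
  expect_equal(mp$com, c(0, 0, 0), tolerance = 1e-9)
  expect_error(massProperties(new("SurfaceMesh",
                                  vertices = mesh@vertices,
                                  triangles = mesh@triangles[-1, ])),
               "watertight")
})

test_that("rigid-body angular momentum equals I omega", {
  mesh <- cylinderMesh(1.25, 5)
  mp <- massProperties(mesh)
  V <- mesh@vertices
  for (w in list(c(0, 0, 3), c(4, 0, 0), c(0, -2, 0))) {
    rel <- sweep(V, 2, mp$com)
    vel <- cbind(w[2] * rel[, 3] - w[3] * rel[, 2],
                 w[3] * rel[, 1] - w[1] * rel[, 3],
                 w[1] * rel[, 2] - w[2] * rel[, 1])
    L <- angularMomentum(V, vel, mesh@triangles, 1000, mp$com, c(0, 0, 0))
    expect_equal(L, drop(mp$inertia %*% w), tolerance = 0.005)
  }
  # rigid translation carries no angular momentum about the CoM
  vel <- matrix(rep(c(10, 5, 2), each = nrow(V)), ncol = 3)
  L <- angularMomentum(V, vel, mesh@triangles, 1000, mp$com, c(10, 5, 2))
  expect_lt(max(abs(L)), 1e-9 * max(abs(mp$inertia)))
  expect_error(angularMomentum(V, vel[-1, ], mesh@triangles, 1000,
                               mp$com, c(0, 0, 0)), "mismatch")
})

test_that("deforming-body angular momentum matches a Monte-Carlo oracle", {
  # two-segment bending rod: segment A fixed, segment B rotating about a
  # hinge at the origin with angular velocity w (rigid per segment, so the
  # per-vertex velocity field is exact)
  mkBox <- function(x0, x1, hw) {
    V <- as.matrix(expand.grid(c(x0, x1), c(-hw, hw), c(-hw, hw)))
    tri <- matrix(c(1, 3, 4, 1, 4, 2, 5, 6, 8, 5, 8, 7, 1, 2, 6, 1, 6, 5,
                    3, 7, 8, 3, 8, 4, 1, 5, 7, 1, 7, 3, 2, 4, 8, 2, 8, 6),
                  ncol = 3, byrow = TRUE)
    list(V = V, tri = tri)
  }
  hw <- 0.4
  A <- mkBox(-3, 0, hw)
  B <- mkBox(0, 3, hw)
  w <- c(0, 0, 2.5)            # rad/s about z through the hinge
  velA <- matrix(0, 8, 3)
  velB <- cbind(-w[3] * B$V[, 2], w[3] * B$V[, 1], 0)
  V <- rbind(A$V, B$V)
  tri <- rbind(A$tri, B$tri + 8L)
  vel <- rbind(velA, velB)
  rho <- 1000
  # CoM of the union (two boxes of equal volume)
  com <- c(0, 0, 0)
  vcom <- colSums(vel) / 16 * 0   # not the true vcom; use zero for both
  L <- angularMomentum(V, vel, tri, rho, com, c(0, 0, 0))
  set.seed(42)
  n <- 1e5
  ptsA <- cbind(runif(n, -3, 0), runif(n, -hw, hw), runif(n, -hw, hw))
  ptsB <- cbind(runif(n, 0, 3), runif(n, -hw, hw), runif(n, -hw, hw))
  volEach <- 3 * (2 * hw)^2
  # r x v integrand; A contributes zero velocity
  rxv <- cbind(ptsB[, 2] * 0 - 0, 0 - ptsB[, 1] * 0,
               ptsB[, 1] * (w[3] * ptsB[, 1]) -
                 ptsB[, 2] * (-w[3] * ptsB[, 2]))
  Lmc <- colMeans(rxv) * volEach * rho * 1e-15
  expect_equal(L, Lmc, tolerance = 0.01)
})

test_that("cylinder round trip recovers prescribed forces and torques", {
  pf <- cylinderProfiles()
  sim <- simulateCylinder(pf$forceFun, pf$torqueFun, fps = 2000,
                          nFrames = 100)
  dyn <- meshDynamics(sim$Varr, sim$tri, fps = 2000)
  keep <- 6:95                       # trim 5 edge frames per side
  fErr <- sqrt(rowSums((dyn$force - sim$refForce)^2))[keep]
  tErr <- sqrt(rowSums((dyn$torque - sim$refTorque)^2))[keep]
  fPeak <- max(sqrt(rowSums(sim$refForce^2)))
  tPeak <- max(sqrt(rowSums(sim$refTorque^2)))
  expect_lt(sqrt(mean(fErr^2)) / fPeak, 0.02)
  expect_lt(sqrt(mean(tErr^2)) / tPeak, 0.02)
  # impulse consistency over an interior window: integrated force equals
  # m * delta vcom (trapezoid of central differences telescopes)
  a <- 6; b <- 95
  dt <- 1 / 2000
  imp <- colSums((dyn$force[a:(b - 1), ] + dyn$force[(a + 1):b, ]) / 2) * dt
  dv <- (dyn$vcom[b, ] + dyn$vcom[b - 1, ] - dyn$vcom[a, ] -
           dyn$vcom[a + 1, ]) / 2 * 1e-3 * dyn$mass
  expect_equal(imp, dv, tolerance = 1e-3)
})

test_that("zero profiles give zero force and torque", {
  zero <- function(t) c(0, 0, 0)
  sim <- simulateCylinder(zero, zero, fps = 2000, nFrames = 30,
                          mesh = cylinderMesh(1.25, 5, nCirc = 32,
                                              nAxial = 9))
  dyn <- meshDynamics(sim$Varr, sim$tri, fps = 2000)
  expect_lt(max(abs(dyn$force)), 1e-15)
  expect_lt(max(abs(dyn$torque)), 1e-18)
})

test_that("constant force follows the closed-form trajectory", {
  F0 <- c(2e-6, 0, 0)
  sim <- simulateCylinder(function(t) F0, function(t) c(0, 0, 0),
                          fps = 2000, nFrames = 60)
  dyn <- meshDynamics(sim$Varr, sim$tri, fps = 2000)
  tEnd <- sim$time[60]
  # CoM displacement = 1/2 (F/m) t^2 (in mm)
  expect_equal(dyn$com[60, 1] - dyn$com[1, 1],
               0.5 * F0[1] / sim$mass * tEnd^2 * 1000, tolerance = 1e-3)
  keep <- 6:55
  expect_equal(max(abs(dyn$force[keep, 1] - F0[1])) / F0[1], 0,
               tolerance = 0.005)
})

test_that("mass is constant across a bending sequence", {
  mod <- fixtureModel()
  pre <- makeDeformer(mod)
  kaps <- seq(-pi / 5, pi / 5, length.out = 9)
  vols <- vapply(kaps, function(k)
    fishtrack3d:::.meshSignedVolume(
      deformVertices(pre, rep(k, 7), c(0, 0, 0), c(0, 0, 0)),
      pre$triangles), numeric(1))
  expect_lt(diff(range(vols)) / mean(vols), 0.005)
})

test_that("torque of a rigid spin is zero and linear L is exact", {
  # constant L: zero torque
  L <- matrix(rep(c(1e-10, -2e-10, 3e-10), each = 40), ncol = 3)
  tau <- resultantTorque(L, 5e-4)
  expect_lt(max(abs(tau)), 1e-20)
  # linear-in-time L: exact constant torque everywhere (2nd-order stencil)
  tgrid <- seq_len(40) * 5e-4
  L <- cbind(1e-9 * tgrid, -2e-9 * tgrid, 0.5e-9 * tgrid)
  tau <- resultantTorque(L, 5e-4)
  expect_equal(tau[, 1], rep(1e-9, 40), tolerance = 1e-8)
  expect_equal(tau[, 2], rep(-2e-9, 40), tolerance = 1e-8)
})

test_that("fish frame axes follow the inertia-weighted body angle", {
  mod <- fixtureModel()
  pre <- makeDeformer(mod)
  # straight fish: x_fish along the (rostral) body axis exactly
  A <- fishtrack3d:::.fishAxes(pre, numeric(7), c(0, 0, 0), c(0, 0, 0),
                               c(2.5, 0, 0.02))
  expect_equal(A[, 1], c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(A[, 3], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(crossprod(A), diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # bent state: equals a dense per-section mass-weighted average oracle
  kap <- rep(0.35, 7)
  V <- deformVertices(pre, kap, c(0, 0, 0), c(0, 0, 0))
  com <- massProperties(V, tri = pre$triangles)$com
  A <- fishtrack3d:::.fishAxes(pre, kap, c(0, 0, 0), c(0, 0, 0), com)
  thSec <- drop(pre$Asec %*% kap)
  px <- c(0, cumsum(pre$dsl * cos(drop(pre$Amid %*% kap))))
  py <- c(0, cumsum(pre$dsl * sin(drop(pre$Amid %*% kap))))
  areas <- vapply(seq_len(pre$M), function(i) {
    if (i == 1 || i == pre$M) return(0)
    p <- which(pre$ringIdx == i)
    polyArea(cbind(pre$Y[p], pre$Z[p]))
  }, numeric(1))
  d2 <- (px - com[1])^2 + (py - com[2])^2
  phi <- sum(areas * d2 * thSec) / sum(areas * d2)
  expect_equal(A[, 1], c(-cos(phi), -sin(phi), 0), tolerance = 0.01)
  ang <- acos(sum(A[, 1] * c(-cos(phi), -sin(phi), 0)))
  expect_lt(ang * 180 / pi, 0.5)
})
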