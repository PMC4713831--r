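# Curvature interpolation, analytic centreline integration, deformation
# and rigid posing.

test_that("curvature interpolation matches trivial and oracle cases", {
  st <- fishState(kappa = numeric(7), stiffFraction = 0)
  expect_equal(interpolateCurvature(st, seq(0, 1, 0.01), 0),
               rep(0, 101))
  st <- fishState(kappa = rep(0.4, 7), kappaS = seq(0, 1, length.out = 7))
  expect_equal(interpolateCurvature(st, seq(0, 1, 0.01), 0),
               rep(0.4, 101), tolerance = 1e-12)
  # sampled sine: compare with a 10x-knot dense-spline oracle
  kS <- seq(0, 1, length.out = 7)
  st <- fishState(kappa = sin(2 * pi * kS), kappaS = kS)
  sGrid <- seq(0, 1, length.out = 200)
  got <- interpolateCurvature(st, sGrid, 0)
  kSd <- seq(0, 1, length.out = 70)
  oracle <- spline(kSd, sin(2 * pi * kSd), xout = sGrid, method = "natural")$y
  tol <- max(abs(oracle - sin(2 * pi * sGrid))) * 10 + 1e-6
  expect_lt(max(abs(got - sin(2 * pi * sGrid))), 0.05)
  expect_lt(max(abs(got - oracle)), 0.05)
})

test_that("centreline integration is exact for the spline", {
  ell <- 5
  # zero curvature: straight line of length ell
  st <- fishState(kappa = numeric(7), stiffFraction = 0)
  cl <- integrateCenterline(st, ell, 200, 0)
  expect_equal(cl$x[200], ell, tolerance = 1e-12)
  expect_equal(max(abs(cl$y)), 0)
  # constant curvature c: head-tail angle = c*ell; chord from arc geometry
  cc <- pi / 2 / ell
  st <- fishState(kappa = rep(cc, 7), kappaS = seq(0, 1, length.out = 7))
  cl <- integrateCenterline(st, ell, 400, 0)
  expect_equal(cl$theta[400], cc * ell, tolerance = 1e-10)
  chord <- sqrt(cl$x[400]^2 + cl$y[400]^2)
  expect_equal(chord, ell * 2 * sqrt(2) / pi, tolerance = 1e-4)
  # arbitrary spline: theta(1) agrees with adaptive quadrature to 1e-10
  set.seed(3)
  kS <- seq(0, 1, length.out = 7)
  kap <- rnorm(7, 0, 0.5)
  st <- fishState(kappa = kap, kappaS = kS)
  cl <- integrateCenterline(st, ell, 50, 0)
  sp <- fishtrack3d:::naturalSpline(kS, kap)
  orc <- integrate(function(u) fishtrack3d:::evalSpline(sp, u), 0, 1,
                   rel.tol = 1e-13)$value * ell
  expect_equal(cl$theta[50], orc, tolerance = 1e-10)
})

test_that("arclength is conserved under bending", {
  ell <- 5
  set.seed(11)
  for (rep in 1:10) {
    kap <- runif(7, -2 * pi / ell, 2 * pi / ell)
    st <- fishState(kappa = kap)
    cl <- integrateCenterline(st, ell, 300)
    len <- sum(sqrt(diff(cl$x)^2 + diff(cl$y)^2))
    expect_equal(len, ell, tolerance = 1e-3)
  }
})

test_that("posing applies the rigid motion exactly", {
  mod <- fixtureModel()
  pre <- makeDeformer(mod)
  zero <- fishState(kappa = numeric(7))
  m0 <- deformAndPose(mod, zero, pre)
  # zero state: straight pose at the origin, snout at 0
  expect_equal(min(m0@vertices[, 1]), 0, tolerance = 1e-12)
  expect_equal(max(m0@vertices[, 1]), mod@length, tolerance = 1e-12)
  # yaw pi/2: vertex-wise rotation of the zero-state mesh
  st <- fishState(angles = c(0, 0, pi / 2), kappa = numeric(7))
  m1 <- deformAndPose(mod, st, pre)
  R <- taitBryanMatrix(0, 0, pi / 2)
  expect_lt(max(abs(m1@vertices - m0@vertices %*% t(R))), 1e-12)
  # constant curvature c*ell = pi: snout-to-tail chord = 2*ell/pi
  st <- fishState(kappa = rep(pi / 5, 7), kappaS = seq(0, 1, length.out = 7))
  modNoStiff <- mod
  modNoStiff@stiffFraction <- 0
  m2 <- deformAndPose(modNoStiff, st)
  tail <- m2@vertices[nrow(m2@vertices), ]
  expect_equal(sqrt(sum(tail^2)), 2 * mod@length / pi, tolerance = 0.002)
})

test_that("posed-mesh volume is invariant under rigid motion", {
  mod <- fixtureModel()
  pre <- makeDeformer(mod)
  kap <- c(0.1, -0.2, 0.4, 0.3, -0.5, 0.2, 0.6)
  v0 <- fishtrack3d:::.meshSignedVolume(
    deformVertices(pre, kap, c(0, 0, 0), c(0, 0, 0)), pre$triangles)
  set.seed(5)
  for (rep in 1:8) {
    v <- fishtrack3d:::.meshSignedVolume(
      deformVertices(pre, kap, rnorm(3), rnorm(3, 0, 5)), pre$triangles)
    expect_equal(v, v0, tolerance = 1e-10)
  }
})

test_that("sections remain planar and perpendicular to the centreline", {
  mod <- fixtureModel()
  pre <- makeDeformer(mod)
  kap <- c(0, 0.3, -0.4, 0.5, 0.2, -0.6, 0.4)
  V <- deformVertices(pre, kap, c(0, 0, 0), c(0, 0, 0))
  thSec <- drop(pre$Asec %*% kap)
  for (i in seq(2, pre$M - 1, by = 7)) {
    idx <- which(pre$ringIdx == i)
    ring <- V[idx, ]
    tangent <- c(cos(thSec[i]), sin(thSec[i]), 0)
    d <- ring %*% tangent
    expect_lt(diff(range(d)), 1e-9)
  }
})
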