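# Objective terms, prediction, initialisation and single-frame fitting.

test_that("goodness of fit equals the brute-force XOR count", {
  # direct cases through the exported interface
  mod <- fixtureModel()
  cams <- rigCameras(256, 15, target = c(2.5, 0, 0))
  st <- fishState(kappa = numeric(7))
  mesh <- deformAndPose(mod, st)
  masks <- lapply(cams, function(cm) renderSilhouette(cm, mesh))
  expect_equal(goodnessOfFit(st, masks, cams, mod), 0)
  # disjoint masks of sizes a and b: symmetric difference a + b
  off <- fishState(position = c(8, 0, 0), kappa = numeric(7))
  meshOff <- deformAndPose(mod, off)
  rendered <- lapply(cams, function(cm) renderSilhouette(cm, meshOff))
  a <- vapply(rendered, sum, numeric(1))
  b <- vapply(masks, sum, numeric(1))
  overlap <- mapply(function(x, y) sum(x & y), rendered, masks)
  expect_true(all(overlap == 0))
  expect_equal(goodnessOfFit(off, masks, cams, mod), sum(a + b))
  # property: random 32x32 mask pairs match an exhaustive pixel loop
  set.seed(8)
  for (rep in 1:25) {
    A <- matrix(runif(32 * 32) < 0.3, 32, 32)
    B <- matrix(runif(32 * 32) < 0.3, 32, 32)
    # rasterise A's set pixels as unit squares covering the pixel centres
    w <- which(A, arr.ind = TRUE)
    if (nrow(w) == 0) next
    px <- py <- numeric(0)
    tri <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(w))) {
      r <- w[k, 1]; cc <- w[k, 2]
      base <- length(px)
      px <- c(px, cc - 1, cc, cc, cc - 1)
      py <- c(py, r - 1, r - 1, r, r)
      tri <- rbind(tri, c(base + 1L, base + 2L, base + 3L),
                   c(base + 1L, base + 3L, base + 4L))
    }
    d <- fishtrack3d:::.silhouetteSymDiff(px, py, tri, B, sum(B))
    expect_equal(d, sum(xor(A, B)))
  }
})

test_that("regularisation matches closed forms and a dense Riemann sum", {
  cfg <- objectiveConfig(c0 = 7, c1 = 2.5)
  # constant curvature: zero penalty
  st <- fishState(kappa = rep(0.8, 7), kappaS = seq(0, 1, length.out = 7))
  expect_equal(regularisation(st, cfg), 0, tolerance = 1e-12)
  # linear curvature a*s with w = c0 exp(-c1 s):
  # integral = c0 a^2 (1 - exp(-c1)) / c1
  a <- 1.7
  st <- fishState(kappa = a * seq(0, 1, length.out = 7),
                  kappaS = seq(0, 1, length.out = 7))
  closed <- 7 * a^2 * (1 - exp(-2.5)) / 2.5
  expect_equal(regularisation(st, cfg), closed, tolerance = 1e-8)
  # arbitrary state: Gauss-Legendre equals a 1e5-point Riemann sum
  set.seed(4)
  kap <- rnorm(7, 0, 0.6)
  kS <- seq(0, 1, length.out = 7)
  st <- fishState(kappa = kap, kappaS = kS)
  got <- regularisation(st, cfg)
  sp <- fishtrack3d:::naturalSpline(kS, kap)
  s <- seq(0, 1, length.out = 1e5)
  smid <- (s[-1] + s[-length(s)]) / 2
  dk <- fishtrack3d:::evalSpline(sp, smid, deriv = 1L)
  riemann <- sum(7 * exp(-2.5 * smid) * dk^2) / (length(s) - 1)
  expect_equal(got, riemann, tolerance = 1e-6)
})

test_that("the total objective is the sum of its two terms", {
  mod <- fixtureModel()
  cams <- rigCameras(256, 15, target = c(2.5, 0, 0))
  st <- fishState(kappa = c(0, 0.2, 0.4, 0.1, -0.3, 0.2, 0.5))
  masks <- lapply(cams, function(cm)
    renderSilhouette(cm, deformAndPose(mod, st)))
  cfg0 <- objectiveConfig(c0 = 0)
  cfg <- objectiveConfig(c0 = 55)
  expect_equal(objective(st, masks, cams, mod, cfg0),
               goodnessOfFit(st, masks, cams, mod))
  expect_equal(objective(st, masks, cams, mod, cfg),
               goodnessOfFit(st, masks, cams, mod) +
                 regularisation(st, cfg))
  # perfect fit with constant curvature: exactly zero
  stc <- fishState(kappa = rep(0.3, 7))
  masksc <- lapply(cams, function(cm)
    renderSilhouette(cm, deformAndPose(mod, stc)))
  expect_equal(objective(stc, masksc, cams, mod, cfg), 0, tolerance = 1e-9)
})

test_that("state prediction copies or linearly extrapolates", {
  s1 <- fishState(position = c(1, 2, 3), angles = c(0.1, 0.2, 0.3),
                  kappa = rep(0.1, 7))
  expect_equal(stateToVector(predictState(list(s1))), stateToVector(s1))
  s2 <- fishState(position = c(1.1, 2, 3), angles = c(0.1, 0.2, 0.35),
                  kappa = rep(0.15, 7))
  p <- predictState(list(s1, s2))
  expect_equal(p@position[1], 1.2, tolerance = 1e-12)
  expect_equal(p@angles[3], 0.4, tolerance = 1e-12)
  expect_equal(p@kappa, rep(0.2, 7), tolerance = 1e-12)
  expect_error(predictState(list()), "empty")
  # constant-velocity trajectory: prediction error second order in the
  # trajectory's curvature
  tgrid <- (0:10) * 5e-4
  states <- cbind(2 * tgrid, -tgrid, 0 * tgrid, 0 * tgrid, 0 * tgrid,
                  0.5 * tgrid, matrix(0, 11, 7))
  pred <- predictState(states[1:10, ])
  expect_equal(pred, states[11, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("first-frame triangulation recovers snout and tail", {
  cams <- rigCameras(1024, 15, target = c(0, 0, 0))
  snout <- c(0.7, -0.4, 0.3)
  tail <- snout + 5 * c(-1, 0, 0)
  clicks <- lapply(cams, function(cm) list(
    snout = drop(projectPoints(cm, matrix(snout, 1))),
    tail = drop(projectPoints(cm, matrix(tail, 1)))))
  got <- initializeFirstFrame(clicks, cams)
  expect_lt(sqrt(sum((got$state@position - snout)^2)), 1e-6)
  expect_equal(got$state@angles[3], pi, tolerance = 1e-9)
  expect_equal(got$state@angles[2], 0, tolerance = 1e-9)
  expect_lt(got$residual, 1e-6)
  # perturbed clicks (+-2 px): residual reported and below 3 px
  set.seed(13)
  clicks2 <- lapply(clicks, function(cl) list(
    snout = cl$snout + runif(2, -2, 2), tail = cl$tail + runif(2, -2, 2)))
  got2 <- initializeFirstFrame(clicks2, cams)
  expect_lt(got2$residual, 3)
  expect_lt(sqrt(sum((got2$state@position - snout)^2)), 0.1)
  expect_error(initializeFirstFrame(clicks[1], cams[1]), "2 cameras")
})

test_that("single-frame fits recover known states from perturbed starts", {
  mod <- fixtureModel()
  cams <- rigCameras(1024, 15, target = c(-0.5, 0.7, -0.15))
  cfg <- objectiveConfig(fineMaxit = 2500, polishMaxit = 800)
  pre <- makeDeformer(mod)
  mot <- generateMotion(defaultMotionScript(), 2000, 60)
  set.seed(77)
  frames <- sample(5:60, 4)
  posErr <- numeric(0)
  for (i in frames) {
    sv <- mot$states[i, ]
    st <- vectorToState(sv, mot$kappaS)
    masks <- lapply(cams, function(cm)
      renderSilhouette(cm, deformAndPose(mod, st, pre)))
    p0 <- sv + c(rnorm(3, 0, 0.025), rnorm(3, 0, 3 * pi / 180),
                 rnorm(7, 0, 0.1 * max(abs(sv[7:13]), 0.1)))
    fit <- fitFrame(vectorToState(p0, mot$kappaS), masks, cams, NULL, cfg,
                    pre = pre)
    err <- stateToVector(fit$state) - sv
    posErr <- c(posErr, sqrt(sum(err[1:3]^2)))
    # snout within 1% of body length for every draw (the silhouette
    # objective has a flat basin for deeply bent poses)
    expect_lt(sqrt(sum(err[1:3]^2)), 0.01 * mod@length)
    # head angles within a few degrees (shallow yaw-curvature trade-off
    # near the head)
    expect_lt(max(abs(err[4:6])) * 180 / pi, 3)
    # monotone improvement: fine stage ended at or below the coarse stage
    expect_lte(fit$objective, fit$coarseObjective + 1e-9)
  }
  # typical recovery: snout within 0.5% of body length
  expect_lt(median(posErr), 0.005 * mod@length)
})

test_that("degenerate frames are flagged instead of crashing", {
  mod <- fixtureModel()
  cams <- rigCameras(128, 15, target = c(2.5, 0, 0))
  cfg <- objectiveConfig(fineMaxit = 200, polishMaxit = 100,
                         coarseMaxit = 60, maxRestarts = 1)
  st <- fishState(kappa = numeric(7))
  empty <- lapply(cams, function(cm)
    matrix(FALSE, cm@imageSize[2], cm@imageSize[1]))
  set.seed(1)
  fit <- fitFrame(st, empty, cams, mod, cfg, prevObjective = 10)
  expect_true(fit$flagged)
  expect_true(is.finite(fit$objective))
})
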