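# Synthetic motion scripts, image degradation and rendering geometry.

test_that("motion generation samples the script faithfully", {
  script <- defaultMotionScript()
  mot <- generateMotion(script, 2000, 40)
  expect_equal(dim(mot$states), c(40, 13))
  expect_equal(mot$time, (0:39) / 2000)
  # constant script: identical states every frame
  const <- script
  const$kappaFun <- function(t) rep(0.2, 7)
  const$yawFun <- function(t) pi
  const$pitchFun <- function(t) 0
  const$rollFun <- function(t) 0
  const$speedFun <- function(t) 0
  const$headingFun <- function(t) 0
  const$recoilFun <- function(t) 0
  const$diveFun <- function(t) 0
  mc <- generateMotion(const, 2000, 10)
  for (i in 2:10) expect_equal(mc$states[i, ], mc$states[1, ])
  # physiological self-checks of the default script
  expect_lt(max(abs(mot$states[, 7:13])), 1.5)       # |kappa| < 1.5 /mm
  v <- sqrt(rowSums(diff(mot$states[, 1:2])^2)) * 2000
  expect_lt(max(v), 500)                              # < 0.5 m/s snout speed
})

test_that("travelling-wave head-tail angle equals the analytic integral", {
  script <- defaultMotionScript()
  kS <- script$kappaS
  # pure wave: kappa(s, t) = A(s) sin(2 pi (f t - s / lambda))
  wave <- script
  A <- 0.4
  wave$kappaFun <- function(t) A * sin(2 * pi * (35 * t - kS / 1))
  mot <- generateMotion(wave, 2000, 20)
  for (i in c(1, 7, 20)) {
    st <- vectorToState(mot$states[i, ], kS)
    got <- integrateCenterline(st, 5, 400)$theta[400]
    sp <- fishtrack3d:::naturalSpline(kS, mot$states[i, 7:13])
    orc <- integrate(function(u) fishtrack3d:::evalSpline(sp, u),
                     0.1, 1, rel.tol = 1e-12)$value * 5
    expect_equal(got, orc, tolerance = 1e-10)
  }
})

test_that("degradation chain is deterministic and well-scaled", {
  mod <- fixtureModel()
  cams <- rigCameras(512, 15, target = c(-0.5, 0.7, -0.15))
  mot <- generateMotion(defaultMotionScript(), 2000, 3)
  # no degradation: binary-valued images = inverted silhouettes
  clean <- syntheticSequence(mot, mod, cams, degrade = NULL)
  fr <- clean$frame(2)
  st <- vectorToState(mot$states[2, ], mot$kappaS)
  mask <- renderSilhouette(cams[[1]], deformAndPose(mod, st))
  expect_equal(fr[[1]], 1 - mask * 1, ignore_attr = TRUE)
  # same seed: bit-identical output
  d1 <- syntheticSequence(mot, mod, cams, degradationConfig(seed = 5))
  d2 <- syntheticSequence(mot, mod, cams, degradationConfig(seed = 5))
  expect_identical(d1$frame(2), d2$frame(2))
  d3 <- syntheticSequence(mot, mod, cams, degradationConfig(seed = 6))
  expect_false(identical(d1$frame(2), d3$frame(2)))
  # background stays light, fish dark, values within [0, 1]
  f <- d1$frame(2)[[2]]
  expect_gte(min(f), 0)
  expect_lte(max(f), 1)
  expect_gt(mean(f[1:40, 1:40]), 0.85)
})

test_that("the simulated fish spans the documented pixel extents", {
  mod <- fixtureModel()
  # ~340 px along the fish at 1024^2 over a 15 mm field of view
  rigs <- resolutionVariants(c(512, 1024, 2048))
  lengths <- vapply(rigs, function(cams)
    as.numeric(apparentLengthPx(mod, cams[[1]],
      fishState(position = c(0.2, 0.7, -0.15), angles = c(0, 0, pi),
                kappa = numeric(7)))), numeric(1))
  expect_lt(abs(lengths[["1024"]] - 340), 5)
  expect_lt(abs(lengths[["512"]] - 170), 3)
  expect_lt(abs(lengths[["2048"]] - 680), 8)
  # the 2048^2 measurement is 4x the 512^2 one up to sub-pixel truncation
  # of the tapering tail tip
  expect_lt(abs(lengths[["2048"]] - 4 * lengths[["512"]]), 8)
  # pixel scale ratios are exactly 2x per step
  expect_equal(rigs[["1024"]][[1]]@focal / rigs[["512"]][[1]]@focal,
               c(2, 2))
  expect_equal(rigs[["2048"]][[1]]@focal / rigs[["1024"]][[1]]@focal,
               c(2, 2))
})

test_that("cylinder simulation integrates sinusoidal torque accurately", {
  tau0 <- 3e-9
  sim <- simulateCylinder(function(t) c(0, 0, 0),
                          function(t) c(0, 0, tau0 * sin(2 * pi * 30 * t)),
                          fps = 2000, nFrames = 80)
  dyn <- meshDynamics(sim$Varr, sim$tri, fps = 2000)
  keep <- 6:75
  tErr <- sqrt(rowSums((dyn$torque - sim$refTorque)^2))[keep]
  expect_lt(sqrt(mean(tErr^2)) / tau0, 0.02)
  expect_lt(max(abs(dyn$force[keep, ])), 1e-12)
})
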