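# Cross-section components, contour merging and body-model construction.

test_that("superellipse evaluation matches closed forms and quadrature", {
  # n = 2 is a circle
  p <- evalSuperellipse(1, 1, 2, 360)
  expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)
  # ellipse area converges to pi*a*b
  p <- evalSuperellipse(2, 1, 2, 20000)
  expect_equal(polyArea(p), 2 * pi, tolerance = 1e-6)
  # Lame curve n = 4: area from numerical quadrature of the area integral
  # (independent oracle): 4 * int_0^1 (1 - x^4)^(1/4) dx = 3.708149...
  oracle <- 4 * integrate(function(x) (1 - x^4)^(1 / 4), 0, 1,
                          rel.tol = 1e-12)$value
  p <- evalSuperellipse(1, 1, 4, 20000)
  expect_equal(polyArea(p), oracle, tolerance = 1e-5)
  expect_error(evalSuperellipse(-1, 1, 2), "positive")
  expect_error(evalSuperellipse(1, 1, 0), "positive")
})

test_that("component merging takes the outermost contour", {
  # single component: identity up to resampling
  tr <- evalSuperellipse(1, 0.6, 2, 256)
  m <- mergeComponents(tr, P = 64)
  expect_equal(nrow(m), 64)
  expect_equal(polyArea(m), polyArea(tr), tolerance = 5e-3)
  # contained component vanishes
  outer <- evalSuperellipse(1, 1, 2, 256)
  inner <- evalSuperellipse(0.5, 0.5, 2, 256)
  m <- mergeComponents(outer, inner, P = 128)
  expect_equal(polyArea(m), pi, tolerance = 1e-3)
  # overlapping circles: union area = 2*pi - lens, checked against a dense
  # rasterised-union pixel count oracle
  c1 <- evalSuperellipse(1, 1, 2, 512, c(0, 0.5))
  c2 <- evalSuperellipse(1, 1, 2, 512, c(0, -0.5))
  m <- mergeComponents(c1, c2, P = 720)
  lens <- 2 * acos(0.5) - 0.5 * sqrt(3)
  expect_equal(polyArea(m), 2 * pi - lens, tolerance = 1e-3)
  gx <- seq(-1.6, 1.6, length.out = 801)
  gr <- as.matrix(expand.grid(gx, gx))
  inUnion <- fishtrack3d:::.pointInPolygon(gr, c1) |
    fishtrack3d:::.pointInPolygon(gr, c2)
  rasterArea <- sum(inUnion) * (gx[2] - gx[1])^2
  expect_equal(polyArea(m), rasterArea, tolerance = 2e-2)
})

test_that("merging is idempotent and order-invariant", {
  tr <- evalSuperellipse(1, 0.7, 2.5, 256)
  eye <- evalSuperellipse(0.4, 0.3, 3, 128, c(0.8, 0.2))
  m1 <- mergeComponents(tr, eye, P = 80)
  m2 <- mergeComponents(eye, tr, P = 80)
  expect_equal(m1, m2, tolerance = 1e-10)
  again <- mergeComponents(m1, P = 80)
  expect_equal(again, m1, tolerance = 1e-8)
})

test_that("disconnected components are rejected", {
  tr <- evalSuperellipse(0.5, 0.5, 2, 128)
  far <- evalSuperellipse(0.2, 0.2, 2, 128, c(3, 0))
  expect_error(mergeComponents(tr, far, P = 40), "disconnected")
})

test_that("capsule body model reproduces the closed-form volume", {
  mod <- buildBodyModel(capsuleSpecs(nRec = 33), length = 5, P = 64,
                        M = 101, stiffFraction = 0.1)
  mesh <- bodyMesh(mod)
  expect_true(isWatertight(mesh))
  vol <- massProperties(mesh)$volume
  r <- 0.625
  exact <- pi * r^2 * (5 - 2 * r) + 4 / 3 * pi * r^3
  expect_equal(vol, exact, tolerance = 0.01)
})

test_that("the zebrafish fixture builds a closed, sane surface", {
  mod <- fixtureModel()
  expect_s4_class(mod, "BodyModel")
  expect_true(all(diff(mod@sValues) > 0))
  mesh <- bodyMesh(mod)
  expect_true(isWatertight(mesh))
  vol <- massProperties(mesh)$volume
  expect_gt(vol, 0.3)            # a 5 mm larva displaces ~0.5-1.5 mm^3
  expect_lt(vol, 2.5)
  # volume vs a voxelisation oracle within 0.5% at 100^3 resolution
  V <- mesh@vertices
  lims <- apply(V, 2, range)
  n <- 100
  gx <- seq(lims[1, 1], lims[2, 1], length.out = n)
  # voxel column test: for speed, sample z-columns over an x,y grid and
  # use the section polygons directly in the head frame (straight pose)
  pre <- makeDeformer(mod)
  sGrid <- mod@sValues * mod@length
  inside <- 0
  dx <- diff(gx)[1]
  gy <- seq(lims[1, 2], lims[2, 2], length.out = n)
  gz <- seq(lims[1, 3], lims[2, 3], length.out = n)
  dv <- dx * diff(gy)[1] * diff(gz)[1]
  pts <- as.matrix(expand.grid(gy, gz))
  for (x in gx) {
    i <- which.min(abs(sGrid - x))
    sec <- mod@sections[, , i]
    if (all(sec == 0)) next
    inside <- inside + sum(fishtrack3d:::.pointInPolygon(pts, sec))
  }
  expect_equal(inside * dv, vol, tolerance = 0.03)
})

test_that("degenerate spec lists are rejected", {
  sp <- capsuleSpecs()[c(1, 6, 17)]
  expect_error(buildBodyModel(sp, length = 5), "at least 4")
  bad <- capsuleSpecs()
  bad[[3]]$s <- bad[[2]]$s
  expect_error(buildBodyModel(bad, length = 5), "sorted")
})

test_that("body spec files round-trip", {
  specs <- capsuleSpecs(nRec = 9)
  path <- tempfile(fileext = ".yaml")
  writeBodySpec(path, "capsule-test", 5, 0.1, specs)
  back <- readBodySpec(path)
  expect_equal(back$length, 5)
  expect_equal(back$stiff_fraction, 0.1)
  expect_equal(length(back$specs), 9)
  expect_equal(back$specs[[5]]$trunkY, specs[[5]]$trunkY, tolerance = 1e-6)
})
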