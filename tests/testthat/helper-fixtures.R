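# Shared fixtures, built in code. Expensive objects are memoised in this
# environment so multiple test files can share them within one run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fixtureModel <- function() memo("model", zebrafishModel())

# cylinder-like body-model specs: constant circular section with
# hemispherical end caps, radius r over total length len
capsuleSpecs <- function(r = 0.625, len = 5, nRec = 17) {
  s <- seq(0, 1, length.out = nRec)
  phi <- (0:7) * pi / 4
  lapply(s, function(si) {
    x <- si * len
    rad <- if (x < r) sqrt(max(r^2 - (r - x)^2, 0))
           else if (x > len - r) sqrt(max(r^2 - (x - (len - r))^2, 0))
           else r
    crossSectionSpec(si, rad * sin(phi), rad * cos(phi))
  })
}

# polygon area by the shoelace formula
polyArea <- function(p) {
  n <- nrow(p)
  abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
}

# wrap-safe distance between the tips of two rotation vectors (axis-angle);
# rotations by an angle near pi have two equivalent representations
rotVecDist <- function(R1, R2) {
  v1 <- rotationVector(R1)
  v2 <- rotationVector(R2)
  alts <- function(v) {
    a <- sqrt(sum(v^2))
    if (a < 1e-12) list(v) else list(v, v * (a - 2 * pi) / a)
  }
  best <- Inf
  for (a in alts(v1)) for (b in alts(v2))
    best <- min(best, sqrt(sum((a - b)^2)))
  best
}

# head-tail angle (deg) of a state row: body length times the integral of
# the curvature spline
headTailAngle <- function(stateRow, kappaS, ell = 5) {
  th <- integrateCenterline(vectorToState(stateRow, kappaS), ell)$theta
  th[length(th)] * 180 / pi
}
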