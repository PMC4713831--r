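# Morphology: building the undeformed 3D surface model from per-section
# component shapes (trunk spline contour, eye superellipses, fin-fold
# ellipse), merged into single cross-sections and lofted into a watertight
# triangulated surface.
#
# Section-plane conventions: local y is lateral, local z is dorsal, the
# centreline passes through the origin of every section plane.  Merged
# contours are sampled at P canonical ray angles measured from +z (dorsal)
# rotating towards +y, so every section shares the same start point and
# winding and sections connect into quadrilateral faces.

#' Evaluate a superellipse contour
#'
#' Points on the Lame curve |x/a|^n + |y/b|^n = 1, uniformly sampled in the
#' angular parameter, returned as an open polygon (closure implicit).
#'
#' @param a,b semi-axes (> 0).
#' @param n exponent (> 0); n = 2 gives an ordinary ellipse.
#' @param nPoints number of samples (>= 8).
#' @param centre contour centre offset, length 2.
#' @return nPoints x 2 matrix.
#' @export
evalSuperellipse <- function(a, b, n = 2, nPoints = 64, centre = c(0, 0)) {
  if (a <= 0 || b <= 0 || n <= 0)
    stop("superellipse parameters must be positive")
  if (nPoints < 8) stop("nPoints must be >= 8")
  t <- seq(0, 2 * pi, length.out = nPoints + 1)[-(nPoints + 1)]
  e <- 2 / n
  cbind(centre[1] + a * sign(cos(t)) * abs(cos(t))^e,
        centre[2] + b * sign(sin(t)) * abs(sin(t))^e)
}

# evaluate a closed trunk contour from its cubic-spline control points by
# periodic parametric splines in the point index
.evalTrunkContour <- function(y, z, nPoints = 256) {
  k <- length(y)
  t <- 0:k
  ts <- seq(0, k, length.out = nPoints + 1)[-(nPoints + 1)]
  cy <- stats::spline(t, c(y, y[1]), method = "periodic", xout = ts)$y
  cz <- stats::spline(t, c(z, z[1]), method = "periodic", xout = ts)$y
  cbind(cy, cz)
}

# even-odd point-in-polygon, vectorised over query points
.pointInPolygon <- function(pts, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, nrow(pts))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > pts[, 2]) != (ye[i] > pts[, 2]))
    xint <- xs[i] + (pts[, 2] - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
    inside <- xor(inside, crosses & (pts[, 1] < xint))
  }
  inside
}

# farthest intersection distance of rays from `centre` with a polygon,
# one ray per angle; 0 where the ray misses the polygon entirely
.rayPolygonMax <- function(poly, centre, theta) {
  n <- nrow(poly)
  p1 <- sweep(poly, 2, centre)
  p2 <- p1[c(2:n, 1), , drop = FALSE]
  ex <- p2[, 1] - p1[, 1]; ey <- p2[, 2] - p1[, 2]
  out <- numeric(length(theta))
  dx <- sin(theta); dy <- cos(theta)   # angle from +z (local col 2) towards +y
  for (k in seq_along(theta)) {
    den <- dx[k] * (-ey) + dy[k] * ex
    ok <- abs(den) > 1e-14
    # solve centre + t*d = p1 + u*(p2-p1)
    t <- (p1[, 1] * (-ey) + p1[, 2] * ex) / den
    u <- (dx[k] * p1[, 2] - dy[k] * p1[, 1]) / den
    hit <- ok & u >= -1e-12 & u <= 1 + 1e-12 & t > 0
    out[k] <- if (any(hit)) max(t[hit]) else 0
  }
  out
}

# do two simple polygons intersect (share area or touch)?
.polygonsOverlap <- function(a, b) {
  any(.pointInPolygon(a, b)) || any(.pointInPolygon(b, a))
}

#' Merge component contours into a single cross-section
#'
#' Components (trunk, optional eyes, optional fin fold) are merged by their
#' outermost contour: for each of P canonical rays from the section origin,
#' the farthest crossing over all components is kept. The result is a
#' closed contour of exactly P points with the canonical start point
#' (dorsal-most ray) and winding shared by all sections of a model.
#'
#' @param trunk closed contour, k x 2 matrix (local y, z in mm).
#' @param eyes optional contour or list of contours (e.g. the two mirrored
#'   eye superellipses).
#' @param finfold optional contour.
#' @param P circumferential point count of the merged section.
#' @return P x 2 matrix.
#' @export
mergeComponents <- function(trunk, eyes = NULL, finfold = NULL, P = 40) {
  comps <- list(trunk)
  addComp <- function(comps, x) {
    if (is.null(x)) return(comps)
    if (is.list(x)) c(comps, x) else c(comps, list(x))
  }
  comps <- addComp(comps, eyes)
  comps <- addComp(comps, finfold)
  if (length(comps) > 1L) {
    base <- comps[[1L]]
    for (i in 2L:length(comps))
      if (!.polygonsOverlap(base, comps[[i]]))
        stop("component union is disconnected: every component must overlap the trunk")
  }
  theta <- 2 * pi * (seq_len(P) - 1) / P
  r <- rep(0, P)
  for (cp in comps) r <- pmax(r, .rayPolygonMax(cp, c(0, 0), theta))
  cbind(r * sin(theta), r * cos(theta))
}

#' Cross-section specification record
#'
#' One digitised record of the body-model spec: arclength position, trunk
#' contour control points, and optional eye-superellipse and fin-fold
#' ellipse parameters. Eyes are specified once and mirrored about the
#' midsagittal plane.
#'
#' @param s normalised arclength in [0, 1].
#' @param trunkY,trunkZ trunk cubic-spline control points (mm); all records
#'   of a model must use the same count.
#' @param eye NULL or list(a, b, n, cy, cz): superellipse semi-axes,
#'   exponent, and centre offset of the (mirrored) eyes.
#' @param finfold NULL or list(a, b, cz): fin-fold ellipse lateral/vertical
#'   semi-axes and vertical centre offset.
#' @return list of class \code{"crossSectionSpec"}.
#' @export
crossSectionSpec <- function(s, trunkY, trunkZ, eye = NULL, finfold = NULL) {
  stopifnot(s >= 0, s <= 1, length(trunkY) == length(trunkZ),
            length(trunkY) >= 4)
  if (!is.null(eye)) {
    stopifnot(eye$a > 0, eye$b > 0, eye$n > 0)
  }
  if (!is.null(finfold)) stopifnot(finfold$a > 0, finfold$b > 0)
  structure(list(s = s, trunkY = trunkY, trunkZ = trunkZ,
                 eye = eye, finfold = finfold),
            class = "crossSectionSpec")
}

# natural-spline interpolation of one component parameter across records,
# clamped to zero outside [sMin, sMax]
.paramSpline <- function(sRec, vRec) {
  sp <- naturalSpline(sRec, vRec)
  rng <- range(sRec)
  function(s) {
    v <- evalSpline(sp, pmin(pmax(s, rng[1]), rng[2]))
    v[s < rng[1] | s > rng[2]] <- 0
    v
  }
}

#' Build a BodyModel from cross-section specs
#'
#' Interpolates every component parameter along the body with natural cubic
#' splines (clamped to zero beyond the component's longitudinal extent),
#' evaluates and merges the component contours at M stations, and collapses
#' the terminal stations to single points so the straight-pose triangulated
#' surface closes at snout and tail.
#'
#' @param specs list of \code{\link{crossSectionSpec}} records, strictly
#'   increasing in s, at least 4, spanning [0, 1].
#' @param length reference body length (mm).
#' @param P circumferential points per merged section (default 40).
#' @param M longitudinal stations (default 51).
#' @param stiffFraction anterior fraction with curvature pinned to zero.
#' @return A \code{\linkS4class{BodyModel}}.
#' @export
buildBodyModel <- function(specs, length = 5, P = 40, M = 51,
                           stiffFraction = 0.1) {
  if (base::length(specs) < 4L)
    stop("need at least 4 cross-section specs")
  sRec <- vapply(specs, function(x) x$s, numeric(1))
  if (any(diff(sRec) <= 0))
    stop("specs must be sorted by strictly increasing s")
  if (sRec[1] > 1e-9 || sRec[base::length(sRec)] < 1 - 1e-9)
    stop("specs must span s in [0, 1]")
  k <- base::length(specs[[1]]$trunkY)
  if (!all(vapply(specs, function(x) base::length(x$trunkY) == k, logical(1))))
    stop("all records must share the same trunk control-point count")

  # trunk control-point coordinate splines
  trunkYf <- lapply(seq_len(k), function(j)
    .paramSpline(sRec, vapply(specs, function(x) x$trunkY[j], numeric(1))))
  trunkZf <- lapply(seq_len(k), function(j)
    .paramSpline(sRec, vapply(specs, function(x) x$trunkZ[j], numeric(1))))

  # optional component parameter splines over their record extent
  compSplines <- function(get, fields) {
    has <- vapply(specs, function(x) !is.null(get(x)), logical(1))
    if (sum(has) < 2L) return(NULL)
    sr <- sRec[has]
    fns <- lapply(fields, function(f)
      .paramSpline(sr, vapply(specs[has], function(x) get(x)[[f]], numeric(1))))
    names(fns) <- fields
    c(fns, list(range = range(sr)))
  }
  eyeF <- compSplines(function(x) x$eye, c("a", "b", "n", "cy", "cz"))
  finF <- compSplines(function(x) x$finfold, c("a", "b", "cz"))

  sStations <- seq(0, 1, length.out = M)
  sections <- array(0, dim = c(P, 2, M))
  for (i in 2:(M - 1)) {
    s <- sStations[i]
    ty <- vapply(trunkYf, function(f) f(s), numeric(1))
    tz <- vapply(trunkZf, function(f) f(s), numeric(1))
    trunk <- .evalTrunkContour(ty, tz)
    eyes <- NULL
    if (!is.null(eyeF) && s >= eyeF$range[1] && s <= eyeF$range[2]) {
      a <- eyeF$a(s); b <- eyeF$b(s)
      if (a > 1e-6 && b > 1e-6) {
        n <- max(eyeF$n(s), 0.5); cy <- eyeF$cy(s); cz <- eyeF$cz(s)
        eyes <- list(evalSuperellipse(a, b, n, 64, c(cy, cz)),
                     evalSuperellipse(a, b, n, 64, c(-cy, cz)))
      }
    }
    fin <- NULL
    if (!is.null(finF) && s >= finF$range[1] && s <= finF$range[2]) {
      a <- finF$a(s); b <- finF$b(s)
      if (a > 1e-6 && b > 1e-6)
        fin <- evalSuperellipse(a, b, 2, 64, c(0, finF$cz(s)))
    }
    sections[, , i] <- mergeComponents(trunk, eyes, fin, P = P)
  }
  new("BodyModel", sections = sections, sValues = sStations,
      length = length, stiffFraction = stiffFraction)
}
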