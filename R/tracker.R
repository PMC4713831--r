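# Tracker: per-frame Nelder-Mead optimisation of the fish state against the
# multi-camera silhouettes.
#
# Objective: f_tot = f_GoF + f_reg, where f_GoF is the total pixel count of
# the symmetric difference between rendered and segmented silhouettes over
# all cameras, and f_reg = integral w(s) (dkappa/ds)^2 ds with the
# head-weighted w(s) = c0 exp(-c1 s). The regulariser is a quadratic form
# in the curvature control values (the spline is linear in them), so it is
# precomputed as a K x K matrix with Gauss-Legendre quadrature per spline
# piece.

# quadratic-form matrix of the regularisation integral
.regularisationMatrix <- function(kappaS, c0, c1, stiffFraction) {
  K <- length(kappaS)
  Q <- matrix(0, K, K)
  basisDeriv <- function(sNodes) {
    B <- matrix(0, length(sNodes), K)
    for (k in seq_len(K)) {
      ek <- numeric(K); ek[k] <- 1
      B[, k] <- evalSpline(naturalSpline(kappaS, ek), sNodes, deriv = 1L)
    }
    B
  }
  for (p in seq_len(K - 1L)) {
    a <- kappaS[p]; b <- kappaS[p + 1L]
    gl <- pracma::gaussLegendre(6, a, b)
    W <- gl$w * c0 * exp(-c1 * gl$x)
    G <- basisDeriv(gl$x)
    Q <- Q + crossprod(G, G * W)
  }
  # curvature is clamped to zero over the stiff head; when the first
  # control point sits at that boundary, charge the transition from the
  # clamped region as a linear ramp over half a control spacing --
  # otherwise the first control value is a free hinge
  if (stiffFraction > 0 && stiffFraction >= kappaS[1] - 1e-9 && K >= 2L) {
    delta <- (kappaS[2] - kappaS[1]) / 2
    Q[1, 1] <- Q[1, 1] + c0 * exp(-c1 * kappaS[1]) / delta
  }
  Q
}

#' Curvature-gradient regularisation term
#'
#' f_reg = integral of w(s) (dkappa/ds)^2 over the spline support, with
#' w(s) = c0 exp(-c1 s); zero iff the interpolated curvature is constant.
#'
#' @param state a \code{\linkS4class{FishState}}.
#' @param cfg an \code{\linkS4class{ObjectiveConfig}}.
#' @return non-negative scalar.
#' @export
regularisation <- function(state, cfg) {
  Q <- .regularisationMatrix(state@kappaS, cfg@c0, cfg@c1, 0)
  drop(state@kappa %*% Q %*% state@kappa)
}

#' Silhouette goodness of fit
#'
#' Sum over cameras of the symmetric-difference pixel count between the
#' rendered silhouette of the posed model and the segmented video
#' silhouette (union minus intersection).
#'
#' @param state a \code{\linkS4class{FishState}}.
#' @param silhouettes list of binary masks (one per camera).
#' @param cams list of \code{\linkS4class{CameraModel}}s.
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param pre optional precomputed deformer.
#' @return non-negative pixel count.
#' @export
goodnessOfFit <- function(state, silhouettes, cams, model, pre = NULL) {
  if (is.null(pre)) pre <- makeDeformer(model, state@kappaS)
  V <- deformVertices(pre, state@kappa, state@angles, state@position)
  total <- 0
  for (ci in seq_along(cams)) {
    m <- silhouettes[[ci]]
    uv <- projectPoints(cams[[ci]], V)
    total <- total + .silhouetteSymDiff(uv[, 1], uv[, 2], pre$triangles,
                                        m, sum(m))
  }
  total
}

#' Total tracking objective
#'
#' @inheritParams goodnessOfFit
#' @param cfg an \code{\linkS4class{ObjectiveConfig}}.
#' @return f_GoF + f_reg.
#' @export
objective <- function(state, silhouettes, cams, model, cfg, pre = NULL) {
  goodnessOfFit(state, silhouettes, cams, model, pre) +
    regularisation(state, cfg)
}

# fast closure over fixed frame data; par is the raw parameter vector.
# All-orthographic rigs take a fused compiled path (projection + symmetric
# difference in one call, back-facing triangles culled on the closed mesh).
.makeObjectiveFun <- function(masks, counts, cams, pre, Q) {
  allOrtho <- all(vapply(cams, function(cm) cm@type == "orthographic",
                         logical(1)))
  if (allOrtho) {
    Alist <- lapply(cams, function(cm)
      diag(cm@focal) %*% cm@R[1:2, , drop = FALSE])
    blist <- lapply(cams, function(cm)
      cm@focal * cm@t[1:2] + cm@principal)
    tri <- pre$triangles
    function(par) {
      kap <- par[-(1:6)]
      V <- deformVertices(pre, kap, par[4:6], par[1:3])
      drop(kap %*% Q %*% kap) +
        .orthoObjective(V, tri, Alist, blist, masks, counts, TRUE)
    }
  } else {
    function(par) {
      kap <- par[-(1:6)]
      V <- deformVertices(pre, kap, par[4:6], par[1:3])
      tot <- drop(kap %*% Q %*% kap)
      for (ci in seq_along(cams)) {
        uv <- projectPoints(cams[[ci]], V)
        tot <- tot + .silhouetteSymDiff(uv[, 1], uv[, 2], pre$triangles,
                                        masks[[ci]], counts[ci])
      }
      tot
    }
  }
}

#' Predict the state of the next frame
#'
#' Copies a single previous state; with two or more, linearly extrapolates
#' position, (unwrapped) angles and curvature control values from the last
#' two.
#'
#' @param states list of previous \code{\linkS4class{FishState}}s or a
#'   matrix of state rows (oldest first).
#' @return a \code{\linkS4class{FishState}} (matrix input: a vector).
#' @export
predictState <- function(states) {
  if (is(states, "FishState")) return(states)
  if (is.list(states)) {
    if (length(states) == 0L) stop("empty history: initialise the first frame manually")
    kS <- states[[length(states)]]@kappaS
    rows <- t(vapply(states, stateToVector,
                     numeric(6 + length(states[[1]]@kappa))))
    v <- predictState(rows)
    return(vectorToState(v, kS))
  }
  n <- nrow(states)
  if (n == 0L) stop("empty history: initialise the first frame manually")
  if (n == 1L) return(states[1, ])
  2 * states[n, ] - states[n - 1, ]
}

#' Triangulate the first-frame state from clicked snout/tail pixels
#'
#' Least-squares intersection of the projection constraints from two or
#' more cameras recovers the snout and tail in 3D; yaw and pitch are set
#' from the snout-to-tail direction, roll and curvature to zero.
#'
#' @param clicks list per camera: list(snout = c(u, v), tail = c(u, v)).
#' @param cams list of \code{\linkS4class{CameraModel}}s (>= 2).
#' @param K number of curvature control points.
#' @param stiffFraction anterior zero-curvature fraction.
#' @return list(state, residual): the initial \code{FishState} and the RMS
#'   reprojection residual (px).
#' @export
initializeFirstFrame <- function(clicks, cams, K = 7, stiffFraction = 0.1) {
  if (length(clicks) < 2L) stop("need clicks from at least 2 cameras")
  triangulate <- function(field) {
    A <- NULL; b <- NULL
    for (ci in seq_along(cams)) {
      cam <- cams[[ci]]
      uv <- clicks[[ci]][[field]]
      if (is.null(uv)) next
      if (cam@type == "orthographic") {
        Ai <- diag(cam@focal) %*% cam@R[1:2, , drop = FALSE]
        bi <- uv - (cam@focal * cam@t[1:2] + cam@principal)
      } else {
        # (f r1 - (u - cx) r3) X = (u - cx) t3 - f t1, same for v
        Ai <- rbind(cam@focal[1] * cam@R[1, ] -
                      (uv[1] - cam@principal[1]) * cam@R[3, ],
                    cam@focal[2] * cam@R[2, ] -
                      (uv[2] - cam@principal[2]) * cam@R[3, ])
        bi <- c((uv[1] - cam@principal[1]) * cam@t[3] -
                  cam@focal[1] * cam@t[1],
                (uv[2] - cam@principal[2]) * cam@t[3] -
                  cam@focal[2] * cam@t[2])
      }
      A <- rbind(A, Ai); b <- c(b, bi)
    }
    sv <- svd(A)
    if (sv$d[3] < 1e-6 * sv$d[1])
      stop("ill-conditioned triangulation: camera rays nearly parallel")
    X <- drop(sv$v %*% ((crossprod(sv$u, b)[1:3]) / sv$d))
    list(X = X, residual = sqrt(mean((A %*% X - b)^2)))
  }
  sn <- triangulate("snout")
  tl <- triangulate("tail")
  d <- tl$X - sn$X
  yaw <- atan2(d[2], d[1])
  pitch <- -asin(d[3] / sqrt(sum(d^2)))
  st <- fishState(position = sn$X, angles = c(0, pitch, yaw),
                  kappa = numeric(K), stiffFraction = stiffFraction)
  list(state = st, residual = sqrt(mean(c(sn$residual, tl$residual)^2)))
}

# simplex scale vector: optim's Nelder-Mead opens its initial simplex at
# 0.1 of a unit when started from the (re-centred) origin, so one tenth of
# these scales is the opening move per parameter group: a few pixels in
# position (0.1 ell), about half a degree in angle, and a curvature step
# whose tail deflection is of the same pixel order
.parScale <- function(ell, K) {
  c(rep(0.1 * ell, 3), rep(0.1, 3), rep(0.75 / ell, K))
}

# one re-centred Nelder-Mead pass over a parameter subset; accepts the
# result only when it improves
.nmPass <- function(fn, cur, fcur, idx, scale, reltol, maxit) {
  fz <- function(z) {
    p <- cur
    p[idx] <- p[idx] + z * scale[idx]
    fn(p)
  }
  o <- optim(numeric(length(idx)), fz, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = reltol))
  if (o$value < fcur) {
    cur[idx] <- cur[idx] + o$par * scale[idx]
    fcur <- o$value
  }
  list(par = cur, value = fcur)
}

# 2x2 block-mean downsampling of a numeric image
.downsample2 <- function(m) {
  H <- nrow(m) %/% 2L * 2L
  W <- ncol(m) %/% 2L * 2L
  mm <- m[seq_len(H), seq_len(W)]
  (mm[seq(1, H, 2), seq(1, W, 2)] + mm[seq(2, H, 2), seq(1, W, 2)] +
     mm[seq(1, H, 2), seq(2, W, 2)] + mm[seq(2, H, 2), seq(2, W, 2)]) / 4
}

# Per-frame fitting context: precomputed camera matrices, soft (graded)
# masks at half resolution for the coarse search, binary masks at full
# resolution for the final (paper-faithful) pixel-count objective.
.frameContext <- function(silhouettes, cams, pre, cfg) {
  Alist <- lapply(cams, function(cm)
    diag(cm@focal) %*% cm@R[1:2, , drop = FALSE])
  blist <- lapply(cams, function(cm) cm@focal * cm@t[1:2] + cm@principal)
  Alist2 <- lapply(Alist, function(A) A / 2)
  blist2 <- lapply(blist, function(b) b / 2)
  soft <- lapply(silhouettes, function(m)
    .gaussBlur(.downsample2(m * 1), cfg@softSigma))
  ssum <- vapply(soft, sum, numeric(1))
  counts <- vapply(silhouettes, sum, numeric(1))
  Q <- .regularisationMatrix(pre$kappaS, cfg@c0, cfg@c1, pre$stiff)
  tri <- pre$triangles
  allOrtho <- all(vapply(cams, function(cm) cm@type == "orthographic",
                         logical(1)))
  fnB <- if (allOrtho) {
    function(par) {
      kap <- par[-(1:6)]
      V <- deformVertices(pre, kap, par[4:6], par[1:3])
      drop(kap %*% Q %*% kap) +
        .orthoObjective(V, tri, Alist, blist, silhouettes, counts, TRUE)
    }
  } else .makeObjectiveFun(silhouettes, counts, cams, pre, Q)
  fnS <- if (allOrtho) {
    function(par) {
      kap <- par[-(1:6)]
      V <- deformVertices(pre, kap, par[4:6], par[1:3])
      drop(kap %*% Q %*% kap) / 4 +
        .orthoObjectiveSoft(V, tri, Alist2, blist2, soft, ssum, TRUE)
    }
  } else fnB
  list(fnB = fnB, fnS = fnS)
}

# one complete two-stage optimisation from a start vector:
# coarse = re-centred subspace Nelder-Mead passes on the smoothed
# half-resolution objective; fine = adaptive Nelder-Mead (ten-fold reduced
# tolerance) on the smoothed objective, then a final polish on the exact
# binary symmetric-difference objective
.runStages <- function(ctx, par0, scale, cfg) {
  rigid <- 1:6
  bend <- 7:length(par0)
  all_ <- seq_along(par0)
  cur <- par0
  fcur <- ctx$fnS(cur)
  for (st in list(list(rigid, 1), list(bend, 1), list(all_, 1 / 3))) {
    r <- .nmPass(ctx$fnS, cur, fcur, st[[1]], scale * st[[2]],
                 cfg@coarseTol, cfg@coarseMaxit)
    cur <- r$par; fcur <- r$value
  }
  coarse <- fcur
  o <- pracma::anms(function(z) ctx$fnS(cur + z * scale / 5),
                    numeric(length(cur)), tol = 1e-5,
                    maxfeval = cfg@fineMaxit)
  if (o$fmin < fcur) cur <- cur + o$xmin * scale / 5
  fb <- ctx$fnB(cur)
  o <- pracma::anms(function(z) ctx$fnB(cur + z * scale / 8),
                    numeric(length(cur)), tol = 1e-5,
                    maxfeval = cfg@polishMaxit)
  if (o$fmin < fb) {
    cur <- cur + o$xmin * scale / 8
    fb <- o$fmin
  }
  list(par = cur, value = fb, coarse = coarse)
}

#' Fit the fish state to one frame
#'
#' Two-stage optimisation from the predicted initial state: a coarse stage
#' of re-centred Nelder-Mead passes (rigid-motion subspace, curvature
#' subspace, joint) on a smoothed half-resolution silhouette objective,
#' then a fine stage with ten-fold reduced tolerance (adaptive Nelder-Mead
#' on the joint space) finishing on the exact binary symmetric-difference
#' objective. If the result exceeds \code{prevObjective} by more than the
#' restart threshold (relative), additional optimisations run from
#' randomised perturbations of the initial state (about 1% body length in
#' position, 4 degrees in angles, 20% of the curvature range), with the
#' perturbation scale escalating per retry, up to the retry cap; the best
#' state found is returned, flagged if the cap was exhausted.
#'
#' @param initial initial \code{\linkS4class{FishState}}.
#' @param silhouettes list of binary masks per camera.
#' @param cams list of \code{\linkS4class{CameraModel}}s.
#' @param model a \code{\linkS4class{BodyModel}} (or NULL with \code{pre}).
#' @param cfg an \code{\linkS4class{ObjectiveConfig}}.
#' @param prevObjective reference objective of the previous frame (or a
#'   running baseline), or NULL for the first frame.
#' @param pre optional precomputed deformer.
#' @return list(state, objective, coarseObjective, restarts, flagged).
#' @export
fitFrame <- function(initial, silhouettes, cams, model, cfg,
                     prevObjective = NULL, pre = NULL) {
  if (is.null(pre)) pre <- makeDeformer(model, initial@kappaS)
  ctx <- .frameContext(silhouettes, cams, pre, cfg)
  scale <- .parScale(pre$ell, pre$K)
  par0 <- stateToVector(initial)
  best <- .runStages(ctx, par0, scale, cfg)
  restarts <- 0L
  flagged <- FALSE
  if (!is.null(prevObjective) && is.finite(prevObjective)) {
    K <- pre$K
    kapRange <- max(diff(range(par0[-(1:6)])), 0.3 / pre$ell)
    while (best$value > prevObjective * (1 + cfg@restartThreshold) &&
           restarts < cfg@maxRestarts) {
      restarts <- restarts + 1L
      start <- par0 + restarts * c(rnorm(3, 0, 0.008 * pre$ell),
                                   rnorm(3, 0, 3.5 * pi / 180),
                                   rnorm(K, 0, 0.2 * kapRange))
      if (restarts %% 3L == 2L) {
        # travelling-wave phase locks are a recurring local-minimum family:
        # also try the curvature profile shifted by one control point
        kap <- start[-(1:6)]
        start[-(1:6)] <- if (restarts %% 2L == 0L)
          c(kap[1], kap[-K]) else c(kap[-1], kap[K])
      } else if (restarts %% 3L == 0L) {
        # rebuild the bend from scratch: rigid parameters kept, curvature
        # reset (recovers from runaway curvature oscillations)
        start[-(1:6)] <- 0
      }
      cand <- .runStages(ctx, start, scale, cfg)
      if (cand$value < best$value) best <- cand
    }
    if (best$value > prevObjective * (1 + cfg@restartThreshold))
      flagged <- TRUE
  }
  list(state = vectorToState(best$par, initial@kappaS),
       objective = best$value, coarseObjective = best$coarse,
       restarts = restarts, flagged = flagged)
}

#' Track a complete multi-camera sequence
#'
#' Per-frame pipeline: segment the frames of every camera, predict the
#' state from previous solutions, and fit by two-stage Nelder-Mead with
#' restart logic.
#'
#' @param frames either a synthetic sequence from
#'   \code{\link{syntheticSequence}}, or a list (one element per camera) of
#'   lists of grayscale matrices, or a function(i) returning the list of
#'   per-camera frames for frame i (with \code{nFrames} supplied).
#' @param cams list of \code{\linkS4class{CameraModel}}s.
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param cfg an \code{\linkS4class{ObjectiveConfig}}.
#' @param init first-frame initialisation: a \code{FishState}, or a clicks
#'   list for \code{\link{initializeFirstFrame}}.
#' @param fps frame rate (1/s).
#' @param nFrames number of frames (required for function input).
#' @param segmentThreshold,relThreshold passed to \code{\link{segmentFrame}};
#'   frames that are already logical masks are used as-is.
#' @param verbose print per-frame progress.
#' @return a \code{\linkS4class{TrackResult}}.
#' @export
trackSequence <- function(frames, cams, model, cfg = objectiveConfig(),
                          init, fps = 2000, nFrames = NULL,
                          segmentThreshold = NULL, relThreshold = 0.35,
                          verbose = FALSE) {
  if (is.list(frames) && !is.null(frames$frame)) {
    getFrames <- frames$frame
    nFrames <- frames$nFrames
  } else if (is.function(frames)) {
    stopifnot(!is.null(nFrames))
    getFrames <- frames
  } else {
    nFrames <- length(frames[[1]])
    stopifnot(all(vapply(frames, length, integer(1)) == nFrames))
    getFrames <- function(i) lapply(frames, `[[`, i)
  }
  if (is.list(init) && !is(init, "FishState"))
    init <- initializeFirstFrame(init, cams,
                                 stiffFraction = model@stiffFraction)$state
  pre <- makeDeformer(model, init@kappaS)
  K <- pre$K
  states <- matrix(0, nFrames, 6 + K)
  objv <- numeric(nFrames)
  restarts <- integer(nFrames)
  flagged <- logical(nFrames)
  for (i in seq_len(nFrames)) {
    fr <- getFrames(i)
    masks <- lapply(fr, function(f) {
      if (is.logical(f)) f
      else segmentFrame(f, threshold = segmentThreshold,
                        relThreshold = relThreshold)
    })
    guess <- if (i == 1L) init
             else {
               g <- predictState(states[seq_len(i - 1L), , drop = FALSE])
               # physiological curvature bound guards the prediction
               g[-(1:6)] <- pmin(pmax(g[-(1:6)], -2.5), 2.5)
               vectorToState(g, init@kappaS)
             }
    # restart baseline: best recent objective, allowing a capped per-frame
    # growth of the attainable floor (the silhouette mismatch floor rises
    # legitimately as the body bends)
    base <- if (i == 1L) NULL else {
      j <- max(1L, i - 12L):(i - 1L)
      cfg@baselineGrowth * min(objv[j])
    }
    fit <- fitFrame(guess, masks, cams, NULL, cfg,
                    prevObjective = base, pre = pre)
    # fall back to the previous frame's solution as an alternative start
    if (i > 2L && fit$objective > base * (1 + cfg@restartThreshold)) {
      alt <- fitFrame(vectorToState(states[i - 1L, ], init@kappaS), masks,
                      cams, NULL, cfg, prevObjective = NULL, pre = pre)
      if (alt$objective < fit$objective) {
        alt$restarts <- fit$restarts
        alt$flagged <- alt$objective > base * (1 + cfg@restartThreshold)
        fit <- alt
      }
    }
    states[i, ] <- stateToVector(fit$state)
    objv[i] <- fit$objective
    restarts[i] <- fit$restarts
    flagged[i] <- fit$flagged
    if (verbose)
      message(sprintf("frame %d/%d: f_tot %.0f, restarts %d", i, nFrames,
                      fit$objective, fit$restarts))
  }
  colnames(states) <- c("x", "y", "z", "roll", "pitch", "yaw",
                        paste0("kappa", seq_len(K)))
  new("TrackResult", time = (seq_len(nFrames) - 1) / fps, states = states,
      kappaS = init@kappaS, objective = objv, restarts = restarts,
      flagged = flagged)
}
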