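# Built-in verification experiments: the synthetic swimming-fish motion
# check and its error metrics. These drive both the test suite and the
# acceptance script, regenerating everything in silico.

#' Run the synthetic motion-verification experiment
#'
#' Generates the default swimming sequence (C-start blending into a
#' travelling wave), renders and degrades it through the three-camera rig,
#' and tracks it. The tracker is given a moderately coarser tessellation of
#' the same body model than the renderer uses, as in real use where the
#' model never matches the imaged fish exactly.
#'
#' @param nFrames sequence length (frames at \code{fps}).
#' @param resolution sensor size in px.
#' @param seed RNG seed for the degradation noise and restart draws.
#' @param fps frame rate (1/s).
#' @param cfg tracker settings.
#' @param script motion script.
#' @param target camera aim point (mm).
#' @return list: track (TrackResult), motion (ground truth), cams,
#'   renderModel, trackModel, fps.
#' @export
verificationExperiment <- function(nFrames = 110, resolution = 1024,
                                   seed = 1, fps = 2000,
                                   cfg = objectiveConfig(),
                                   script = defaultMotionScript(),
                                   target = c(-0.5, 0.7, -0.15)) {
  set.seed(seed)
  renderModel <- zebrafishModel()          # P = 40, M = 51
  trackModel <- zebrafishModel(P = 28, M = 35)
  motion <- generateMotion(script, fps, nFrames)
  cams <- rigCameras(resolution, 15, target = target)
  seqd <- syntheticSequence(motion, renderModel, cams,
                            degradationConfig(seed = seed))
  init <- vectorToState(motion$states[1, ], motion$kappaS)
  track <- trackSequence(seqd, cams, trackModel, cfg, init = init,
                         fps = fps)
  list(track = track, motion = motion, cams = cams,
       renderModel = renderModel, trackModel = trackModel, fps = fps)
}

# wrap-safe distance between the tips of two axis-angle rotation vectors
.rotVecDist <- function(R1, R2) {
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

#' Motion-tracking error metrics against ground truth
#'
#' Per-frame snout-position error, polyhedral CoM error (both as % body
#' length), head-orientation error (Euclidean distance between the tips of
#' the reference and tracked axis-angle rotation vectors, degrees), and
#' head-tail angle error (integrated curvature difference, degrees).
#'
#' @param exp result of \code{\link{verificationExperiment}}.
#' @return data.frame with per-frame columns snoutPct, comPct, rotDeg,
#'   headTailDeg.
#' @export
motionErrors <- function(exp) {
  tr <- exp$track
  mot <- exp$motion
  mod <- exp$renderModel
  ell <- mod@length
  pre <- makeDeformer(mod, mot$kappaS)
  n <- nrow(tr@states)
  out <- data.frame(snoutPct = numeric(n), comPct = numeric(n),
                    rotDeg = numeric(n), headTailDeg = numeric(n))
  for (i in seq_len(n)) {
    sv <- tr@states[i, ]
    gt <- mot$states[i, ]
    out$snoutPct[i] <- sqrt(sum((sv[1:3] - gt[1:3])^2)) / ell * 100
    Vt <- deformVertices(pre, sv[-(1:6)], sv[4:6], sv[1:3])
    Vg <- deformVertices(pre, gt[-(1:6)], gt[4:6], gt[1:3])
    ct <- massProperties(Vt, tri = pre$triangles)$com
    cg <- massProperties(Vg, tri = pre$triangles)$com
    out$comPct[i] <- sqrt(sum((ct - cg)^2)) / ell * 100
    out$rotDeg[i] <- .rotVecDist(
      taitBryanMatrix(sv[4], sv[5], sv[6]),
      taitBryanMatrix(gt[4], gt[5], gt[6])) * 180 / pi
    thT <- integrateCenterline(vectorToState(sv, mot$kappaS), ell)$theta
    thG <- integrateCenterline(vectorToState(gt, mot$kappaS), ell)$theta
    out$headTailDeg[i] <-
      abs(thT[length(thT)] - thG[length(thG)]) * 180 / pi
  }
  out
}

#' Inverse-dynamics error metrics against the prescribed reference
#'
#' Runs the full post-processing chain on the tracked states and, as the
#' reference, on the prescribed ground-truth states (the prescribed body
#' shapes fed directly into the inverse-dynamics module), then compares
#' the resultant force and torque series outside the edge-trimmed frames.
#'
#' @param exp result of \code{\link{verificationExperiment}}.
#' @param lambda smoothing weight for the tracked states (NULL = the
#'   cutoff-frequency default of \code{\link{computeDynamics}}).
#' @param trim edge frames excluded at each end.
#' @return list: maxForce_uN, maxTorque_uNmm, per-frame error series and
#'   both DynamicsSeries objects.
#' @export
dynamicsErrors <- function(exp, lambda = NULL, trim = 5) {
  mod <- exp$renderModel
  fps <- exp$fps
  dynT <- computeDynamics(exp$track, mod, fps, lambda = lambda,
                          trim = trim)
  dynR <- computeDynamics(exp$motion$states, mod, fps, lambda = 0,
                          trim = trim, kappaS = exp$motion$kappaS)
  n <- length(dynT@time)
  keep <- (trim + 1):(n - trim)
  fErr <- sqrt(rowSums((dynT@force - dynR@force)^2)) * 1e6     # uN
  tErr <- sqrt(rowSums((dynT@torque - dynR@torque)^2)) * 1e9   # uN mm
  list(maxForce_uN = max(fErr[keep]), maxTorque_uNmm = max(tErr[keep]),
       forceErr_uN = fErr, torqueErr_uNmm = tErr,
       tracked = dynT, reference = dynR, keep = keep)
}
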