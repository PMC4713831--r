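# Synthetic verification experiments, generated entirely in silico:
#  - a simulated swimming larva with exactly known motion (a C-start-like
#    bend blending into a travelling-body-wave swimming mode), rendered to
#    degraded multi-camera shadow images;
#  - a rigid cylinder driven by prescribed forces and torques, integrated
#    forward in time and fed directly into the inverse-dynamics chain.

#' Default motion script for the simulated swimming fish
#'
#' Analytic, twice continuously differentiable functions of time for snout
#' position, head angles and curvature at the control points. The default
#' emulates a 5 mm larva at 2000 fps: a C-start of about 20 ms whose
#' head-tail angle peaks near 170 degrees, blending into a continuous
#' swimming mode with a travelling body wave (35 Hz, wavelength about one
#' body length), with small roll/pitch oscillations and a slight dive.
#' Position is the path integral of an analytic speed and heading; all
#' blends use C2 (or smoother) ramps so reference forces and torques are
#' well defined.
#'
#' @param ell body length (mm).
#' @param cStartDuration C-start duration (s).
#' @param peakHeadTail peak head-tail angle of the C-bend (rad).
#' @param waveFreq tail-beat frequency of the travelling wave (Hz).
#' @param waveLength body-wave wavelength in body lengths.
#' @param waveKappa curvature amplitude of the wave at the tail (1/mm).
#' @param vMax terminal swimming speed (mm/s).
#' @param turnAngle net heading change during the start (rad).
#' @param stiffFraction anterior zero-curvature fraction.
#' @param K number of curvature control points.
#' @return object of class \code{"motionScript"}.
#' @export
defaultMotionScript <- function(ell = 5, cStartDuration = 0.020,
                                peakHeadTail = 170 * pi / 180,
                                waveFreq = 35, waveLength = 1,
                                waveKappa = 0.55, vMax = 80,
                                turnAngle = 50 * pi / 180,
                                stiffFraction = 0.1, K = 7) {
  kappaS <- seq(stiffFraction, 1, length.out = K)
  envC <- function(s) smoothstep5((s - stiffFraction) / 0.5)
  # normalise the C-bend amplitude so the peak head-tail angle is attained
  sFine <- seq(0, 1, length.out = 400)
  envInt <- mean(envC(sFine)) * 1
  kapC <- peakHeadTail / (ell * envInt)
  bump <- function(t, Tc) ifelse(t >= 0 & t <= Tc, sin(pi * t / Tc)^4, 0)
  gw <- function(t) smoothstep5((t - 0.015) / 0.015)   # wave onset ramp
  envW <- function(s) smoothstep5((s - stiffFraction) / 0.4) *
    (0.35 + 0.65 * s^2)
  deg <- pi / 180

  kappaFun <- function(t) {
    kapC * envC(kappaS) * bump(t, cStartDuration) +
      waveKappa * envW(kappaS) *
        sin(2 * pi * (waveFreq * t - kappaS / waveLength)) * gw(t)
  }
  yawFun <- function(t) pi + turnAngle * smoothstep5(t / 0.020) +
    6 * deg * sin(2 * pi * waveFreq * t + 2.2) * gw(t)
  pitchFun <- function(t) -4 * deg * smoothstep5(t / 0.040) +
    2 * deg * sin(2 * pi * waveFreq * t + 0.5) * gw(t)
  rollFun <- function(t) 8 * deg * bump(t, 1.5 * cStartDuration) +
    6 * deg * sin(2 * pi * waveFreq * t + 1.0) * gw(t)
  speedFun <- function(t) vMax * smoothstep5(t / 0.025)
  headingFun <- function(t) yawFun(t) - pi        # facing azimuth
  recoilFun <- function(t) 0.12 * sin(2 * pi * waveFreq * t + 0.8) * gw(t)
  diveFun <- function(t) -0.3 * smoothstep5(t / 0.040)

  structure(list(ell = ell, K = K, kappaS = kappaS,
                 stiffFraction = stiffFraction,
                 kappaFun = kappaFun, yawFun = yawFun, pitchFun = pitchFun,
                 rollFun = rollFun, speedFun = speedFun,
                 headingFun = headingFun, recoilFun = recoilFun,
                 diveFun = diveFun,
                 params = list(cStartDuration = cStartDuration,
                               peakHeadTail = peakHeadTail,
                               waveFreq = waveFreq,
                               waveLength = waveLength,
                               waveKappa = waveKappa, vMax = vMax,
                               turnAngle = turnAngle)),
            class = "motionScript")
}

#' Sample a motion script into ground-truth states
#'
#' Positions are obtained by integrating the script's speed along its
#' heading with a finely oversampled trapezoidal rule (64x the frame rate),
#' then sampling at the frame times; all other parameters are evaluated
#' directly.
#'
#' @param script a \code{\link{defaultMotionScript}}-style object.
#' @param fps frame rate (1/s).
#' @param nFrames number of frames.
#' @return list: states (n x (6 + K) matrix), time, kappaS, script.
#' @export
generateMotion <- function(script, fps = 2000, nFrames = 120) {
  stopifnot(fps > 0, nFrames >= 1)
  time <- (seq_len(nFrames) - 1) / fps
  over <- 64L
  tFine <- seq(0, max(time), length.out = (nFrames - 1L) * over + 1L)
  sp <- rep_len(script$speedFun(tFine), length(tFine))
  hd <- rep_len(script$headingFun(tFine), length(tFine))
  dxf <- sp * cos(hd); dyf <- sp * sin(hd)
  dt <- if (length(tFine) > 1L) tFine[2] - tFine[1] else 0
  cumtrap <- function(v) c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt))
  xs <- cumtrap(dxf)[seq(1, length(tFine), by = over)]
  ys <- cumtrap(dyf)[seq(1, length(tFine), by = over)]
  # lateral recoil acts perpendicular to the heading
  hdF <- rep_len(script$headingFun(time), length(time))
  rec <- rep_len(script$recoilFun(time), length(time))
  states <- matrix(0, nFrames, 6 + script$K)
  for (i in seq_len(nFrames)) {
    t <- time[i]
    states[i, 1] <- xs[i] - rec[i] * sin(hdF[i])
    states[i, 2] <- ys[i] + rec[i] * cos(hdF[i])
    states[i, 3] <- script$diveFun(t)
    states[i, 4] <- script$rollFun(t)
    states[i, 5] <- script$pitchFun(t)
    states[i, 6] <- script$yawFun(t)
    states[i, -(1:6)] <- script$kappaFun(t)
  }
  colnames(states) <- c("x", "y", "z", "roll", "pitch", "yaw",
                        paste0("kappa", seq_len(script$K)))
  list(states = states, time = time, kappaS = script$kappaS,
       script = script)
}

#' Image degradation settings for the synthetic sequences
#'
#' Defaults reproduce the verification imaging chain: Gaussian blur of
#' sigma 1 px, contrast reduced by 45% (output range 0.55 of the input
#' range about the light background), and additive normally distributed
#' noise (sigma 5% of maximum intensity) generated at 10x lower resolution,
#' oversampled (nearest neighbour) to full resolution and Gaussian blurred
#' with sigma 5 px.
#'
#' @param blurSigma silhouette blur in px.
#' @param contrast contrast retention factor (0.55 = 45% reduction).
#' @param noiseSigma noise std as a fraction of maximum intensity.
#' @param noiseDown noise-grid downscale factor.
#' @param noiseBlur noise blur sigma in px.
#' @param seed RNG seed for the noise stream.
#' @export
degradationConfig <- function(blurSigma = 1, contrast = 0.55,
                              noiseSigma = 0.05, noiseDown = 10,
                              noiseBlur = 5, seed = 1L) {
  list(blurSigma = blurSigma, contrast = contrast,
       noiseSigma = noiseSigma, noiseDown = noiseDown,
       noiseBlur = noiseBlur, seed = as.integer(seed))
}

.gblurMat <- function(x, sigma) {
  .gaussBlur(x, sigma)
}

# degrade one clean silhouette mask into a grayscale shadow image
.degradeMask <- function(mask, cfg, noiseSeed) {
  img <- 1 - mask                     # dark fish on light background
  storage.mode(img) <- "double"
  if (cfg$blurSigma > 0) img <- .gblurMat(img, cfg$blurSigma)
  img <- 1 - cfg$contrast * (1 - img)
  if (cfg$noiseSigma > 0) {
    H <- nrow(img); W <- ncol(img)
    hl <- max(2L, round(H / cfg$noiseDown))
    wl <- max(2L, round(W / cfg$noiseDown))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(noiseSeed)
    g <- matrix(rnorm(hl * wl, 0, cfg$noiseSigma), hl, wl)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    ri <- pmin(hl, floor((seq_len(H) - 1) * hl / H) + 1L)
    ci <- pmin(wl, floor((seq_len(W) - 1) * wl / W) + 1L)
    noise <- g[ri, ci]
    if (cfg$noiseBlur > 0) noise <- .gblurMat(noise, cfg$noiseBlur)
    img <- img + noise
  }
  pmin(pmax(img, 0), 1)
}

#' Synthetic multi-camera sequence of a swimming fish
#'
#' Renders the ground-truth states of a motion script through the virtual
#' cameras and degrades the images (blur, contrast reduction, structured
#' background noise). Frames are produced lazily through \code{frame(i)} so
#' long high-resolution sequences never need to be held in memory at once.
#'
#' @param motion output of \code{\link{generateMotion}}.
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param cams list of \code{\linkS4class{CameraModel}}s.
#' @param degrade a \code{\link{degradationConfig}}, or NULL for clean
#'   binary silhouettes.
#' @return list: \code{frame(i)} returning the list of per-camera grayscale
#'   frames for frame i; \code{truth} (the motion object); \code{cams};
#'   \code{nFrames}.
#' @export
syntheticSequence <- function(motion, model, cams, degrade = degradationConfig()) {
  pre <- makeDeformer(model, motion$kappaS)
  n <- nrow(motion$states)
  frame <- function(i) {
    stopifnot(i >= 1, i <= n)
    st <- motion$states[i, ]
    V <- deformVertices(pre, st[-(1:6)], st[4:6], st[1:3])
    mesh <- new("SurfaceMesh", vertices = V, triangles = pre$triangles)
    lapply(seq_along(cams), function(ci) {
      mask <- renderSilhouette(cams[[ci]], mesh)
      mode(mask) <- "numeric"
      if (is.null(degrade)) 1 - mask
      else .degradeMask(mask, degrade,
                        noiseSeed = (degrade$seed %% 10000L) * 200000L +
                          ci * 50000L + i)
    })
  }
  list(frame = frame, truth = motion, cams = cams, nFrames = n, pre = pre)
}

#' Triangulated cylinder mesh
#'
#' Axis along x, centred at the origin, flat end caps closed by vertex
#' fans; watertight and outward oriented.
#'
#' @param diameter,length cylinder dimensions (mm).
#' @param nCirc circumferential points.
#' @param nAxial axial stations.
#' @return a \code{\linkS4class{SurfaceMesh}}.
#' @export
cylinderMesh <- function(diameter = 1.25, length = 5, nCirc = 64,
                         nAxial = 21) {
  r <- diameter / 2
  th <- 2 * pi * (seq_len(nCirc) - 1) / nCirc
  xs <- seq(-length / 2, length / 2, length.out = nAxial)
  V <- matrix(0, 2 + nAxial * nCirc, 3)
  V[1, ] <- c(-length / 2, 0, 0)
  for (i in seq_len(nAxial))
    V[1 + ((i - 1) * nCirc + 1):(i * nCirc), ] <-
      cbind(xs[i], r * cos(th), r * sin(th))
  V[nrow(V), ] <- c(length / 2, 0, 0)
  idx <- function(i, j) 1L + (i - 1L) * nCirc + ((j - 1L) %% nCirc) + 1L
  tris <- NULL
  tris <- matrix(0L, 2L * nCirc * nAxial, 3L)
  rr <- 0L
  for (j in seq_len(nCirc)) {
    rr <- rr + 1L; tris[rr, ] <- c(1L, idx(1L, j + 1L), idx(1L, j))
  }
  for (i in seq_len(nAxial - 1L)) for (j in seq_len(nCirc)) {
    a <- idx(i, j); b <- idx(i, j + 1L)
    cc <- idx(i + 1L, j + 1L); dd <- idx(i + 1L, j)
    tris[rr + 1L, ] <- c(a, b, cc); tris[rr + 2L, ] <- c(a, cc, dd)
    rr <- rr + 2L
  }
  for (j in seq_len(nCirc)) {
    rr <- rr + 1L
    tris[rr, ] <- c(nrow(V), idx(nAxial, j), idx(nAxial, j + 1L))
  }
  mesh <- new("SurfaceMesh", vertices = V, triangles = tris)
  if (.meshSignedVolume(V, tris) < 0)
    mesh@triangles <- tris[, c(1L, 3L, 2L)]
  mesh
}

#' Rigid-cylinder inverse-dynamics experiment
#'
#' Integrates prescribed force and torque profiles forward in time
#' (trapezoidal rule for the translational state, midpoint rule for angular
#' momentum and orientation), applies the resulting rigid transforms to the
#' triangulated cylinder, and returns the mesh sequence together with the
#' reference profiles for direct injection into \code{\link{meshDynamics}}.
#'
#' @param forceFun function(t) -> force vector (N).
#' @param torqueFun function(t) -> torque vector about the CoM (N m).
#' @param fps frame rate (1/s); \code{nFrames} sequence length.
#' @param mesh cylinder mesh (default the 1.25 mm x 5 mm verification
#'   cylinder).
#' @param rho density (kg/m^3).
#' @return list: Varr (n x nv x 3 vertex trajectory, mm), tri, time,
#'   refForce (N), refTorque (N m), mass (kg), mesh.
#' @export
simulateCylinder <- function(forceFun, torqueFun, fps = 2000, nFrames = 100,
                             mesh = cylinderMesh(), rho = 1000) {
  mp <- massProperties(mesh, rho = rho)
  m <- mp$mass
  Ibody <- mp$inertia
  IbodyInv <- solve(Ibody)
  V0 <- sweep(mesh@vertices, 2, mp$com)   # body frame about the CoM
  dt <- 1 / fps
  time <- (seq_len(nFrames) - 1) * dt
  # translation: trapezoidal integration of F/m (SI), positions in m
  acc <- t(vapply(time, function(t) forceFun(t) / m, numeric(3)))
  vel <- apply(acc, 2, function(a)
    c(0, cumsum((a[-1] + a[-length(a)]) / 2 * dt)))
  pos <- apply(vel, 2, function(v)
    c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt)))
  # rotation: midpoint rule on angular momentum and orientation
  Rk <- diag(3)
  Lk <- c(0, 0, 0)
  Varr <- array(0, dim = c(nFrames, nrow(V0), 3))
  Rlist <- vector("list", nFrames)
  for (k in seq_len(nFrames)) {
    Rlist[[k]] <- Rk
    Varr[k, , ] <- sweep(V0 %*% t(Rk), 2, pos[k, ] * 1000, "+")
    if (k < nFrames) {
      tauMid <- torqueFun(time[k] + dt / 2)
      Lmid <- Lk + tauMid * dt / 2
      omegaMid <- drop(Rk %*% IbodyInv %*% crossprod(Rk, Lmid))
      Rk <- rodrigues(omegaMid * dt) %*% Rk
      Lk <- Lk + tauMid * dt
    }
  }
  refForce <- t(vapply(time, forceFun, numeric(3)))
  refTorque <- t(vapply(time, torqueFun, numeric(3)))
  list(Varr = Varr, tri = mesh@triangles, time = time,
       refForce = refForce, refTorque = refTorque, mass = m,
       rotations = Rlist, mesh = mesh)
}

#' Default prescribed profiles for the cylinder experiment
#'
#' Smooth multi-frequency sinusoids at the micro-Newton / micro-Newton-mm
#' scale typical of larval-fish swimming.
#' @return list(forceFun, torqueFun).
#' @export
cylinderProfiles <- function() {
  list(
    forceFun = function(t)
      1e-6 * c(2.0 * sin(2 * pi * 30 * t),
               1.5 * sin(2 * pi * 20 * t + 1.0),
               1.0 * cos(2 * pi * 25 * t)),
    torqueFun = function(t)
      1e-9 * c(2.0 * sin(2 * pi * 25 * t + 0.5),
               3.0 * sin(2 * pi * 35 * t),
               4.0 * sin(2 * pi * 18 * t + 1.2)))
}

#' Resolution variants of the verification rig
#'
#' The same kinematics and camera geometry rendered at several sensor
#' resolutions (default the 512, 1024 and 2048 square sensors of the
#' verification study; the 15 mm field of view is fixed, so pixel scale
#' doubles with each step).
#'
#' @param resolutions vector of sensor sizes in px.
#' @param fovMm field of view (mm).
#' @param target rig aim point (mm).
#' @return named list of camera-rig lists.
#' @export
resolutionVariants <- function(resolutions = c(512, 1024, 2048),
                               fovMm = 15, target = c(-0.5, 0.7, -0.15)) {
  out <- lapply(resolutions, function(r) rigCameras(r, fovMm, target))
  names(out) <- as.character(resolutions)
  out
}

#' Apparent fish length in pixels
#'
#' Renders the straight-pose model through a camera and measures the
#' bounding-box extent of the silhouette along its longest axis, i.e. the
#' number of pixel columns spanned by the fish.
#'
#' @param model a \code{\linkS4class{BodyModel}}.
#' @param cam a \code{\linkS4class{CameraModel}} viewing the fish
#'   broadside (the vertical rig camera works; the fish is posed axis
#'   aligned in the frontal plane).
#' @param state pose used for the measurement (default: straight fish,
#'   axis aligned, at the camera target).
#' @return apparent length in pixels (integer column count).
#' @export
apparentLengthPx <- function(model, cam, state = NULL) {
  if (is.null(state))
    state <- fishState(position = c(-model@length / 2, 0, 0),
                       angles = c(0, 0, 0), kappa = numeric(7),
                       stiffFraction = model@stiffFraction)
  mask <- renderSilhouette(cam, deformAndPose(model, state))
  cols <- which(colSums(mask) > 0)
  rows <- which(rowSums(mask) > 0)
  max(diff(range(cols)) + 1L, diff(range(rows)) + 1L)
}
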