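# Constructors, accessors and show() methods for the core classes.

#' Construct a FishState
#'
#' @param position snout position (x, y, z), mm.
#' @param angles Tait-Bryan head angles (roll, pitch, yaw), rad.
#' @param kappa curvature values at the control points (1/mm).
#' @param kappaS control-point arclength positions; default K equally spaced
#'   points spanning from the stiff-head boundary to the tail tip.
#' @param stiffFraction used only to place the default \code{kappaS}.
#' @return A \code{\linkS4class{FishState}}.
#' @export
fishState <- function(position = c(0, 0, 0), angles = c(0, 0, 0),
                      kappa = numeric(7),
                      kappaS = NULL, stiffFraction = 0.1) {
  if (is.null(kappaS))
    kappaS <- seq(stiffFraction, 1, length.out = length(kappa))
  new("FishState", position = as.numeric(position),
      angles = as.numeric(angles), kappa = as.numeric(kappa),
      kappaS = as.numeric(kappaS))
}

#' Construct an ObjectiveConfig
#'
#' Defaults: \code{c0} scaled so the curvature penalty sits at a few percent
#' of a typical pixel-count misfit for realistic curvature gradients;
#' \code{c1 = 1.5} weights the head about four times more strongly than
#' the tail while still charging enough at the weakly observed tail tip to
#' suppress spurious tail-curvature spikes. The fine simplex tolerance is
#' always \code{coarseTol / 10}.
#' @param c0,c1 weighting function w(s) = c0 exp(-c1 s) of the curvature
#'   gradient penalty.
#' @param restartThreshold max relative frame-to-frame objective increase.
#' @param coarseTol coarse-stage relative tolerance; fine is 10x smaller.
#' @param coarseMaxit iteration cap of each coarse Nelder-Mead pass.
#' @param fineMaxit evaluation cap of the fine-stage adaptive Nelder-Mead.
#' @param polishMaxit evaluation cap of the final binary-objective polish.
#' @param softSigma Gaussian blur sigma (px, at the halved working
#'   resolution) of the graded masks used by the coarse search.
#' @param baselineGrowth restart trigger headroom: a frame whose objective
#'   exceeds baselineGrowth times the best recent objective (last 12
#'   frames) by more than restartThreshold is refit from perturbed starts
#'   (the attainable misfit floor rises as the body bends, hence > 1).
#' @param maxRestarts randomised-restart cap.
#' @export
objectiveConfig <- function(c0 = 40, c1 = 1.5, restartThreshold = 0.25,
                            coarseTol = 1e-3, coarseMaxit = 250,
                            fineMaxit = 1200, polishMaxit = 400,
                            softSigma = 0.75, baselineGrowth = 1.3,
                            maxRestarts = 3) {
  new("ObjectiveConfig", c0 = c0, c1 = c1,
      restartThreshold = restartThreshold,
      coarseTol = coarseTol, fineTol = coarseTol / 10,
      coarseMaxit = coarseMaxit, fineMaxit = fineMaxit,
      polishMaxit = polishMaxit, softSigma = softSigma,
      baselineGrowth = baselineGrowth, maxRestarts = maxRestarts)
}

#' @rdname vertices
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname vertices
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' Mesh accessors
#'
#' @param x a \code{\linkS4class{SurfaceMesh}}.
#' @return \code{vertices}: n x 3 matrix (mm); \code{triangles}: m x 3
#'   integer matrix of 1-based indices.
#' @aliases vertices triangles
#' @name vertices
#' @export
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname vertices
#' @export
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)

#' @rdname stateMatrix
#' @export
setGeneric("stateMatrix", function(x) standardGeneric("stateMatrix"))

#' Extract the per-frame state matrix
#'
#' @param x a \code{\linkS4class{TrackResult}} or
#'   \code{\linkS4class{DynamicsSeries}}.
#' @return numeric matrix n x (6 + K) with columns x, y, z, roll, pitch,
#'   yaw, kappa_1..kappa_K.
#' @name stateMatrix
#' @export
setMethod("stateMatrix", "TrackResult", function(x) x@states)
#' @rdname stateMatrix
#' @export
setMethod("stateMatrix", "DynamicsSeries", function(x) x@states)

#' @rdname comSeries
#' @export
setGeneric("comSeries", function(x) standardGeneric("comSeries"))
#' @rdname comSeries
#' @export
setGeneric("forceSeries", function(x, frame = c("world", "fish"))
  standardGeneric("forceSeries"))
#' @rdname comSeries
#' @export
setGeneric("torqueSeries", function(x, frame = c("world", "fish"))
  standardGeneric("torqueSeries"))

#' Dynamics accessors
#'
#' @param x a \code{\linkS4class{DynamicsSeries}}.
#' @param frame \code{"world"} or \code{"fish"} coordinate frame.
#' @return \code{comSeries}: n x 3 CoM positions (mm); \code{forceSeries}:
#'   n x 3 resultant force (N); \code{torqueSeries}: n x 3 resultant torque
#'   (N m).
#' @name comSeries
#' @export
setMethod("comSeries", "DynamicsSeries", function(x) x@com)
#' @rdname comSeries
#' @export
setMethod("forceSeries", "DynamicsSeries", function(x, frame = c("world", "fish")) {
  if (match.arg(frame) == "world") x@force else x@forceFish
})
#' @rdname comSeries
#' @export
setMethod("torqueSeries", "DynamicsSeries", function(x, frame = c("world", "fish")) {
  if (match.arg(frame) == "world") x@torque else x@torqueFish
})

#' Convert a FishState to / from a parameter vector
#'
#' The flat layout x, y, z, roll, pitch, yaw, kappa_1..kappa_K is the vector
#' the optimiser marches and the row format of the kinematics CSV.
#' @param state a \code{FishState}.
#' @export
stateToVector <- function(state) {
  c(state@position, state@angles, state@kappa)
}

#' @rdname stateToVector
#' @param v numeric vector of length 6 + K.
#' @param kappaS control-point positions of the reconstructed state.
#' @export
vectorToState <- function(v, kappaS) {
  new("FishState", position = v[1:3], angles = v[4:6],
      kappa = v[-(1:6)], kappaS = kappaS)
}

setMethod("show", "BodyModel", function(object) {
  d <- dim(object@sections)
  cat(sprintf("BodyModel: %d sections x %d circumferential points, length %.3g mm, stiff head %.0f%%\n",
              d[3], d[1], object@length, 100 * object@stiffFraction))
})

setMethod("show", "FishState", function(object) {
  cat(sprintf("FishState: snout (%.3g, %.3g, %.3g) mm, rpy (%.3g, %.3g, %.3g) rad, %d curvature control points\n",
              object@position[1], object@position[2], object@position[3],
              object@angles[1], object@angles[2], object@angles[3],
              length(object@kappa)))
})

setMethod("show", "SurfaceMesh", function(object) {
  cat(sprintf("SurfaceMesh: %d vertices, %d triangles\n",
              nrow(object@vertices), nrow(object@triangles)))
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel '%s': %s, %d x %d px\n", object@id, object@type,
              object@imageSize[1], object@imageSize[2]))
})

setMethod("show", "TrackResult", function(object) {
  cat(sprintf("TrackResult: %d frames, %d flagged, median objective %.4g\n",
              nrow(object@states), sum(object@flagged),
              median(object@objective)))
})

setMethod("show", "DynamicsSeries", function(object) {
  cat(sprintf("DynamicsSeries: %d frames, mass %.4g kg, edge trim %d frames\n",
              length(object@time), object@mass, object@trim))
})
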