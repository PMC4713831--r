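#' @import methods
#' @importFrom stats optim approx rnorm runif quantile median sd
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib fishtrack3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' BodyModel: undeformed 3D surface model of a fish
#'
#' A longitudinal series of merged cross-section contours describing the
#' straight-pose outer surface. Each of the \code{M} sections is a closed
#' contour of exactly \code{P} circumferential points in its local section
#' plane (lateral \code{y}, dorsal \code{z}; mm), sampled at the same
#' canonical ray angles (start dorsal, counter-clockwise seen from the
#' snout), so corresponding points connect into quadrilateral faces. The
#' terminal sections collapse to single points so the triangulated surface
#' is watertight.
#'
#' @slot sections numeric array \code{P x 2 x M} of local (y, z) contour
#'   coordinates in mm.
#' @slot sValues normalised arclength of each section, strictly increasing
#'   in [0, 1] (0 = snout tip, 1 = tail tip).
#' @slot length reference body length in mm.
#' @slot stiffFraction anterior fraction of the body with curvature pinned
#'   to zero (default 0.10).
#' @export
setClass("BodyModel",
  representation(sections = "array", sValues = "numeric",
                 length = "numeric", stiffFraction = "numeric"),
  validity = function(object) {
    d <- dim(object@sections)
    if (length(d) != 3L || d[2] != 2L)
      return("sections must be a P x 2 x M array")
    if (d[1] < 16L) return("P must be >= 16")
    if (d[3] < 20L) return("M must be >= 20")
    if (length(object@sValues) != d[3])
      return("sValues length must equal the number of sections")
    if (any(diff(object@sValues) <= 0) || object@sValues[1] < 0 ||
        object@sValues[length(object@sValues)] > 1)
      return("sValues must be strictly increasing within [0, 1]")
    if (object@length <= 0) return("body length must be positive")
    if (object@stiffFraction < 0 || object@stiffFraction >= 1)
      return("stiffFraction must be in [0, 1)")
    TRUE
  })

#' FishState: pose and deformation parameters for one frame
#'
#' Houses the full parameter vector of the tracker: snout-tip position,
#' Tait-Bryan head angles and curvature values at the midline control
#' points. Curvature is interpolated to the body-model stations with a
#' natural cubic spline and forced to zero over the stiff head fraction.
#'
#' @slot position snout-tip position (x, y, z) in mm, world frame.
#' @slot angles Tait-Bryan head angles (roll, pitch, yaw) in radians.
#' @slot kappa curvature (1/mm) at the K control points.
#' @slot kappaS normalised arclength positions of the control points.
#' @export
setClass("FishState",
  representation(position = "numeric", angles = "numeric",
                 kappa = "numeric", kappaS = "numeric"),
  validity = function(object) {
    if (length(object@position) != 3L) return("position must have length 3")
    if (length(object@angles) != 3L) return("angles must have length 3")
    if (length(object@kappa) < 3L) return("need at least 3 curvature control points")
    if (length(object@kappaS) != length(object@kappa))
      return("kappaS must match kappa in length")
    if (any(diff(object@kappaS) <= 0))
      return("kappaS must be strictly increasing")
    if (any(!is.finite(c(object@position, object@angles, object@kappa))))
      return("state parameters must be finite")
    TRUE
  })

#' SurfaceMesh: triangulated closed surface
#'
#' @slot vertices numeric matrix n x 3 (mm).
#' @slot triangles integer matrix m x 3 of 1-based vertex indices with
#'   consistent outward orientation.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix"),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
    if (ncol(object@triangles) != 3L) return("triangles must be m x 3")
    if (min(object@triangles) < 1L ||
        max(object@triangles) > nrow(object@vertices))
      return("triangle indices out of range")
    TRUE
  })

#' CameraModel: calibrated virtual pinhole or parallel-projection camera
#'
#' Maps world points (mm) to continuous pixel coordinates with origin at the
#' image top-left, x rightward, y downward. The orthographic model matches
#' collimated-light shadow imaging (magnification independent of depth);
#' a perspective model is available via \code{type = "perspective"}.
#'
#' @slot type \code{"orthographic"} or \code{"perspective"}.
#' @slot imageSize c(W, H) in pixels.
#' @slot focal c(fx, fy): px/mm for orthographic, focal length in px for
#'   perspective.
#' @slot principal c(cx, cy) principal point in px.
#' @slot R 3x3 rotation, world to camera.
#' @slot t translation (mm), world to camera: Xcam = R Xworld + t.
#' @slot id camera identifier.
#' @export
setClass("CameraModel",
  representation(type = "character", imageSize = "numeric",
                 focal = "numeric", principal = "numeric",
                 R = "matrix", t = "numeric", id = "character"),
  validity = function(object) {
    if (!object@type %in% c("orthographic", "perspective"))
      return("type must be 'orthographic' or 'perspective'")
    if (any(object@imageSize <= 0)) return("image size must be positive")
    E <- crossprod(object@R) - diag(3)
    if (max(abs(E)) > 1e-10) return("rotation must be orthonormal (1e-10)")
    if (length(object@t) != 3L) return("t must have length 3")
    TRUE
  })

#' ObjectiveConfig: tracker objective and optimiser settings
#'
#' @slot c0 regularisation amplitude (px^2 units so the curvature penalty is
#'   commensurate with the pixel-count goodness of fit).
#' @slot c1 decay rate of the head-weighted penalty w(s) = c0 exp(-c1 s).
#' @slot restartThreshold maximum allowed relative increase of the objective
#'   between consecutive frames before randomised restarts are attempted.
#' @slot coarseTol,fineTol relative simplex tolerances of the two
#'   Nelder-Mead stages; fine is one tenth of coarse.
#' @slot coarseMaxit,fineMaxit iteration caps of the two stages.
#' @slot polishMaxit evaluation cap of the final binary-objective polish.
#' @slot softSigma Gaussian sigma (px, at half resolution) of the graded
#'   silhouette masks used by the coarse search.
#' @slot baselineGrowth headroom factor of the restart baseline over the
#'   best recent objective.
#' @slot maxRestarts randomised-restart cap per frame.
#' @export
setClass("ObjectiveConfig",
  representation(c0 = "numeric", c1 = "numeric",
                 restartThreshold = "numeric",
                 coarseTol = "numeric", fineTol = "numeric",
                 coarseMaxit = "numeric", fineMaxit = "numeric",
                 polishMaxit = "numeric", softSigma = "numeric",
                 baselineGrowth = "numeric", maxRestarts = "numeric"),
  validity = function(object) {
    if (object@c0 < 0) return("c0 must be >= 0")
    if (object@c1 <= 0) return("c1 must be > 0")
    if (abs(object@fineTol - object@coarseTol / 10) >
        1e-12 * object@coarseTol)
      return("fine tolerance must be coarse / 10")
    TRUE
  })

#' TrackResult: fitted states for a video sequence
#'
#' @slot time frame times (s).
#' @slot states numeric matrix n x (6 + K): x, y, z, roll, pitch, yaw,
#'   kappa_1..kappa_K.
#' @slot kappaS control-point positions shared by all frames.
#' @slot objective final objective value per frame.
#' @slot restarts randomised-restart count per frame.
#' @slot flagged frames whose restart cap was exhausted.
#' @export
setClass("TrackResult",
  representation(time = "numeric", states = "matrix", kappaS = "numeric",
                 objective = "numeric", restarts = "integer",
                 flagged = "logical"),
  validity = function(object) {
    n <- nrow(object@states)
    if (length(object@time) != n || length(object@objective) != n ||
        length(object@restarts) != n || length(object@flagged) != n)
      return("per-frame slots must have one entry per frame")
    if (any(!is.finite(object@objective)))
      return("objective values must be finite")
    TRUE
  })

#' DynamicsSeries: smoothed kinematics and inverse-dynamics output
#'
#' All geometric quantities are stored in the units they are reported in:
#' positions mm, mass kg, force N, angular momentum kg m^2/s, torque N m.
#' The first and last \code{trim} frames have reduced accuracy from
#' smoothing/differentiation edge effects and are flagged.
#'
#' @slot time frame times (s).
#' @slot states smoothed state matrix (as in \code{TrackResult}).
#' @slot com,vcom,acom n x 3 CoM position (mm), velocity (mm/s),
#'   acceleration (mm/s^2).
#' @slot mass body mass (kg).
#' @slot force n x 3 resultant force (N), world frame.
#' @slot forceFish n x 3 force in the fish frame; \code{forward} its
#'   component along the CoM velocity direction.
#' @slot L n x 3 angular momentum about the CoM (kg m^2/s).
#' @slot torque,torqueFish n x 3 resultant torque (N m), world and fish frame.
#' @slot axes 3 x 3 x n fish-frame axes (columns x_fish, y_fish, z_fish).
#' @slot lambda smoothing parameter(s) used per state column.
#' @slot trim number of edge frames flagged at each end.
#' @export
setClass("DynamicsSeries",
  representation(time = "numeric", states = "matrix", com = "matrix",
                 vcom = "matrix", acom = "matrix", mass = "numeric",
                 force = "matrix", forceFish = "matrix", forward = "numeric",
                 L = "matrix", torque = "matrix", torqueFish = "matrix",
                 axes = "array", lambda = "numeric", trim = "numeric"),
  validity = function(object) {
    n <- length(object@time)
    mats <- list(object@com, object@vcom, object@acom, object@force,
                 object@L, object@torque)
    for (m in mats) if (nrow(m) != n || ncol(m) != 3L)
      return("per-frame 3-vector series must be n x 3")
    if (object@mass <= 0) return("mass must be positive")
    TRUE
  })
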