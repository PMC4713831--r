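# Projection: calibrated virtual cameras and silhouette rendering.
#
# The default camera is orthographic (parallel projection): the imaging rig
# this emulates uses collimated back-light, making magnification independent
# of depth. A standard pinhole (perspective) model is available as well.

#' Construct a CameraModel
#'
#' @param type "orthographic" (default) or "perspective".
#' @param imageSize c(W, H) pixels.
#' @param focal c(fx, fy): px/mm scale for orthographic cameras, focal
#'   length in px for perspective. A scalar is recycled.
#' @param principal principal point (cx, cy) in px; defaults to the image
#'   centre.
#' @param R 3x3 world-to-camera rotation (camera axes: x image-right,
#'   y image-down, z viewing direction).
#' @param t world-to-camera translation (mm): Xcam = R Xworld + t.
#' @param id camera identifier.
#' @return A \code{\linkS4class{CameraModel}}.
#' @export
cameraModel <- function(type = c("orthographic", "perspective"),
                        imageSize = c(1024, 1024), focal = 1,
                        principal = imageSize / 2, R = diag(3),
                        t = c(0, 0, 0), id = "cam") {
  type <- match.arg(type)
  if (length(focal) == 1L) focal <- rep(focal, 2L)
  new("CameraModel", type = type, imageSize = as.numeric(imageSize),
      focal = as.numeric(focal), principal = as.numeric(principal),
      R = R, t = as.numeric(t), id = id)
}

# world-to-camera rotation looking along viewDir with an up hint
.lookRotation <- function(viewDir, upHint = c(0, 0, 1)) {
  z <- viewDir / sqrt(sum(viewDir^2))
  yp <- -(upHint - sum(upHint * z) * z)
  ny <- sqrt(sum(yp^2))
  if (ny < 1e-9) stop("up hint parallel to the viewing direction")
  y <- yp / ny
  x <- c(y[2] * z[3] - y[3] * z[2],
         y[3] * z[1] - y[1] * z[3],
         y[1] * z[2] - y[2] * z[1])
  rbind(x, y, z, deparse.level = 0)
}

#' Build a camera looking at a target point
#'
#' @param eye camera position (mm).
#' @param target point the optical axis passes through (mm).
#' @param imageSize c(W, H) px.
#' @param fovMm field-of-view width in mm (orthographic scale =
#'   imageSize[1] / fovMm px/mm).
#' @param type camera model type.
#' @param upHint approximate image-up direction in world coordinates.
#' @param id camera identifier.
#' @export
lookAtCamera <- function(eye, target, imageSize = c(1024, 1024),
                         fovMm = 15, type = "orthographic",
                         upHint = c(0, 0, 1), id = "cam") {
  R <- .lookRotation(target - eye, upHint)
  t <- -drop(R %*% eye)
  scale <- imageSize[1] / fovMm
  cameraModel(type = type, imageSize = imageSize, focal = scale,
              principal = imageSize / 2, R = R, t = t, id = id)
}

#' The three-camera verification rig
#'
#' One vertical camera looking straight down and left/right cameras at 30
#' degrees to horizontal (azimuth +-90 degrees), all aimed at \code{target},
#' matching the geometry of the experimental setup the synthetic sequences
#' emulate (15 x 15 mm field of view by default).
#'
#' @param resolution image width/height in px (square sensors).
#' @param fovMm field of view in mm.
#' @param target aim point (mm).
#' @param distance camera distance from the target (mm; irrelevant for the
#'   orthographic projection itself but kept for realistic geometry).
#' @return list of three \code{\linkS4class{CameraModel}}s.
#' @export
rigCameras <- function(resolution = 1024, fovMm = 15,
                       target = c(0, 0, 0), distance = 100) {
  el <- 30 * pi / 180
  list(
    lookAtCamera(target + c(0, 0, distance), target,
                 imageSize = c(resolution, resolution), fovMm = fovMm,
                 upHint = c(0, 1, 0), id = "top"),
    lookAtCamera(target + c(0, distance * cos(el), distance * sin(el)),
                 target, imageSize = c(resolution, resolution),
                 fovMm = fovMm, id = "left"),
    lookAtCamera(target + c(0, -distance * cos(el), distance * sin(el)),
                 target, imageSize = c(resolution, resolution),
                 fovMm = fovMm, id = "right"))
}

#' Project world points to pixel coordinates
#'
#' Continuous pixel coordinates, origin at the image top-left, x rightward,
#' y downward.
#'
#' @param cam a \code{\linkS4class{CameraModel}}.
#' @param points n x 3 matrix (mm).
#' @return n x 2 matrix of pixel coordinates.
#' @export
projectPoints <- function(cam, points) {
  if (any(!is.finite(points))) stop("points must be finite")
  Xc <- points %*% t(cam@R)
  Xc[, 1] <- Xc[, 1] + cam@t[1]
  Xc[, 2] <- Xc[, 2] + cam@t[2]
  Xc[, 3] <- Xc[, 3] + cam@t[3]
  if (cam@type == "orthographic") {
    cbind(cam@focal[1] * Xc[, 1] + cam@principal[1],
          cam@focal[2] * Xc[, 2] + cam@principal[2])
  } else {
    if (any(Xc[, 3] <= 0))
      stop("point behind perspective camera")
    cbind(cam@focal[1] * Xc[, 1] / Xc[, 3] + cam@principal[1],
          cam@focal[2] * Xc[, 2] / Xc[, 3] + cam@principal[2])
  }
}

#' Render a binary silhouette of a mesh
#'
#' A pixel is set iff its centre falls inside at least one projected, filled
#' triangle of the mesh.
#'
#' @param cam a \code{\linkS4class{CameraModel}}.
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @return H x W logical matrix (rows = image rows).
#' @export
renderSilhouette <- function(cam, mesh) {
  uv <- projectPoints(cam, mesh@vertices)
  .rasterTriangles(uv[, 1], uv[, 2], mesh@triangles,
                   as.integer(cam@imageSize[1]),
                   as.integer(cam@imageSize[2]))
}

#' Read / write camera calibration files
#'
#' Plain-text (YAML) calibration: per camera the model type, image size,
#' focal/scale, principal point, 3x3 rotation (row-major) and translation.
#' The loader validates rotation orthonormality via the class validity.
#'
#' @param path file path.
#' @return list of \code{\linkS4class{CameraModel}}s.
#' @export
readCameras <- function(path) {
  doc <- yaml::read_yaml(path)
  lapply(doc$cameras, function(cc)
    cameraModel(type = cc$type, imageSize = unlist(cc$image_size),
                focal = unlist(cc$focal), principal = unlist(cc$principal),
                R = matrix(unlist(cc$rotation), 3, 3, byrow = TRUE),
                t = unlist(cc$translation), id = cc$id))
}

#' @rdname readCameras
#' @param cams list of \code{\linkS4class{CameraModel}}s.
#' @export
writeCameras <- function(cams, path) {
  doc <- list(cameras = lapply(cams, function(cm) list(
    id = cm@id, type = cm@type, image_size = cm@imageSize,
    focal = cm@focal, principal = cm@principal,
    rotation = as.vector(t(cm@R)), translation = cm@t)))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
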