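# Frame stacks, result files, run configuration and the end-to-end
# pipeline: segment -> track -> smooth -> inverse dynamics.

#' Load a frame stack from a directory
#'
#' Reads numbered grayscale TIFF/PNG frames, sorted by filename, normalised
#' to [0, 1].
#'
#' @param dir directory containing the frames.
#' @param pattern filename glob-ish regular expression (default matches
#'   .png/.tif/.tiff).
#' @return list of grayscale matrices.
#' @export
loadFrames <- function(dir, pattern = "\\.(png|tif|tiff)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames found in ", dir)
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE))
      png::readPNG(f) else tiff::readTIFF(f)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"),
                 character(1))
  if (length(unique(dims)) != 1L)
    stop("frames have mixed sizes: ", paste(unique(dims), collapse = ", "))
  frames
}

#' Write a silhouette mask as 8-bit PNG
#'
#' Background pixels 0, fish pixels 255.
#' @param mask logical matrix.
#' @param path output path.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write tracking and dynamics results
#'
#' Writes the kinematics CSV (one row per frame: t, x, y, z, roll, pitch,
#' yaw, kappa_1..K, objective, restarts, flag), the dynamics CSV (CoM,
#' velocity, acceleration, force in world/fish/forward components, angular
#' momentum, torque in world/fish components, edge flag) and a metadata
#' JSON (package version, smoothing weights, density, edge trim, seed).
#'
#' @param track a \code{\linkS4class{TrackResult}}.
#' @param dyn a \code{\linkS4class{DynamicsSeries}} (or NULL to skip).
#' @param outDir output directory (created if missing).
#' @param meta named list merged into the metadata JSON.
#' @return invisibly, the paths written.
#' @export
writeResults <- function(track, dyn, outDir, meta = list()) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  kin <- data.frame(t = track@time, track@states,
                    objective = track@objective,
                    restarts = track@restarts,
                    flag = ifelse(track@flagged, "FLAGGED", ""))
  kinPath <- file.path(outDir, "kinematics.csv")
  write.csv(kin, kinPath, row.names = FALSE)
  paths <- c(paths, kinPath)
  if (!is.null(dyn)) {
    n <- length(dyn@time)
    edge <- seq_len(n) <= dyn@trim | seq_len(n) > n - dyn@trim
    dynDf <- data.frame(t = dyn@time,
                        com_x = dyn@com[, 1], com_y = dyn@com[, 2],
                        com_z = dyn@com[, 3],
                        vcom_x = dyn@vcom[, 1], vcom_y = dyn@vcom[, 2],
                        vcom_z = dyn@vcom[, 3],
                        acom_x = dyn@acom[, 1], acom_y = dyn@acom[, 2],
                        acom_z = dyn@acom[, 3],
                        F_x = dyn@force[, 1], F_y = dyn@force[, 2],
                        F_z = dyn@force[, 3],
                        F_fish_x = dyn@forceFish[, 1],
                        F_fish_y = dyn@forceFish[, 2],
                        F_fish_z = dyn@forceFish[, 3],
                        F_forward = dyn@forward,
                        L_x = dyn@L[, 1], L_y = dyn@L[, 2],
                        L_z = dyn@L[, 3],
                        tau_x = dyn@torque[, 1], tau_y = dyn@torque[, 2],
                        tau_z = dyn@torque[, 3],
                        tau_fish_x = dyn@torqueFish[, 1],
                        tau_fish_y = dyn@torqueFish[, 2],
                        tau_fish_z = dyn@torqueFish[, 3],
                        edge_flag = ifelse(edge, "EDGE", ""))
    dynPath <- file.path(outDir, "dynamics.csv")
    write.csv(dynDf, dynPath, row.names = FALSE)
    paths <- c(paths, dynPath)
  }
  metaAll <- c(list(package = "fishtrack3d",
                    version = as.character(utils::packageVersion("fishtrack3d")),
                    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
               if (!is.null(dyn)) list(lambda = dyn@lambda,
                                       trim = dyn@trim,
                                       mass_kg = dyn@mass),
               meta)
  metaPath <- file.path(outDir, "metadata.json")
  jsonlite::write_json(metaAll, metaPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, metaPath))
}

#' Read back a kinematics CSV as a TrackResult
#' @param path kinematics CSV written by \code{\link{writeResults}}.
#' @param kappaS control-point positions.
#' @export
readTrackResult <- function(path, kappaS = seq(0.1, 1, length.out = 7)) {
  df <- read.csv(path)
  kcols <- grep("^kappa", names(df))
  new("TrackResult", time = df$t,
      states = as.matrix(df[, c(2:7, kcols)]),
      kappaS = kappaS, objective = df$objective,
      restarts = as.integer(df$restarts),
      flagged = df$flag == "FLAGGED")
}

#' Load a run configuration file
#'
#' YAML with paths (frame directories per camera, calibration file, body
#' model spec), sub-configuration blocks (segmentation, objective,
#' smoother), a seed and the frame rate. Referenced paths are checked at
#' load time.
#'
#' @param path YAML config path.
#' @return named list with an \code{objective} entry already turned into
#'   an \code{\linkS4class{ObjectiveConfig}}.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (p in c(cfg$paths$frames, cfg$paths$cameras, cfg$paths$model)) {
    if (!is.null(p) && !file.exists(p))
      stop("configured path does not exist: ", p)
  }
  ob <- cfg$objective
  cfg$objective <- do.call(objectiveConfig, if (is.null(ob)) list() else ob)
  if (is.null(cfg$fps)) cfg$fps <- 2000
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

#' Run the full tracking + inverse-dynamics pipeline
#'
#' Stages: load and segment frames, track the sequence, smooth and
#' post-process into forces and torques, and write all outputs. Stage
#' failures abort with a stage-named error.
#'
#' @param cfg list from \code{\link{readRunConfig}} (or an equivalent
#'   hand-built list).
#' @return invisibly, the output paths.
#' @export
runPipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  set.seed(cfg$seed)
  cams <- stage("calibration", readCameras(cfg$paths$cameras))
  spec <- stage("model", readBodySpec(cfg$paths$model))
  model <- stage("model", buildBodyModel(spec$specs, length = spec$length,
                                         stiffFraction = spec$stiff_fraction))
  frames <- stage("frames",
                  lapply(cfg$paths$frames, loadFrames))
  init <- stage("init", {
    cl <- cfg$init_clicks
    if (is.null(cl)) stop("config must provide init_clicks")
    lapply(cl, function(x) list(snout = unlist(x$snout),
                                tail = unlist(x$tail)))
  })
  track <- stage("track",
                 trackSequence(frames, cams, model, cfg$objective,
                               init = init, fps = cfg$fps,
                               segmentThreshold = cfg$segmentation$threshold,
                               relThreshold =
                                 if (is.null(cfg$segmentation$rel_threshold))
                                   0.35 else cfg$segmentation$rel_threshold))
  lambda <- cfg$smoother$lambda   # NULL = bandwidth-based default
  dyn <- stage("dynamics",
               computeDynamics(track, model, cfg$fps, lambda = lambda))
  stage("write", writeResults(track, dyn, cfg$paths$out,
                              meta = list(seed = cfg$seed, fps = cfg$fps)))
}
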