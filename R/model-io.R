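# Body-model spec files and mesh export.
#
# The digitised morphology travels as a plain-text (YAML) spec: one record
# per cross-section with the trunk spline control points and the optional
# eye-superellipse / fin-fold-ellipse parameters. The shipped zebrafish
# fixture (inst/extdata/zebrafish_larva_synthetic.yaml) is a synthetic
# stand-in whose proportions follow a 5 mm larva.

#' Read / write a body-model spec file
#'
#' @param path file path.
#' @return \code{readBodySpec}: list with \code{name}, \code{length},
#'   \code{stiff_fraction} and \code{specs} (a list of
#'   \code{\link{crossSectionSpec}} records).
#' @export
readBodySpec <- function(path) {
  doc <- yaml::read_yaml(path)
  specs <- lapply(doc$sections, function(sec) {
    eye <- if (!is.null(sec$eye)) sec$eye
    fin <- if (!is.null(sec$finfold)) sec$finfold
    crossSectionSpec(sec$s, unlist(sec$trunk_y), unlist(sec$trunk_z),
                     eye = eye, finfold = fin)
  })
  list(name = doc$name, length = doc$length,
       stiff_fraction = doc$stiff_fraction, specs = specs)
}

#' @rdname readBodySpec
#' @param name model name.
#' @param length body length (mm).
#' @param stiffFraction anterior zero-curvature fraction.
#' @param specs list of \code{\link{crossSectionSpec}} records.
#' @export
writeBodySpec <- function(path, name, length, stiffFraction, specs) {
  doc <- list(name = name, length = length,
              stiff_fraction = stiffFraction,
              sections = lapply(specs, function(x) {
                rec <- list(s = x$s, trunk_y = x$trunkY, trunk_z = x$trunkZ)
                if (!is.null(x$eye)) rec$eye <- x$eye
                if (!is.null(x$finfold)) rec$finfold <- x$finfold
                rec
              }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Load the shipped synthetic zebrafish body model
#'
#' @param P,M circumferential / longitudinal resolution.
#' @return A \code{\linkS4class{BodyModel}}.
#' @export
zebrafishModel <- function(P = 40, M = 51) {
  path <- system.file("extdata", "zebrafish_larva_synthetic.yaml",
                      package = "fishtrack3d")
  spec <- readBodySpec(path)
  buildBodyModel(spec$specs, length = spec$length, P = P, M = M,
                 stiffFraction = spec$stiff_fraction)
}

#' Export a mesh as Wavefront OBJ
#'
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @param path output path.
#' @export
writeMeshOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- mesh@vertices
  writeLines(sprintf("v %.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  Tm <- mesh@triangles
  writeLines(sprintf("f %d %d %d", Tm[, 1], Tm[, 2], Tm[, 3]), con)
  invisible(path)
}

#' Watertightness check
#'
#' A triangulated surface is watertight when every undirected edge is shared
#' by exactly two triangles (and orientations are consistent: each edge
#' appears once per direction).
#' @param mesh a \code{\linkS4class{SurfaceMesh}}.
#' @return TRUE/FALSE.
#' @export
isWatertight <- function(mesh) {
  Tm <- mesh@triangles
  e <- rbind(Tm[, c(1, 2)], Tm[, c(2, 3)], Tm[, c(3, 1)])
  keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  if (!all(table(keys) == 2L)) return(FALSE)
  # consistent orientation: every directed edge appears exactly once
  !anyDuplicated(paste(e[, 1], e[, 2]))
}
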