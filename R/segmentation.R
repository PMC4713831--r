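# Segmentation of raw grayscale frames into binary fish silhouettes:
# illumination correction, spatial-gradient thresholding, hole filling and
# largest-component selection. Intensity thresholding is deliberately
# avoided: translucent larval fins have almost no grayscale contrast to the
# background, but their edges still carry gradient.

#' Correct a sequence for light-source intensity fluctuations
#'
#' Computes the average background intensity of every frame over a fish-free
#' region, normalises it by its maximum over the sequence, and divides each
#' frame by its factor, equalising per-frame background levels.
#'
#' @param frames list of grayscale matrices in [0, 1].
#' @param backgroundRegion logical mask (same size as the frames) or a
#'   rectangle c(row1, row2, col1, col2) that stays fish-free.
#' @return list of corrected frames.
#' @export
correctIllumination <- function(frames, backgroundRegion) {
  stopifnot(length(frames) >= 1L)
  if (is.numeric(backgroundRegion) && length(backgroundRegion) == 4L) {
    r <- backgroundRegion
    sel <- function(f) f[r[1]:r[2], r[3]:r[4]]
  } else if (is.logical(backgroundRegion)) {
    if (!any(backgroundRegion)) stop("background region is empty")
    sel <- function(f) f[backgroundRegion]
  } else stop("backgroundRegion must be a rectangle or logical mask")
  bg <- vapply(frames, function(f) mean(sel(f)), numeric(1))
  if (any(!is.finite(bg)) || length(bg) == 0L)
    stop("background region is empty")
  fac <- bg / max(bg)
  mapply(function(f, g) f / g, frames, fac, SIMPLIFY = FALSE)
}

# Sobel gradient magnitude (compiled separable kernel)
.gradientMagnitude <- function(x) {
  .sobelMagnitude(x)
}

#' Segment a fish silhouette from a grayscale frame
#'
#' Thresholds the magnitude of the spatial gradient (Sobel), fills all
#' holes, and keeps the largest connected component. With
#' \code{threshold = NULL} the threshold is \code{relThreshold} times the
#' robust maximum gradient (99.9th percentile), making the segmentation
#' invariant to global affine intensity rescaling.
#'
#' @param frame grayscale matrix in [0, 1].
#' @param threshold absolute gradient threshold (> 0), or NULL to use the
#'   relative rule.
#' @param relThreshold fraction of the robust maximum gradient used when
#'   \code{threshold} is NULL.
#' @param erode radius (px) of a final morphological erosion compensating
#'   the half-width of the suprathreshold edge band, which otherwise
#'   dilates the silhouette by 1-2 px; 0 disables.
#' @param exclude optional logical mask of pixels to ignore (e.g. other
#'   fish); best-effort occlusion handling.
#' @return logical silhouette mask (TRUE = fish).
#' @export
segmentFrame <- function(frame, threshold = NULL, relThreshold = 0.35,
                         erode = 2, exclude = NULL) {
  mag <- .gradientMagnitude(frame)
  if (is.null(threshold)) {
    # robust max: 99.9th percentile via a partial sort
    k <- max(1L, ceiling(0.999 * length(mag)))
    threshold <- relThreshold * sort(mag, partial = k)[k]
    if (threshold <= 0)
      stop("no fish found: frame has no spatial gradient")
  }
  if (threshold <= 0) stop("gradient threshold must be positive")
  mask <- mag > threshold
  if (!is.null(exclude)) mask[exclude] <- FALSE
  if (!any(mask)) stop("no fish found: empty mask after gradient threshold")
  filled <- EBImage::fillHull(EBImage::Image(mask * 1)) > 0.5
  if (erode > 0) {
    k <- EBImage::makeBrush(2 * erode + 1, "disc")
    filled <- as.matrix(EBImage::erode(EBImage::Image(filled * 1), k)) > 0.5
    if (!any(filled)) stop("no fish found: mask vanished after erosion")
  }
  lab <- EBImage::bwlabel(EBImage::Image(filled * 1))
  labm <- as.matrix(EBImage::imageData(lab))
  counts <- tabulate(labm[labm > 0])
  best <- which.max(counts)
  out <- labm == best
  dim(out) <- dim(frame)
  out
}
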