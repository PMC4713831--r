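# Natural cubic spline with explicit piecewise-polynomial coefficients.
#
# The tracker needs more than interpolated values: the local centreline angle
# is the *analytic* integral of the curvature spline, and the curvature
# regulariser integrates the squared spline derivative.  stats::splinefun
# hides its coefficients, so a small classical implementation is kept here.

#' Natural cubic spline coefficients
#'
#' Fits the natural cubic interpolating spline (second derivative zero at both
#' ends) through \code{(x, y)} and returns its piecewise polynomial
#' coefficients: on \code{[x[i], x[i+1]]} the spline is
#' \code{y[i] + b[i] t + c[i] t^2 + d[i] t^3} with \code{t = s - x[i]}.
#'
#' @param x strictly increasing knot positions (length >= 2).
#' @param y values at the knots.
#' @return An object of class \code{"naturalSpline"}.
#' @keywords internal
naturalSpline <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 2L, length(y) == n, all(diff(x) > 0))
  if (n == 2L) {
    h <- x[2] - x[1]
    return(structure(list(x = x, y = y, b = (y[2] - y[1]) / h,
                          c = 0, d = 0), class = "naturalSpline"))
  }
  h <- diff(x)
  # tridiagonal system for interior second derivatives m[2..n-1]; m[1]=m[n]=0
  m <- numeric(n)
  if (n > 2L) {
    A <- matrix(0, n - 2L, n - 2L)
    rhs <- numeric(n - 2L)
    for (i in seq_len(n - 2L)) {
      A[i, i] <- 2 * (h[i] + h[i + 1L])
      if (i > 1L) A[i, i - 1L] <- h[i]
      if (i < n - 2L) A[i, i + 1L] <- h[i + 1L]
      rhs[i] <- 6 * ((y[i + 2L] - y[i + 1L]) / h[i + 1L] -
                       (y[i + 1L] - y[i]) / h[i])
    }
    m[2:(n - 1L)] <- solve(A, rhs)
  }
  i <- seq_len(n - 1L)
  b <- (y[i + 1L] - y[i]) / h - h * (2 * m[i] + m[i + 1L]) / 6
  cc <- m[i] / 2
  d <- (m[i + 1L] - m[i]) / (6 * h)
  structure(list(x = x, y = y[i], b = b, c = cc, d = d),
            class = "naturalSpline")
}

# piece index for evaluation points, clamped so extrapolation continues the
# terminal cubic (constant-extrapolation of the polynomial piece)
.splinePiece <- function(sp, s) {
  idx <- findInterval(s, sp$x, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(sp$b))
}

#' Evaluate a natural spline (or its derivative)
#' @param sp a \code{naturalSpline}.
#' @param s evaluation points.
#' @param deriv 0, 1 or 2.
#' @keywords internal
evalSpline <- function(sp, s, deriv = 0L) {
  i <- .splinePiece(sp, s)
  t <- s - sp$x[i]
  if (deriv == 0L) sp$y[i] + t * (sp$b[i] + t * (sp$c[i] + t * sp$d[i]))
  else if (deriv == 1L) sp$b[i] + t * (2 * sp$c[i] + 3 * t * sp$d[i])
  else 2 * sp$c[i] + 6 * t * sp$d[i]
}

#' Exact antiderivative of a natural spline
#'
#' Returns \code{F(s) = integral from x[1] to s} of the piecewise cubic,
#' evaluated by per-piece quartic antiderivatives (no quadrature error).
#' @keywords internal
integrateSpline <- function(sp, s) {
  h <- diff(sp$x)
  # cumulative integral up to the start of each piece
  pieceInt <- sp$y * h + sp$b * h^2 / 2 + sp$c * h^3 / 3 + sp$d * h^4 / 4
  cum <- c(0, cumsum(pieceInt))
  i <- .splinePiece(sp, s)
  t <- s - sp$x[i]
  cum[i] + t * (sp$y[i] + t * (sp$b[i] / 2 + t * (sp$c[i] / 3 + t * sp$d[i] / 4)))
}

# C2 quintic smoothstep on [0,1], clamped outside; used by the motion scripts
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (10 + u * (-15 + 6 * u))
}
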