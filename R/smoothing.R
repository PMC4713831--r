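# Penalised least-squares (Whittaker) smoothing with a 4th-order difference
# penalty, so second time derivatives of the smoothed series remain smooth.
# The smoother is applied to the raw model parameters only; derived
# quantities are never re-smoothed.

#' Whittaker smoother with 4th-order difference penalty
#'
#' Minimises sum (yhat - y)^2 + lambda * sum (Delta^4 yhat)^2. Cubic
#' polynomials lie in the penalty null space and pass through unchanged;
#' lambda = 0 returns the input exactly.
#'
#' @param y numeric series (uniform sampling), length >= 9.
#' @param lambda penalty weight (>= 0), or NA to select it by generalised
#'   cross-validation (GCV).
#' @param order difference order of the penalty (fixed default 4).
#' @return list(y = smoothed series, lambda = value used, gcv = GCV score
#'   at that value or NA).
#' @export
smoothSeries <- function(y, lambda = NA, order = 4L) {
  n <- length(y)
  if (n < 2L * order + 1L) stop("series too short to smooth (need >= 9 samples)")
  if (!is.na(lambda) && lambda == 0)
    return(list(y = y, lambda = 0, gcv = NA_real_))
  D <- diff(diag(n), differences = order)
  E <- eigen(crossprod(D), symmetric = TRUE)
  z <- drop(crossprod(E$vectors, y))
  fitAt <- function(lam) {
    w <- 1 / (1 + lam * E$values)
    yhat <- drop(E$vectors %*% (w * z))
    list(yhat = yhat, trH = sum(w),
         rss = sum((z * (1 - w))^2))
  }
  gcvAt <- function(lam) {
    f <- fitAt(lam)
    n * f$rss / (n - f$trH)^2
  }
  gcv <- NA_real_
  if (is.na(lambda)) {
    grid <- 10^seq(-2, 10, by = 0.25)
    scores <- vapply(grid, gcvAt, numeric(1))
    i <- which.min(scores)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(function(u) gcvAt(10^u), c(log10(lo), log10(hi)))
    lambda <- 10^opt$minimum
    gcv <- opt$objective
  }
  f <- fitAt(lambda)
  list(y = f$yhat, lambda = lambda, gcv = gcv)
}

#' Smooth a state matrix column-wise
#'
#' @param states n x p matrix of raw tracked parameters.
#' @param lambda scalar or length-p vector of penalty weights; NA entries
#'   are chosen per column by GCV.
#' @return list(states = smoothed matrix, lambda = per-column values used).
#' @export
smoothStates <- function(states, lambda = NA) {
  p <- ncol(states)
  if (length(lambda) == 1L) lambda <- rep(lambda, p)
  out <- states
  used <- numeric(p)
  for (j in seq_len(p)) {
    sm <- smoothSeries(states[, j], lambda[j])
    out[, j] <- sm$y
    used[j] <- sm$lambda
  }
  list(states = out, lambda = used)
}

#' Penalty weight for a target cutoff frequency
#'
#' For the 4th-order-difference Whittaker smoother the frequency response
#' is |H(f)| = 1 / (1 + lambda (2 sin(pi f / fs))^8); this returns the
#' lambda whose half-power point sits at \code{cutoffHz}. Used as the
#' default smoothing weight: the cutoff is placed above the kinematic band
#' of interest (tail-beat frequency and its first harmonics) and below the
#' frame-rate noise band.
#'
#' @param fps sampling rate (1/s).
#' @param cutoffHz half-power frequency (default 150 Hz at 2000 fps).
#' @return penalty weight lambda.
#' @export
cutoffLambda <- function(fps, cutoffHz = 150) {
  (2 * sin(pi * cutoffHz / fps))^-8
}

#' Second-order finite-difference derivatives
#'
#' Central differences in the interior, one-sided second-order stencils at
#' the ends; exact for quadratics everywhere.
#'
#' @param y numeric vector or matrix (columns differentiated independently).
#' @param dt uniform sampling interval (> 0).
#' @param deriv 1 or 2.
#' @return same shape as \code{y}.
#' @export
differentiate <- function(y, dt, deriv = 1L) {
  stopifnot(dt > 0)
  if (is.matrix(y)) return(apply(y, 2, differentiate, dt = dt, deriv = deriv))
  n <- length(y)
  stopifnot(n >= 4L)
  if (deriv == 1L) {
    d <- c(-3 * y[1] + 4 * y[2] - y[3],
           y[3:n] - y[1:(n - 2)],
           3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  } else {
    d <- c(2 * y[1] - 5 * y[2] + 4 * y[3] - y[4],
           y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)],
           2 * y[n] - 5 * y[n - 1] + 4 * y[n - 2] - y[n - 3]) / dt^2
  }
  d
}
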