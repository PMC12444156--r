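# Finite-difference differentiation on (possibly non-uniform) time grids.
#
# Interior points use the three-point Lagrange stencil (central differences
# generalised to unequal spacing): exact on quadratics, second-order accurate
# on uniform grids. The two boundary points use one-sided stencils of the
# same accuracy (3 nodes for the first derivative, 4 for the second). The
# third derivative is the first derivative of the second -- this keeps the
# boundary error of the jerk estimate small enough for the log dimensionless
# jerk to resolve its analytic value at ordinary capture rates.

# Fornberg's algorithm: weights for the m-th derivative at point z given
# nodes x (used for the one-sided boundary stencils).
.fd_weights <- function(z, x, m) {
  n <- length(x) - 1L
  c_mat <- matrix(0, n + 1L, m + 1L)
  c1 <- 1
  c4 <- x[1L] - z
  c_mat[1L, 1L] <- 1
  for (i in seq_len(n)) {
    mn <- min(i, m)
    c2 <- 1
    c5 <- c4
    c4 <- x[i + 1L] - z
    for (j in seq_len(i) - 1L) {
      c3 <- x[i + 1L] - x[j + 1L]
      c2 <- c2 * c3
      if (j == i - 1L) {
        for (k in seq(mn, 1L)) {
          c_mat[i + 1L, k + 1L] <- c1 * (k * c_mat[i, k] - c5 * c_mat[i, k + 1L]) / c2
        }
        c_mat[i + 1L, 1L] <- -c1 * c5 * c_mat[i, 1L] / c2
      }
      for (k in seq(mn, 1L)) {
        c_mat[j + 1L, k + 1L] <- (c4 * c_mat[j + 1L, k + 1L] - k * c_mat[j + 1L, k]) / c3
      }
      c_mat[j + 1L, 1L] <- c4 * c_mat[j + 1L, 1L] / c3
    }
    c1 <- c2
  }
  c_mat[, m + 1L]
}

# single differentiation (order 1 or 2) of the columns of Y over t
.deriv_once <- function(t, Y, m) {
  n <- length(t)
  out <- matrix(0, n, ncol(Y))
  h1 <- t[2:(n - 1)] - t[1:(n - 2)]
  h2 <- t[3:n] - t[2:(n - 1)]
  if (m == 1L) {
    wm <- -h2 / (h1 * (h1 + h2))
    w0 <- (h2 - h1) / (h1 * h2)
    wp <- h1 / (h2 * (h1 + h2))
  } else {
    wm <- 2 / (h1 * (h1 + h2))
    w0 <- -2 / (h1 * h2)
    wp <- 2 / (h2 * (h1 + h2))
  }
  for (j in seq_len(ncol(Y))) {
    y <- Y[, j]
    out[2:(n - 1), j] <- wm * y[1:(n - 2)] + w0 * y[2:(n - 1)] + wp * y[3:n]
  }
  # one-sided boundary stencils, second-order accurate
  k <- min(n, m + 2L)
  wl <- .fd_weights(t[1L], t[seq_len(k)], m)
  wr <- .fd_weights(t[n], t[seq(n - k + 1L, n)], m)
  for (j in seq_len(ncol(Y))) {
    out[1L, j] <- sum(wl * Y[seq_len(k), j])
    out[n, j] <- sum(wr * Y[seq(n - k + 1L, n), j])
  }
  out
}

.deriv_matrix <- function(t, Y, order) {
  n <- length(t)
  if (anyDuplicated(t)) stop("duplicate timestamps", call. = FALSE)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (n < order + 1L) {
    stop(sprintf("need at least %d samples for derivative order %d", order + 1L, order),
         call. = FALSE)
  }
  switch(as.character(order),
    "1" = .deriv_once(t, Y, 1L),
    "2" = .deriv_once(t, Y, 2L),
    "3" = .deriv_once(t, .deriv_once(t, Y, 2L), 1L),
    stop("order must be 1, 2 or 3", call. = FALSE)
  )
}

#' Numerical differentiation of a profile or path
#'
#' Differentiates a [scalar_profile()] or [path3d()] with respect to time.
#' Interior points use three-point Lagrange (central) differences supporting
#' non-uniform spacing; the two boundary points use one-sided second-order
#' stencils. The output has the same length as the input.
#'
#' @param x A `scalar_profile` or `path3d`.
#' @param order Derivative order: 1, 2 or 3.
#' @param ... Unused.
#' @return An object of the same class as `x` holding the derivative; the
#'   `derivative_order` tag is incremented by `order`.
#' @export
differentiate <- function(x, order = 1L, ...) UseMethod("differentiate")

#' @rdname differentiate
#' @export
differentiate.scalar_profile <- function(x, order = 1L, ...) {
  d <- .deriv_matrix(x$times, matrix(x$values, ncol = 1L), as.integer(order))
  unit <- if (nzchar(x$unit)) paste0(x$unit, "/s", if (order > 1L) paste0("^", order) else "") else ""
  scalar_profile(x$times, d[, 1L], unit = unit,
                 derivative_order = x$derivative_order + as.integer(order))
}

#' @rdname differentiate
#' @export
differentiate.path3d <- function(x, order = 1L, ...) {
  d <- .deriv_matrix(x$times, x$points, as.integer(order))
  out <- structure(list(times = x$times, points = d), class = "path3d")
  attr(out, "derivative_order") <- as.integer(order)
  out
}

#' Speed profile of a 3D path
#'
#' The Euclidean norm of the first time-derivative of position: the
#' instantaneous speed of the end-effector in mm/s.
#'
#' @param path A [path3d()] with at least 2 samples.
#' @return A [scalar_profile()] with unit `"mm/s"` and derivative order 1.
#' @export
speed_profile <- function(path) {
  if (!inherits(path, "path3d")) stop("path must be a path3d", call. = FALSE)
  if (length(path$times) < 2L) stop("need at least 2 samples", call. = FALSE)
  d <- differentiate(path, 1L)
  scalar_profile(path$times, .row_norms(d$points), unit = "mm/s", derivative_order = 1L)
}

#' Path length of a polyline
#'
#' Sum of Euclidean distances between consecutive points; always at least
#' the straight-line start-to-end distance.
#'
#' @param path A [path3d()] or an N x 3 matrix of points (mm).
#' @return Path length in mm.
#' @export
path_length <- function(path) {
  pts <- if (inherits(path, "path3d")) path$points else .as_points(path)
  if (nrow(pts) < 2L) stop("need at least 2 points", call. = FALSE)
  sum(.row_norms(diff(pts)))
}

#' Resample a scalar profile onto a uniform grid
#'
#' Linear interpolation onto an evenly spaced grid spanning exactly
#' `[min(times), max(times)]`. The number of samples is chosen so the grid
#' step is as close as possible to `1/rate`; when the span is an integer
#' multiple of `1/rate` the requested rate is met exactly and both endpoints
#' are grid points.
#'
#' @param profile A [scalar_profile()] with at least 2 samples.
#' @param rate Target sampling rate in Hz.
#' @return A uniformly sampled [scalar_profile()].
#' @export
resample_uniform <- function(profile, rate) {
  if (!inherits(profile, "scalar_profile")) stop("profile must be a scalar_profile", call. = FALSE)
  if (length(profile$times) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a positive number", call. = FALSE)
  }
  span <- max(profile$times) - min(profile$times)
  n <- max(2L, as.integer(round(span * rate)) + 1L)
  grid <- seq(min(profile$times), max(profile$times), length.out = n)
  vals <- stats::approx(profile$times, profile$values, xout = grid)$y
  scalar_profile(grid, vals, unit = profile$unit,
                 derivative_order = profile$derivative_order)
}
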