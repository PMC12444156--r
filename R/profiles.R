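#' Timestamped scalar profile
#'
#' A scalar time series (speed, tangential acceleration, joint angle, ...)
#' with a unit tag and the derivative order it represents relative to
#' position (0 = position-like, 1 = velocity, 2 = acceleration, 3 = jerk).
#'
#' @param times Numeric vector of timestamps in seconds, strictly increasing.
#' @param values Numeric vector, same length as `times`.
#' @param unit Unit tag, e.g. `"mm/s"` or `"deg"`.
#' @param derivative_order Integer in 0..3.
#' @return An object of class `scalar_profile`.
#' @export
scalar_profile <- function(times, values, unit = "", derivative_order = 0L) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("times and values must have the same length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(
    list(times = times, values = values, unit = unit,
         derivative_order = as.integer(derivative_order)),
    class = "scalar_profile"
  )
}

#' @export
print.scalar_profile <- function(x, ...) {
  cat(sprintf("<scalar_profile> %d samples, unit '%s', derivative order %d\n",
              length(x$times), x$unit, x$derivative_order))
  if (length(x$times)) {
    cat(sprintf("  t: [%.4g, %.4g] s   values: [%.4g, %.4g]\n",
                min(x$times), max(x$times), min(x$values), max(x$values)))
  }
  invisible(x)
}

#' @export
length.scalar_profile <- function(x) length(x$times)

#' 3D path
#'
#' A timestamped sequence of 3D positions in millimetres.
#'
#' @param times Numeric vector of timestamps in seconds, strictly increasing.
#' @param points N x 3 numeric matrix of positions (mm), columns x, y, z.
#' @return An object of class `path3d`.
#' @export
path3d <- function(times, points) {
  times <- as.numeric(times)
  points <- .as_points(points)
  if (length(times) != nrow(points)) {
    stop("times and points must have the same length", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, points = points), class = "path3d")
}

#' @export
print.path3d <- function(x, ...) {
  cat(sprintf("<path3d> %d samples over %.4g s\n",
              length(x$times), diff(range(x$times))))
  invisible(x)
}

#' @export
length.path3d <- function(x) length(x$times)
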