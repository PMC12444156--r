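#' @keywords internal
"_PACKAGE"

# row-wise Euclidean norm of an N x 3 matrix
.row_norms <- function(m) sqrt(rowSums(m * m))

# coerce a 3-vector or N x 3 matrix to an N x 3 matrix
.as_points <- function(p, name = "points") {
  if (is.null(dim(p))) {
    if (length(p) != 3L) stop(name, " must be a 3-vector or an N x 3 matrix", call. = FALSE)
    p <- matrix(p, nrow = 1L)
  }
  p <- as.matrix(p)
  if (ncol(p) != 3L) stop(name, " must have 3 columns (x, y, z)", call. = FALSE)
  storage.mode(p) <- "double"
  p
}

.stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

.up_axis_index <- function(up_axis) {
  if (is.numeric(up_axis)) {
    i <- as.integer(up_axis)
    if (!i %in% 1:3) stop("up_axis must be 'x', 'y', 'z' or 1..3", call. = FALSE)
    return(i)
  }
  i <- match(tolower(up_axis), c("x", "y", "z"))
  if (is.na(i)) stop("up_axis must be 'x', 'y', 'z' or 1..3", call. = FALSE)
  i
}

# trapezoidal integral of y over t
.trapz <- function(t, y) sum((y[-1] + y[-length(y)]) / 2 * diff(t))

# clamp for acos arguments
.clamp1 <- function(x) pmin(1, pmax(-1, x))
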