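# Speed, efficiency, accuracy and control-strategy metrics.
# Profiles are accepted either as scalar_profile objects or as bare numeric
# vectors (with times where the metric needs them).

.profile_values <- function(profile) {
  if (inherits(profile, "scalar_profile")) profile$values else as.numeric(profile)
}

.profile_times <- function(profile) {
  if (inherits(profile, "scalar_profile")) profile$times else
    stop("a scalar_profile with times is required", call. = FALSE)
}

.seg_times <- function(seg) {
  # accept a one-row data.frame from split_segments() or a list(t0=, t1=)
  t0 <- seg$t0; t1 <- seg$t1
  if (is.null(t0) || is.null(t1) || length(t0) != 1L || length(t1) != 1L) {
    stop("seg must supply scalar t0 and t1", call. = FALSE)
  }
  if (t1 < t0) stop("segment has t1 < t0", call. = FALSE)
  c(t0, t1)
}

#' Movement time
#'
#' Duration of one movement segment, `t1 - t0`, from the segmentation
#' supplied in the input labels (boundaries inclusive).
#'
#' @param seg A segment row from [split_segments()] (or any list with
#'   `t0` and `t1`).
#' @return Seconds.
#' @export
movement_time <- function(seg) {
  tt <- .seg_times(seg)
  tt[2L] - tt[1L]
}

#' Mean velocity
#'
#' Arithmetic mean of the instantaneous speed samples in a segment's speed
#' profile.
#'
#' @param profile Speed profile ([scalar_profile()] or numeric vector), mm/s.
#' @return Mean speed in mm/s.
#' @export
mean_velocity <- function(profile) {
  v <- .profile_values(profile)
  if (!length(v)) stop("empty speed profile", call. = FALSE)
  mean(v)
}

#' Peak velocity
#'
#' Maximum of the speed profile within a segment.
#'
#' @inheritParams mean_velocity
#' @return Peak speed in mm/s.
#' @export
peak_velocity <- function(profile) {
  v <- .profile_values(profile)
  if (!length(v)) stop("empty speed profile", call. = FALSE)
  max(v)
}

#' Hand path ratio
#'
#' Traveled path length divided by the straight-line distance between the
#' first and last point. 1 means a perfectly direct movement; larger values
#' indicate detours, hesitations or corrections.
#'
#' @param path A [path3d()] (or N x 3 matrix) of end-effector positions.
#' @return Dimensionless ratio, >= 1 up to discretization tolerance.
#' @export
hand_path_ratio <- function(path) {
  pts <- if (inherits(path, "path3d")) path$points else .as_points(path)
  if (nrow(pts) < 2L) stop("need at least 2 points", call. = FALSE)
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1L, ])^2))
  if (chord == 0) stop("undefined HPR for closed path (start equals end)", call. = FALSE)
  path_length(pts) / chord
}

#' Target error
#'
#' Euclidean distance between the end-effector's final position and the
#' designated target location.
#'
#' @param p_final Final position, 3-vector (mm).
#' @param target Target position, 3-vector (mm) (or a list with `$position`).
#' @return Distance in mm.
#' @export
target_error <- function(p_final, target) {
  if (is.list(target) && !is.null(target$position)) target <- target$position
  p_final <- as.numeric(p_final); target <- as.numeric(target)
  if (length(p_final) != 3L || length(target) != 3L) {
    stop("p_final and target must be 3D points", call. = FALSE)
  }
  .stopifnot_finite(c(p_final, target), "target/endpoint")
  sqrt(sum((p_final - target)^2))
}

#' Time to peak velocity
#'
#' Time at which the speed maximum occurs, as a percentage of the segment
#' duration. Ties are broken to the earliest sample, since the metric
#' measures how early the ballistic peak occurs.
#'
#' @param profile Speed profile as a [scalar_profile()] (times required).
#' @param seg Optional segment supplying `t0`/`t1`; defaults to the profile's
#'   time span.
#' @return Percentage in \[0, 100\].
#' @export
time_to_peak_velocity <- function(profile, seg = NULL) {
  v <- .profile_values(profile)
  tt <- .profile_times(profile)
  if (!length(v)) stop("empty speed profile", call. = FALSE)
  bounds <- if (is.null(seg)) range(tt) else .seg_times(seg)
  if (bounds[2L] <= bounds[1L]) stop("zero-duration segment", call. = FALSE)
  t_peak <- tt[which.max(v)]
  100 * (t_peak - bounds[1L]) / (bounds[2L] - bounds[1L])
}
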