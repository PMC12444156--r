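# Joint angles and range of motion for elbow and shoulder.
#
# Elbow: angle between the upper-arm vector (shoulder -> elbow) and the
# forearm vector (elbow -> wrist). 0 deg = fully extended (vectors
# parallel), 180 deg = fully folded.
#
# Shoulder: angle between the upper-arm vector (shoulder -> elbow) and the
# trunk vector from the shoulder to a virtual trunk point placed
# horizontally along the neck -> shoulder direction -- a digital analogue
# of aligning a goniometer arm with the trunk.

JOINT_IDS <- c("left_elbow", "right_elbow", "left_shoulder", "right_shoulder")

# row-wise angle in degrees between two N x 3 matrices of vectors
.angle_between <- function(u, v, what = "limb") {
  nu <- .row_norms(u); nv <- .row_norms(v)
  bad <- which(nu == 0 | nv == 0)
  if (length(bad)) {
    stop(sprintf("zero-length %s vector at frame %d", what, bad[1L]), call. = FALSE)
  }
  acos(.clamp1(rowSums(u * v) / (nu * nv))) * 180 / pi
}

#' Elbow angle
#'
#' Angle between the upper-arm vector (shoulder to elbow) and the forearm
#' vector (elbow to wrist), in degrees. 0 = fully extended, 180 = fully
#' folded.
#'
#' @param shoulder,elbow,wrist 3-vectors or N x 3 matrices of positions (mm).
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
elbow_angle <- function(shoulder, elbow, wrist) {
  s <- .as_points(shoulder, "shoulder")
  e <- .as_points(elbow, "elbow")
  w <- .as_points(wrist, "wrist")
  .angle_between(e - s, w - e, "limb")
}

#' Virtual trunk point
#'
#' A reference point placed at the shoulder's height, `offset` mm from the
#' shoulder along the horizontal projection of the neck-to-shoulder
#' direction. It emulates the trunk arm of a goniometer for shoulder-angle
#' measurement; the shoulder angle does not depend on `offset`.
#'
#' @param neck,shoulder 3-vectors or N x 3 matrices (mm).
#' @param offset Distance from the shoulder in mm (default 100).
#' @param up_axis Vertical axis: `"x"`, `"y"` or `"z"` (default).
#' @param direction `"neck_to_shoulder"` (default) or `"shoulder_to_neck"`,
#'   flipping the sign of the horizontal reference direction.
#' @return Point(s) with the same up-axis coordinate as the shoulder.
#' @export
virtual_trunk_point <- function(neck, shoulder, offset = 100, up_axis = "z",
                                direction = c("neck_to_shoulder", "shoulder_to_neck")) {
  direction <- match.arg(direction)
  nk <- .as_points(neck, "neck")
  sh <- .as_points(shoulder, "shoulder")
  ax <- .up_axis_index(up_axis)
  h <- sh - nk
  if (direction == "shoulder_to_neck") h <- -h
  h[, ax] <- 0
  hn <- .row_norms(h)
  bad <- which(hn == 0)
  if (length(bad)) {
    stop(sprintf("neck directly above/below shoulder at frame %d: horizontal direction undefined",
                 bad[1L]), call. = FALSE)
  }
  sh + offset * h / hn
}

#' Shoulder angle
#'
#' Angle between the upper-arm vector (shoulder to elbow) and the trunk
#' vector (shoulder to the [virtual_trunk_point()]), in degrees. Independent
#' of the virtual-trunk offset magnitude.
#'
#' @param shoulder,elbow,neck 3-vectors or N x 3 matrices (mm).
#' @inheritParams virtual_trunk_point
#' @return Angle(s) in degrees, in \[0, 180\].
#' @export
shoulder_angle <- function(shoulder, elbow, neck, up_axis = "z", offset = 100,
                           direction = c("neck_to_shoulder", "shoulder_to_neck")) {
  sh <- .as_points(shoulder, "shoulder")
  el <- .as_points(elbow, "elbow")
  vtp <- virtual_trunk_point(neck, sh, offset = offset, up_axis = up_axis,
                             direction = direction)
  .angle_between(el - sh, vtp - sh, "shoulder/trunk")
}

#' Per-frame joint-angle series
#'
#' Computes the elbow or shoulder angle at every frame of a recording.
#' Shoulder angles use the NK landmark when present, otherwise the neck is
#' estimated from the shoulders ([estimate_neck()]). A degenerate frame
#' (zero-length limb vector) is an error naming the frame; no silent
#' interpolation is performed.
#'
#' @param rec A [recording()].
#' @param joint One of `"left_elbow"`, `"right_elbow"`, `"left_shoulder"`,
#'   `"right_shoulder"`.
#' @param up_axis Vertical axis, used for shoulder angles (default `"z"`).
#' @param direction Sign convention for the trunk reference direction; see
#'   [virtual_trunk_point()].
#' @return An `angle_series`: list with `times` (s), `angles` (degrees) and
#'   `joint`.
#' @export
angle_series <- function(rec, joint, up_axis = "z",
                         direction = c("neck_to_shoulder", "shoulder_to_neck")) {
  if (!inherits(rec, "recording")) stop("rec must be a recording", call. = FALSE)
  joint <- match.arg(joint, JOINT_IDS)
  side <- if (startsWith(joint, "left")) "L" else "R"
  need <- function(code) {
    if (!code %in% names(rec$positions)) {
      stop("landmark ", code, " required for ", joint, " is missing", call. = FALSE)
    }
    rec$positions[[code]]
  }
  angles <- if (endsWith(joint, "elbow")) {
    elbow_angle(need(paste0(side, "SH")), need(paste0(side, "EL")),
                need(paste0(side, "WR")))
  } else {
    if (!"NK" %in% names(rec$positions)) rec <- estimate_neck(rec)
    shoulder_angle(need(paste0(side, "SH")), need(paste0(side, "EL")),
                   rec$positions$NK, up_axis = up_axis, direction = direction)
  }
  structure(list(times = rec$times, angles = angles, joint = joint),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %s: %d samples, range [%.2f, %.2f] deg\n",
              x$joint, length(x$times), min(x$angles), max(x$angles)))
  invisible(x)
}

#' Range of motion of a joint-angle series
#'
#' Max minus min of the joint angle within a segment (or over the whole
#' series), in degrees.
#'
#' @param series An [angle_series()].
#' @param seg Optional segment (`t0`/`t1`); defaults to the whole series.
#' @return A `rom_result`: list with `joint`, `rom`, `min_angle`,
#'   `max_angle` and the (windowed) `series`.
#' @export
rom_range <- function(series, seg = NULL) {
  if (!inherits(series, "angle_series")) stop("series must be an angle_series", call. = FALSE)
  idx <- if (is.null(seg)) seq_along(series$times) else
    which(series$times >= seg$t0 & series$times <= seg$t1)
  if (!length(idx)) stop("segment does not overlap the angle series", call. = FALSE)
  a <- series$angles[idx]
  structure(list(joint = series$joint,
                 rom = max(a) - min(a),
                 min_angle = min(a), max_angle = max(a),
                 series = structure(list(times = series$times[idx], angles = a,
                                         joint = series$joint),
                                    class = "angle_series")),
            class = "rom_result")
}

#' @export
print.rom_result <- function(x, ...) {
  cat(sprintf("<rom_result> %s: ROM %.2f deg (min %.2f, max %.2f)\n",
              x$joint, x$rom, x$min_angle, x$max_angle))
  invisible(x)
}
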