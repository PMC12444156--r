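# Full analysis pipeline: read -> segment -> per-segment per-side metrics
# -> whole-task ROM -> export.

#' Metric identifiers computed by [run_analysis()]
#' @export
METRIC_NAMES <- c("movement_time", "mean_velocity", "peak_velocity",
                  "velocity_ratio", "n_velocity_peaks", "accel_zero_crossings",
                  "log_dimensionless_jerk", "sparc", "time_to_peak_velocity",
                  "hand_path_ratio", "target_error")

.METRIC_UNITS <- c(movement_time = "s", mean_velocity = "mm/s",
                   peak_velocity = "mm/s", velocity_ratio = "",
                   n_velocity_peaks = "count", accel_zero_crossings = "count",
                   log_dimensionless_jerk = "", sparc = "",
                   time_to_peak_velocity = "%", hand_path_ratio = "",
                   target_error = "mm")

.TARGET_METRICS <- c("hand_path_ratio", "target_error")

.side_wrist <- c(left = "LWR", right = "RWR")

# resolve per-side end-effector codes from the end_effector argument
.resolve_ee <- function(end_effector, sides) {
  if (is.null(end_effector)) return(.side_wrist[sides])
  if (!is.null(names(end_effector))) {
    ee <- end_effector[sides]
    if (anyNA(ee)) stop("end_effector must name every analyzed side", call. = FALSE)
    return(ee)
  }
  stats::setNames(rep(end_effector[1L], length(sides)), sides)
}

# resolve the per-side target (3-vector) or NULL
.resolve_target <- function(target, rec, side, seg) {
  if (is.list(target)) return(target[[side]])
  if (is.numeric(target)) return(target)
  if (!is.null(rec$target)) return(rec$target[seg$end, ])
  NULL
}

#' Run the full kinematic analysis pipeline
#'
#' For every movement segment and every requested side, computes the
#' end-effector speed-profile metrics (movement time, mean/peak velocity,
#' velocity ratio, velocity-peak count, tangential-acceleration
#' zero-crossings, log dimensionless jerk, SPARC, time to peak velocity)
#' plus hand path ratio and target error when a target is configured, and
#' whole-recording elbow/shoulder range of motion per side. A metric that
#' fails on one segment (e.g. zero path length) is recorded as skipped with
#' a reason and the run continues; schema errors abort.
#'
#' Tangential-acceleration zero-crossings are counted on the interior
#' samples of the acceleration profile, where the central-difference
#' stencils apply.
#'
#' @param input Path to a marker CSV or a [recording()].
#' @param mapping Optional column mapping for [read_recording()].
#' @param sides Character subset of `c("left", "right")`.
#' @param end_effector Landmark code(s) whose trajectory represents the
#'   movement: `NULL` (default) uses each side's wrist; a single code is
#'   used for all sides; a named vector (`c(left = ..., right = ...)`) sets
#'   them per side.
#' @param target Target position for accuracy/efficiency metrics: a
#'   3-vector (mm), a named list per side, or `NULL` to use the recording's
#'   `target_x/y/z` columns when present. Without any target, the hand path
#'   ratio and target error are skipped with a recorded reason.
#' @param metrics `"all"` or a character subset of [METRIC_NAMES].
#' @param peak_params,sparc_params Metric parameters ([peak_params()],
#'   [sparc_params()]).
#' @param up_axis Vertical axis for shoulder angles (default `"z"`).
#' @param unit_scale Coordinate multiplier applied on read (file input only).
#' @param rest_labels Iteration labels treated as rest.
#' @return A `kin_report`: list with `metrics` (long data.frame: segment,
#'   side, metric, value, unit, skip_reason), `rom` (data.frame: joint,
#'   side, rom, min_angle, max_angle, skip_reason) and `provenance`.
#' @export
run_analysis <- function(input, mapping = NULL, sides = c("left", "right"),
                         end_effector = NULL, target = NULL, metrics = "all",
                         peak_params = armkin::peak_params(),
                         sparc_params = armkin::sparc_params(),
                         up_axis = "z", unit_scale = 1,
                         rest_labels = DEFAULT_REST_LABELS) {
  rec <- if (inherits(input, "recording")) input else
    read_recording(input, mapping = mapping, unit_scale = unit_scale)
  sides <- match.arg(sides, c("left", "right"), several.ok = TRUE)
  if (identical(metrics, "all")) metrics <- METRIC_NAMES
  unknown <- setdiff(metrics, METRIC_NAMES)
  if (length(unknown)) {
    stop("unknown metric(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  segs <- split_segments(rec, rest_labels = rest_labels)
  ee <- .resolve_ee(end_effector, sides)

  rows <- list()
  emit <- function(segment, side, metric, value, reason = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      segment = segment, side = side, metric = metric,
      value = if (is.na(reason)) as.numeric(value) else NA_real_,
      unit = unname(.METRIC_UNITS[metric]), skip_reason = reason,
      stringsAsFactors = FALSE)
  }

  for (si in seq_len(nrow(segs))) {
    seg <- segs[si, ]
    for (side in sides) {
      path <- .landmark_path(rec, ee[[side]], seg)
      speed <- tryCatch(speed_profile(path), error = function(e) e)
      accel <- if (inherits(speed, "error")) speed else
        tryCatch(differentiate(speed, 1L), error = function(e) e)
      tgt <- .resolve_target(target, rec, side, seg)
      for (metric in metrics) {
        if (metric %in% .TARGET_METRICS && is.null(tgt)) {
          emit(seg$label, side, metric,
               NA, "no target configured")
          next
        }
        res <- tryCatch(switch(metric,
          movement_time = movement_time(seg),
          mean_velocity = mean_velocity(speed),
          peak_velocity = peak_velocity(speed),
          velocity_ratio = velocity_ratio(speed),
          n_velocity_peaks = count_velocity_peaks(speed, peak_params),
          accel_zero_crossings = {
            n <- length(accel$values)
            if (n < 4L) stop("too few samples for interior zero-crossings")
            zero_crossings_accel(accel$values[2:(n - 1L)])
          },
          log_dimensionless_jerk = log_dimensionless_jerk(path, seg),
          sparc = sparc(speed, sparc_params),
          time_to_peak_velocity = time_to_peak_velocity(speed, seg),
          hand_path_ratio = hand_path_ratio(path),
          target_error = target_error(path$points[nrow(path$points), ], tgt)
        ), error = function(e) e)
        if (inherits(speed, "error") &&
            metric %in% c("mean_velocity", "peak_velocity", "velocity_ratio",
                          "n_velocity_peaks", "sparc", "time_to_peak_velocity")) {
          res <- speed
        }
        if (inherits(res, "error")) {
          emit(seg$label, side, metric, NA, conditionMessage(res))
        } else {
          emit(seg$label, side, metric, res)
        }
      }
    }
  }
  mdf <- do.call(rbind, rows)

  rom_rows <- list()
  for (side in sides) {
    for (jt in c("elbow", "shoulder")) {
      joint <- paste0(side, "_", jt)
      rr <- tryCatch({
        ser <- angle_series(rec, joint, up_axis = up_axis)
        rom_range(ser)
      }, error = function(e) e)
      rom_rows[[length(rom_rows) + 1L]] <- if (inherits(rr, "error")) {
        data.frame(joint = joint, side = side, rom = NA_real_,
                   min_angle = NA_real_, max_angle = NA_real_,
                   skip_reason = conditionMessage(rr), stringsAsFactors = FALSE)
      } else {
        data.frame(joint = joint, side = side, rom = rr$rom,
                   min_angle = rr$min_angle, max_angle = rr$max_angle,
                   skip_reason = NA_character_, stringsAsFactors = FALSE)
      }
    }
  }
  romdf <- do.call(rbind, rom_rows)

  structure(list(
    metrics = mdf,
    rom = romdf,
    provenance = list(
      tool = paste0("armkin ", as.character(utils::packageVersion("armkin"))),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = list(sides = sides, end_effector = as.list(ee),
                    metrics = metrics,
                    peak_params = unclass(peak_params),
                    sparc_params = unclass(sparc_params[!vapply(sparc_params, is.null, TRUE)]),
                    up_axis = up_axis, unit_scale = unit_scale,
                    rest_labels = rest_labels,
                    n_segments = nrow(segs))
    )
  ), class = "kin_report")
}

#' @export
print.kin_report <- function(x, ...) {
  n_seg <- length(unique(x$metrics$segment))
  n_skip <- sum(!is.na(x$metrics$skip_reason))
  cat(sprintf("<kin_report> %d segment(s) x %d side(s), %d metric values (%d skipped)\n",
              n_seg, length(unique(x$metrics$side)),
              nrow(x$metrics), n_skip))
  print(utils::head(x$metrics, 12L), row.names = FALSE)
  if (nrow(x$metrics) > 12L) cat("  ...\n")
  cat("ROM:\n")
  print(x$rom, row.names = FALSE)
  invisible(x)
}

#' @export
summary.kin_report <- function(object, ...) {
  ok <- object$metrics[is.na(object$metrics$skip_reason), ]
  agg <- stats::aggregate(value ~ metric + side, data = ok, FUN = mean)
  names(agg)[names(agg) == "value"] <- "mean_value"
  agg[order(agg$side, match(agg$metric, METRIC_NAMES)), ]
}

#' @export
as.data.frame.kin_report <- function(x, ...) x$metrics

#' Export an analysis report
#'
#' JSON export nests values by segment/side/metric with units, skip reasons
#' and provenance; CSV export is a tidy long table (segment, side, metric,
#' value, unit, skip_reason) with the ROM results appended as
#' `rom_elbow`/`rom_shoulder` rows (segment `"(all)"`). Both carry the same
#' values at full precision.
#'
#' @param report A `kin_report` from [run_analysis()].
#' @param format `"json"` or `"csv"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, format = c("json", "csv"), path) {
  if (!inherits(report, "kin_report")) stop("report must be a kin_report", call. = FALSE)
  if (!nrow(report$metrics)) stop("empty report", call. = FALSE)
  format <- match.arg(format)
  if (format == "csv") {
    rom_rows <- data.frame(
      segment = "(all)", side = report$rom$side,
      metric = paste0("rom_", sub("^(left|right)_", "", report$rom$joint)),
      value = report$rom$rom, unit = "deg",
      skip_reason = report$rom$skip_reason, stringsAsFactors = FALSE)
    utils::write.csv(rbind(report$metrics, rom_rows), path, row.names = FALSE)
  } else {
    nested <- list()
    for (i in seq_len(nrow(report$metrics))) {
      r <- report$metrics[i, ]
      entry <- list(value = if (is.na(r$value)) NULL else r$value, unit = r$unit)
      if (!is.na(r$skip_reason)) entry$skip_reason <- r$skip_reason
      nested[[r$segment]][[r$side]][[r$metric]] <- entry
    }
    rom <- lapply(seq_len(nrow(report$rom)), function(i) {
      r <- report$rom[i, ]
      out <- list(joint = r$joint, side = r$side)
      if (is.na(r$skip_reason)) {
        out$rom <- r$rom; out$min_angle <- r$min_angle; out$max_angle <- r$max_angle
      } else {
        out$skip_reason <- r$skip_reason
      }
      out
    })
    jsonlite::write_json(list(provenance = report$provenance,
                              segments = nested, rom = rom),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(path)
}
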