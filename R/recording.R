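# Canonical marker CSV schema
#
# Columns: `timestamp` (UNIX seconds), `iteration` (per-row segment label,
# a rest token between movements), and one x/y/z triplet per landmark named
# <code>x, <code>y, <code>z (e.g. RWRx, RWRy, RWRz). Positions are in
# millimetres. Eight landmark codes exist; NK (neck) is the only optional
# one and can be estimated from the shoulders.

#' Upper-limb landmark codes
#'
#' The eight canonical landmark codes: left/right wrist (LWR, RWR),
#' elbow (LEL, REL), shoulder (LSH, RSH), trunk (TRK) and neck (NK).
#' NK is the only optional landmark.
#' @export
LANDMARK_CODES <- c("LWR", "RWR", "LEL", "REL", "LSH", "RSH", "TRK", "NK")

#' Default rest labels separating movement iterations
#' @export
DEFAULT_REST_LABELS <- c("", "rest")

.triplet_cols <- function(code) paste0(code, c("x", "y", "z"))

#' Construct a recording
#'
#' @param times Numeric vector of timestamps (UNIX seconds), strictly increasing.
#' @param positions Named list of N x 3 matrices (mm), names in [LANDMARK_CODES].
#' @param iteration Character vector of per-row iteration labels.
#' @param meta List of metadata; a `rate_hz` estimate and `units` tag are
#'   filled in automatically.
#' @return An object of class `recording`.
#' @export
recording <- function(times, positions, iteration, meta = list()) {
  times <- as.numeric(times)
  n <- length(times)
  if (n >= 2L && any(diff(times) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (!length(positions)) stop("at least one landmark is required", call. = FALSE)
  bad <- setdiff(names(positions), LANDMARK_CODES)
  if (length(bad)) stop("unknown landmark code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  positions <- lapply(positions, .as_points)
  for (nm in names(positions)) {
    if (nrow(positions[[nm]]) != n) {
      stop("landmark ", nm, " length differs from timestamps", call. = FALSE)
    }
    .stopifnot_finite(positions[[nm]], paste("landmark", nm))
  }
  iteration <- as.character(iteration)
  iteration[is.na(iteration)] <- ""
  if (length(iteration) != n) stop("iteration labels must cover every row", call. = FALSE)
  meta$units <- if (is.null(meta$units)) "mm" else meta$units
  meta$rate_hz <- if (n >= 2L) 1 / stats::median(diff(times)) else NA_real_
  structure(list(times = times, positions = positions,
                 iteration = iteration, meta = meta),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d frames, %d landmarks (%s)\n",
              length(x$times), length(x$positions),
              paste(names(x$positions), collapse = ", ")))
  cat(sprintf("  ~%.4g Hz, units %s\n", x$meta$rate_hz, x$meta$units))
  labs <- unique(x$iteration)
  cat(sprintf("  iteration labels: %s\n", paste(utils::head(labs, 8L), collapse = ", ")))
  invisible(x)
}

# apply a user column mapping ({"timestamp": "...", "RWR": ["cx","cy","cz"]})
# to a raw data.frame, returning canonical column names
.apply_mapping <- function(df, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- jsonlite::read_json(mapping, simplifyVector = TRUE)
  }
  for (key in names(mapping)) {
    val <- unlist(mapping[[key]])
    if (key %in% c("timestamp", "iteration")) {
      if (!val %in% names(df)) stop("mapped column '", val, "' not found", call. = FALSE)
      names(df)[names(df) == val] <- key
    } else if (key %in% LANDMARK_CODES) {
      if (length(val) != 3L) stop("mapping for ", key, " must list 3 columns", call. = FALSE)
      miss <- setdiff(val, names(df))
      if (length(miss)) stop("mapped column(s) not found: ", paste(miss, collapse = ", "), call. = FALSE)
      names(df)[match(val, names(df))] <- .triplet_cols(key)
    } else {
      stop("unknown mapping key: ", key, call. = FALSE)
    }
  }
  df
}

# core schema checks shared by read_recording and validate_schema;
# returns a data.frame of issues (severity, column, message)
.schema_issues <- function(df) {
  issue <- function(severity, column, message) {
    data.frame(severity = severity, column = column, message = message,
               stringsAsFactors = FALSE)
  }
  issues <- list()
  add <- function(...) issues[[length(issues) + 1L]] <<- issue(...)

  if (!"timestamp" %in% names(df)) add("error", "timestamp", "missing mandatory column")
  if (!"iteration" %in% names(df)) add("error", "iteration", "missing mandatory column")

  present <- character(0)
  for (code in LANDMARK_CODES) {
    cols <- .triplet_cols(code)
    have <- cols %in% names(df)
    if (any(have) && !all(have)) {
      for (m in cols[!have]) add("error", m, paste0("incomplete ", code, " triplet: column absent"))
    }
    if (all(have)) present <- c(present, code)
  }
  if (!any(c("LWR", "RWR") %in% present)) {
    add("error", "LWRx/RWRx", "no wrist landmark present (need LWR or RWR triplet)")
  }

  for (code in present) {
    for (col in .triplet_cols(code)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) | !is.finite(v))
      if (length(bad)) {
        add("error", col, sprintf("non-numeric or non-finite coordinate at row %d", bad[1L]))
      }
    }
  }

  if ("timestamp" %in% names(df)) {
    ts <- suppressWarnings(as.numeric(df$timestamp))
    if (anyNA(ts)) {
      add("error", "timestamp", "non-numeric timestamp")
    } else if (nrow(df) >= 2L) {
      d <- diff(ts)
      if (any(d < 0)) {
        add("error", "timestamp", "non-monotonic timestamps")
      } else if (any(d == 0)) {
        add("warning", "timestamp", "duplicated timestamp rows (first kept on read)")
      }
      dpos <- d[d > 0]
      if (length(dpos) >= 2L) {
        cv <- stats::sd(dpos) / stats::median(dpos)
        if (is.finite(cv) && cv > 0.01) {
          add("warning", "timestamp",
              sprintf("sampling interval jitter %.2f%% of median; spectral metrics will resample",
                      100 * cv))
        }
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(0), column = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' Validate a marker CSV against the canonical schema
#'
#' @param x File path or data.frame.
#' @param mapping Optional column-name mapping (named list or path to a JSON
#'   file), as for [read_recording()].
#' @return A data.frame of issues with columns `severity` (`"error"` blocks
#'   analysis, `"warning"` does not), `column` and `message`. Zero rows iff
#'   [read_recording()] would succeed.
#' @export
validate_schema <- function(x, mapping = NULL) {
  if (is.character(x)) {
    df <- tryCatch(suppressWarnings(
      utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)),
      error = function(e) e)
    if (inherits(df, "error")) {
      return(data.frame(severity = "error", column = "(file)",
                        message = paste("unreadable file:", conditionMessage(df)),
                        stringsAsFactors = FALSE))
    }
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (!is.null(mapping)) {
    df <- tryCatch(.apply_mapping(df, mapping), error = function(e) e)
    if (inherits(df, "error")) {
      return(data.frame(severity = "error", column = "(mapping)",
                        message = conditionMessage(df), stringsAsFactors = FALSE))
    }
  }
  .schema_issues(df)
}

#' Read a recording from a marker CSV
#'
#' Reads a CSV in the canonical schema (see [validate_schema()]); an optional
#' column mapping adapts other dialects. Coordinates are multiplied by
#' `unit_scale` (use 1000 for metre-based inputs).
#'
#' @param path CSV file path.
#' @param mapping Optional named list (or JSON file path) mapping canonical
#'   names to the file's columns: `list(timestamp = "ts", RWR = c("rx","ry","rz"))`.
#' @param unit_scale Multiplier applied to all coordinates (default 1 = mm input).
#' @return A [recording()].
#' @export
read_recording <- function(path, mapping = NULL, unit_scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!is.null(mapping)) df <- .apply_mapping(df, mapping)
  issues <- .schema_issues(df)
  errs <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(errs)) {
    stop("schema errors:\n", paste0("  [", errs$column, "] ", errs$message, collapse = "\n"),
         call. = FALSE)
  }
  ts <- as.numeric(df$timestamp)
  keep <- !duplicated(ts)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " duplicated-timestamp row(s)", call. = FALSE)
    df <- df[keep, , drop = FALSE]
    ts <- ts[keep]
  }
  codes <- LANDMARK_CODES[vapply(LANDMARK_CODES,
                                 function(code) all(.triplet_cols(code) %in% names(df)),
                                 logical(1L))]
  positions <- lapply(codes, function(code) {
    m <- vapply(.triplet_cols(code), function(col) as.numeric(df[[col]]),
                numeric(nrow(df)))
    m <- matrix(m, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
    m * unit_scale
  })
  names(positions) <- codes
  rec <- recording(ts, positions, df$iteration,
                   meta = list(source = path, unit_scale = unit_scale))
  tg_cols <- paste0("target_", c("x", "y", "z"))
  if (all(tg_cols %in% names(df))) {
    tg <- vapply(tg_cols, function(col) as.numeric(df[[col]]), numeric(nrow(df)))
    rec$target <- matrix(tg, ncol = 3L, dimnames = list(NULL, c("x", "y", "z"))) * unit_scale
  }
  rec
}

#' Write a recording to a marker CSV
#'
#' Writes the canonical schema. Coordinates are formatted with enough digits
#' that a read/write round trip reproduces them to better than 1e-9 mm.
#'
#' @param rec A [recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "recording")) stop("rec must be a recording", call. = FALSE)
  if (!length(rec$times)) stop("cannot write an empty recording", call. = FALSE)
  num <- function(x) formatC(x, format = "g", digits = 17)
  cols <- list(timestamp = num(rec$times), iteration = rec$iteration)
  for (code in names(rec$positions)) {
    pts <- rec$positions[[code]]
    trip <- .triplet_cols(code)
    for (j in 1:3) cols[[trip[j]]] <- num(pts[, j])
  }
  if (!is.null(rec$target)) {
    tg <- .as_points(rec$target)
    if (nrow(tg) == 1L) tg <- tg[rep(1L, length(rec$times)), , drop = FALSE]
    for (j in 1:3) cols[[paste0("target_", c("x", "y", "z")[j])]] <- num(tg[, j])
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Estimate the neck landmark from the shoulders
#'
#' When the neck marker is absent it is estimated as the midpoint of the two
#' shoulder markers at every frame -- the simplest estimator consistent with
#' a level shoulder girdle, and sufficient for the shoulder-angle geometry,
#' which uses only the horizontal neck-to-shoulder direction.
#'
#' @param rec A [recording()] with LSH and RSH present.
#' @param overwrite Replace an existing NK series (default FALSE: error if
#'   NK is already present).
#' @return The recording with an NK series added.
#' @export
estimate_neck <- function(rec, overwrite = FALSE) {
  if (!inherits(rec, "recording")) stop("rec must be a recording", call. = FALSE)
  if (!all(c("LSH", "RSH") %in% names(rec$positions))) {
    stop("neck estimation requires both shoulder landmarks (LSH, RSH)", call. = FALSE)
  }
  if ("NK" %in% names(rec$positions) && !overwrite) {
    stop("NK already present; use overwrite = TRUE to replace it", call. = FALSE)
  }
  rec$positions$NK <- (rec$positions$LSH + rec$positions$RSH) / 2
  rec
}

#' Split a recording into movement segments
#'
#' One segment per maximal run of identical non-rest iteration labels, in
#' temporal order. Boundaries are inclusive: `t0`/`t1` are the first/last
#' timestamps of the run. Rest rows belong to no segment; a label value may
#' recur later in the file and then starts a new segment.
#'
#' @param rec A [recording()].
#' @param rest_labels Label values treated as rest (default `""` and `"rest"`;
#'   `NA` labels are always rest).
#' @return A data.frame with columns `label`, `t0`, `t1`, `start`, `end`
#'   (row indices, inclusive), one row per segment.
#' @export
split_segments <- function(rec, rest_labels = DEFAULT_REST_LABELS) {
  if (!inherits(rec, "recording")) stop("rec must be a recording", call. = FALSE)
  lab <- rec$iteration
  is_rest <- lab %in% rest_labels
  r <- rle(paste0(ifelse(is_rest, "\r", "\a"), lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  move <- !startsWith(r$values, "\r")
  if (!any(move)) stop("no movement iterations found", call. = FALSE)
  data.frame(
    label = substring(r$values[move], 2L),
    t0 = rec$times[starts[move]],
    t1 = rec$times[ends[move]],
    start = starts[move],
    end = ends[move],
    stringsAsFactors = FALSE
  )
}

# extract the path3d of one landmark over a segment (or the whole recording)
.landmark_path <- function(rec, code, seg = NULL) {
  if (!code %in% names(rec$positions)) {
    stop("landmark ", code, " not present in recording", call. = FALSE)
  }
  idx <- if (is.null(seg)) seq_along(rec$times) else seq(seg$start, seg$end)
  path3d(rec$times[idx], rec$positions[[code]][idx, , drop = FALSE])
}

#' Mirror a recording across the sagittal plane
#'
#' Negates the given axis (default x) for every landmark and swaps the
#' left/right landmark series, producing the recording of the mirrored
#' movement. Useful for left/right comparisons and symmetry checks.
#'
#' @param rec A [recording()].
#' @param axis Mediolateral axis to negate (`"x"`, `"y"` or `"z"`).
#' @return The mirrored [recording()].
#' @export
mirror_recording <- function(rec, axis = "x") {
  if (!inherits(rec, "recording")) stop("rec must be a recording", call. = FALSE)
  ax <- .up_axis_index(axis)
  pos <- lapply(rec$positions, function(m) { m[, ax] <- -m[, ax]; m })
  swap <- c(LWR = "RWR", RWR = "LWR", LEL = "REL", REL = "LEL",
            LSH = "RSH", RSH = "LSH", TRK = "TRK", NK = "NK")
  names(pos) <- unname(swap[names(pos)])
  out <- recording(rec$times, pos, rec$iteration, meta = rec$meta)
  if (!is.null(rec$target)) {
    tg <- rec$target
    tg[, ax] <- -tg[, ax]
    out$target <- tg
  }
  out
}
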