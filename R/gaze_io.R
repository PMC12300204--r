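#' Screen geometry of the recording setup
#'
#' Physical description of the monitor and viewing distance used to convert
#' pixel coordinates into degrees of visual angle (DVA). Defaults describe a
#' 1680x1050 monitor of 474x297 mm viewed from 550 mm with the head
#' stabilised, a common laboratory eye-tracking arrangement.
#'
#' @param distance_mm Viewing distance, eye to screen, in millimetres.
#' @param res_x,res_y Screen resolution in pixels.
#' @param width_mm,height_mm Physical screen size in millimetres.
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' pixels_to_dva(840, 525, geom) # screen centre -> (0, 0)
#' @export
screen_geometry <- function(distance_mm = 550, res_x = 1680, res_y = 1050,
                            width_mm = 474, height_mm = 297) {
  vals <- c(distance_mm, res_x, res_y, width_mm, height_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_gazeid("all screen geometry fields must be strictly positive",
                "gazeid_validation_error")
  }
  structure(list(distance_mm = distance_mm, res_x = res_x, res_y = res_y,
                 width_mm = width_mm, height_mm = height_mm),
            class = "screen_geometry")
}

#' Convert pixel coordinates to degrees of visual angle
#'
#' Offsets are measured from the screen centre and converted per axis with
#' `atan(offset_mm / distance_mm)`, the small-angle-safe planar projection.
#' Positive x points right; positive y points toward the bottom of the screen
#' (screen pixel convention).
#'
#' @param px,py Pixel coordinates (vectors of equal length).
#' @param geom A [screen_geometry()].
#' @return A two-column matrix with columns `x`, `y` in DVA.
#' @export
pixels_to_dva <- function(px, py, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"), length(px) == length(py))
  off_x <- (px - geom$res_x / 2) * geom$width_mm / geom$res_x
  off_y <- (py - geom$res_y / 2) * geom$height_mm / geom$res_y
  cbind(x = atan(off_x / geom$distance_mm) * 180 / pi,
        y = atan(off_y / geom$distance_mm) * 180 / pi)
}

#' Convert degrees of visual angle back to pixel coordinates
#'
#' Inverse of [pixels_to_dva()].
#'
#' @param dx,dy Angles in DVA.
#' @inheritParams pixels_to_dva
#' @return A two-column matrix with columns `px`, `py`.
#' @export
dva_to_pixels <- function(dx, dy, geom = screen_geometry()) {
  stopifnot(inherits(geom, "screen_geometry"), length(dx) == length(dy))
  off_x <- tan(dx * pi / 180) * geom$distance_mm
  off_y <- tan(dy * pi / 180) * geom$distance_mm
  cbind(px = off_x * geom$res_x / geom$width_mm + geom$res_x / 2,
        py = off_y * geom$res_y / geom$height_mm + geom$res_y / 2)
}

#' Construct a gaze recording
#'
#' A per-sample gaze/target/validity stream for one session trial, nominally
#' sampled at 1000 Hz (1 ms timestamps). Samples where the tracker lost the
#' eye (blinks, partial occlusions) carry `NaN` gaze and `valid = FALSE`; the
#' two encodings are kept in lockstep.
#'
#' @param timestamps Sample times in ms; strictly increasing in 1 ms steps.
#' @param gaze_x,gaze_y Gaze position in DVA; `NaN` on invalid samples.
#' @param target_x,target_y Stimulus position in DVA.
#' @param valid Optional logical vector; derived from `NaN` gaze if missing.
#' @param subject_id,session_id Labels identifying the trial.
#' @return An object of class `gaze_recording` (a list of aligned vectors).
#' @export
gaze_recording <- function(timestamps, gaze_x, gaze_y, target_x, target_y,
                           valid = NULL, subject_id = NA_character_,
                           session_id = NA_character_) {
  n <- length(timestamps)
  if (n == 0L) {
    stop_gazeid("a gaze recording must contain at least one sample",
                "gazeid_validation_error")
  }
  lens <- c(length(gaze_x), length(gaze_y), length(target_x), length(target_y))
  if (any(lens != n)) {
    stop_gazeid("all per-sample arrays must have equal length",
                "gazeid_validation_error")
  }
  if (n > 1L && any(diff(timestamps) != 1)) {
    stop_gazeid("timestamps must be strictly increasing in 1 ms steps (1000 Hz)",
                "gazeid_validation_error")
  }
  nan_gaze <- !is.finite(gaze_x) | !is.finite(gaze_y)
  if (is.null(valid)) {
    valid <- !nan_gaze
  } else {
    valid <- as.logical(valid) & !nan_gaze
  }
  # keep the invariant: invalid samples carry NaN gaze
  gaze_x[!valid] <- NaN
  gaze_y[!valid] <- NaN
  structure(list(timestamps = as.numeric(timestamps),
                 gaze_x = as.numeric(gaze_x), gaze_y = as.numeric(gaze_y),
                 target_x = as.numeric(target_x), target_y = as.numeric(target_y),
                 valid = valid,
                 subject_id = as.character(subject_id),
                 session_id = as.character(session_id)),
            class = "gaze_recording")
}

#' @export
length.gaze_recording <- function(x) length(x$timestamps)

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> subject=%s session=%s, %d samples (%.1f s), %d invalid\n",
              x$subject_id, x$session_id, length(x),
              length(x) / 1000, sum(!x$valid)))
  invisible(x)
}

#' Default CSV column mapping
#'
#' Column names follow the common random-saccades layout: sample index `n`,
#' gaze `x`/`y` (DVA), validity flag `val` (0 = valid), target `xT`/`yT`.
#'
#' @return Named list mapping internal fields to CSV column names.
#' @export
default_gaze_columns <- function() {
  list(t = "n", x = "x", y = "y", val = "val", tx = "xT", ty = "yT")
}

#' Read a gaze recording from CSV
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param columns Column-name mapping as produced by [default_gaze_columns()];
#'   individual entries may be overridden.
#' @param subject_id,session_id Labels to attach to the recording.
#' @return A [gaze_recording()]. Samples with a non-zero validity flag or
#'   `NaN` gaze are marked invalid and carry `NaN` gaze.
#' @export
read_gaze_csv <- function(path, columns = default_gaze_columns(),
                          subject_id = NA_character_,
                          session_id = NA_character_) {
  if (!file.exists(path)) {
    stop_gazeid(sprintf("file not found: %s", path), "gazeid_io_error")
  }
  columns <- utils::modifyList(default_gaze_columns(), as.list(columns))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop_gazeid(sprintf("empty data section in %s", path),
                "gazeid_validation_error")
  }
  needed <- unlist(columns[c("t", "x", "y", "val", "tx", "ty")])
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_gazeid(sprintf("missing column(s) in %s: %s", path,
                        paste(missing_cols, collapse = ", ")),
                "gazeid_format_error")
  }
  ts <- df[[columns$t]]
  if (length(ts) > 1L && any(diff(ts) <= 0)) {
    stop_gazeid(sprintf("non-monotone timestamps in %s", path),
                "gazeid_validation_error")
  }
  flag_ok <- df[[columns$val]] == 0
  flag_ok[is.na(flag_ok)] <- FALSE
  gaze_recording(timestamps = ts,
                 gaze_x = df[[columns$x]], gaze_y = df[[columns$y]],
                 target_x = df[[columns$tx]], target_y = df[[columns$ty]],
                 valid = flag_ok,
                 subject_id = subject_id, session_id = session_id)
}

#' Write a gaze recording to CSV
#'
#' Numeric fields are serialised with 17 significant digits so that a
#' write/read round trip reproduces all finite values bit-exactly; invalid
#' samples are written with the literal `NaN` and validity flag 1.
#'
#' @param rec A [gaze_recording()].
#' @param path Output file path.
#' @param columns Column-name mapping; see [default_gaze_columns()].
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path, columns = default_gaze_columns()) {
  stopifnot(inherits(rec, "gaze_recording"))
  columns <- utils::modifyList(default_gaze_columns(), as.list(columns))
  fmt <- function(v) sprintf("%.17g", v)
  header <- paste(unlist(columns[c("t", "x", "y", "val", "tx", "ty")]),
                  collapse = ",")
  body <- paste(fmt(rec$timestamps), fmt(rec$gaze_x), fmt(rec$gaze_y),
                as.integer(!rec$valid), fmt(rec$target_x), fmt(rec$target_y),
                sep = ",")
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop_gazeid(sprintf("cannot open %s for writing", path), "gazeid_io_error")
  })
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
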