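#' Construct a pressure frame
#'
#' A pressure frame is one 2-D grid of interface pressures (mmHg) captured by
#' the sensor mattress at one timestamp. Rows run head-to-foot (row 1 = head
#' end), columns run across the bed; "left"/"right" throughout the package are
#' image-frame (viewer) left/right. Values are stored as doubles even when the
#' sensor emits integers so that filtering stages do not truncate.
#'
#' @param values numeric matrix of pressures in mmHg, default grid 64 rows x
#'   32 columns (the long bed axis is the row axis).
#' @param timestamp seconds from the start of the sequence.
#' @param sensor_max upper bound of the sensor's capture range, mmHg.
#' @return an object of class `pressure_frame`.
#' @examples
#' f <- pressure_frame(matrix(0, 64, 32))
#' dim(f$values)
#' @export
pressure_frame <- function(values, timestamp = 0, sensor_max = 1000) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  storage.mode(values) <- "double"
  f <- structure(
    list(values = values, timestamp = as.numeric(timestamp),
         sensor_max = sensor_max),
    class = "pressure_frame"
  )
  validate_frame(f)
  f
}

#' Validate pressure-frame invariants
#'
#' Checks that all values are finite, non-negative and within the sensor
#' range. Called by every constructor and by the reader; violations raise an
#' error rather than being silently clamped.
#'
#' @param frame a `pressure_frame`.
#' @return the frame, invisibly.
#' @export
validate_frame <- function(frame) {
  v <- frame$values
  if (anyNA(v) || any(!is.finite(v))) {
    stop("pressure frame contains NA or non-finite values")
  }
  if (any(v < 0)) {
    stop("pressure frame contains negative values")
  }
  if (any(v > frame$sensor_max)) {
    stop("pressure frame exceeds sensor_max (", frame$sensor_max, " mmHg)")
  }
  invisible(frame)
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %d x %d sensels, t = %g s, range [%g, %g] mmHg\n",
              nrow(x$values), ncol(x$values), x$timestamp,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Construct a pressure sequence
#'
#' An ordered series of [pressure_frame()]s at a fixed sampling rate (the
#' reference mattress samples at 1 Hz). Frame timestamps are (re)assigned on
#' construction as `(i - 1) / sampling_hz` so they are strictly increasing
#' with a constant step.
#'
#' @param frames list of `pressure_frame` objects sharing one grid shape.
#' @param sampling_hz frames per second.
#' @param subject_id,pose_id opaque metadata strings.
#' @return an object of class `pressure_sequence`.
#' @export
pressure_sequence <- function(frames, sampling_hz = 1,
                              subject_id = NA_character_,
                              pose_id = NA_character_) {
  if (!is.list(frames) || length(frames) == 0) {
    stop("`frames` must be a non-empty list of pressure frames")
  }
  shapes <- vapply(frames, function(f) dim(f$values), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("all frames in a sequence must share one grid shape")
  }
  for (i in seq_along(frames)) {
    frames[[i]]$timestamp <- (i - 1) / sampling_hz
    validate_frame(frames[[i]])
  }
  structure(
    list(frames = frames, sampling_hz = sampling_hz,
         subject_id = subject_id, pose_id = pose_id),
    class = "pressure_sequence"
  )
}

#' @export
print.pressure_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]]$values)
  cat(sprintf("<pressure_sequence> %d frames of %d x %d at %g Hz (subject %s, pose %s)\n",
              length(x$frames), d[1], d[2], x$sampling_hz,
              x$subject_id, x$pose_id))
  invisible(x)
}

#' @export
length.pressure_sequence <- function(x) length(x$frames)

frame_shape <- function(frame) dim(frame$values)

# Coerce a bare matrix (or frame) to a frame; internal convenience so that
# numeric matrices can be passed wherever a frame is accepted.
as_frame <- function(x, sensor_max = 1000) {
  if (inherits(x, "pressure_frame")) return(x)
  pressure_frame(x, sensor_max = sensor_max)
}
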