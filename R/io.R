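#' Read a pressure sequence from plain-text matrix files
#'
#' Parses the plain-matrix dialect used by public pressure-mat datasets and by
#' [write_sequence()]: numeric tokens, whitespace- or comma-delimited, with
#' each frame serialized as `rows x cols` values. Two layouts are accepted:
#' a single file with frames concatenated (stacked dialect), or a directory
#' holding one frame per file (read in lexicographic order). Lines starting
#' with `#` form an optional `key: value` metadata header (grid shape,
#' sampling rate, subject/pose ids); explicit arguments override the header.
#'
#' The total token count must be an exact multiple of `rows * cols`; any
#' malformed token is reported with its line number, and frames violating the
#' pressure-frame invariants (negative, NA, above `sensor_max`) are rejected
#' rather than clamped.
#'
#' @param path file or directory to read.
#' @param grid_shape integer `c(rows, cols)`; default 64 x 32 (rows are the
#'   long, head-to-foot axis).
#' @param sampling_hz sampling rate used to assign timestamps.
#' @param flip_rows if `TRUE`, reverse the row order of every frame. Public
#'   datasets do not document whether row 1 is the head or the foot end, so
#'   the reader exposes this flag instead of guessing.
#' @param sensor_max sensor capture ceiling, mmHg.
#' @return a [pressure_sequence()].
#' @seealso [write_sequence()]
#' @export
read_sequence <- function(path, grid_shape = NULL, sampling_hz = NULL,
                          flip_rows = FALSE, sensor_max = 1000) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  files <- if (dir.exists(path)) {
    fs <- sort(list.files(path, full.names = TRUE))
    fs <- fs[!dir.exists(fs)]
    if (length(fs) == 0) stop("directory contains no frame files: ", path)
    fs
  } else {
    path
  }

  header <- list()
  values <- numeric(0)
  for (f in files) {
    lines <- readLines(f, warn = FALSE)
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") next
      if (startsWith(ln, "#")) {
        kv <- sub("^#\\s*", "", ln)
        m <- regmatches(kv, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", kv))[[1]]
        if (length(m) == 3) header[[m[2]]] <- m[3]
        next
      }
      toks <- strsplit(ln, "[,[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      x <- suppressWarnings(as.numeric(toks))
      if (anyNA(x)) {
        bad <- toks[which(is.na(x))[1]]
        stop(sprintf("parse error: malformed token '%s' at %s line %d",
                     bad, basename(f), i))
      }
      values <- c(values, x)
    }
  }

  if (is.null(grid_shape)) {
    if (!is.null(header$rows) && !is.null(header$cols)) {
      grid_shape <- c(as.integer(header$rows), as.integer(header$cols))
    } else {
      grid_shape <- c(64L, 32L)
    }
  }
  if (is.null(sampling_hz)) {
    sampling_hz <- if (!is.null(header$sampling_hz)) {
      as.numeric(header$sampling_hz)
    } else 1
  }

  cells <- prod(grid_shape)
  if (length(values) == 0) stop("no numeric data found in ", path)
  if (length(values) %% cells != 0) {
    stop(sprintf("shape error: %d tokens is not a multiple of %d x %d = %d",
                 length(values), grid_shape[1], grid_shape[2], cells))
  }
  n_frames <- length(values) %/% cells

  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    chunk <- values[((k - 1) * cells + 1):(k * cells)]
    m <- matrix(chunk, nrow = grid_shape[1], ncol = grid_shape[2], byrow = TRUE)
    if (flip_rows) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    frames[[k]] <- pressure_frame(m, sensor_max = sensor_max)
  }
  pressure_sequence(frames, sampling_hz = sampling_hz,
                    subject_id = header$subject_id %||% NA_character_,
                    pose_id = header$pose_id %||% NA_character_)
}

#' Write a pressure sequence as plain-text matrices
#'
#' Emits the stacked-frames dialect accepted by [read_sequence()]: a `#`
#' metadata header, then each frame as `rows` lines of `cols`
#' whitespace-separated values at full double precision (17 significant
#' digits), frames separated by a blank line. Reading the file back
#' reproduces every value bit-exactly.
#'
#' @param seq a [pressure_sequence()].
#' @param path output file path.
#' @export
write_sequence <- function(seq, path) {
  if (!inherits(seq, "pressure_sequence")) stop("`seq` must be a pressure_sequence")
  if (length(seq$frames) == 0) stop("refusing to write an empty sequence")
  d <- dim(seq$frames[[1]]$values)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# rows: %d", d[1]),
    sprintf("# cols: %d", d[2]),
    sprintf("# sampling_hz: %.17g", seq$sampling_hz),
    sprintf("# subject_id: %s", seq$subject_id),
    sprintf("# pose_id: %s", seq$pose_id)
  ), con)
  for (fr in seq$frames) {
    m <- fr$values
    for (r in seq_len(nrow(m))) {
      writeLines(paste(sprintf("%.17g", m[r, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
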