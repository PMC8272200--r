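#' Track high-risk regions over a pressure sequence
#'
#' Runs the per-frame detection chain (enhance, gradient-field maxima, region
#' growing, size/plausibility filtering, spatial labelling) on every frame
#' and associates the labelled regions to per-label tracks: a detection joins
#' its label's track when its centroid lies within `gate` sensels of the
#' track's last known centroid (patients of interest barely move, so the gate
#' is tight). Frames where a label is missing or outside the gate are
#' recorded as gaps. Mean pressures are taken from the raw frames, in mmHg.
#'
#' @param seq a [pressure_sequence()] (>= 1 frame).
#' @param posture posture label used for filtering and labelling; `"auto"`
#'   requires a `model`.
#' @param model optional [train_posture_model()] fit, used to classify the
#'   first frame when `posture = "auto"`.
#' @param min_height,rel_level,min_area detection parameters, see
#'   [find_maxima()], [grow_regions()], [filter_regions()].
#' @param gate maximum per-frame centroid displacement, sensels.
#' @return a `track_set`: list with `tracks` (per-label `track_record`s:
#'   `label`, `timestamp`, `mean_pressure`, `centroid_row`, `centroid_col`,
#'   `gaps`) and `posture`.
#' @seealso [track_table()] for a flat data-frame view.
#' @export
track_regions <- function(seq, posture = "supine", model = NULL,
                          min_height = 20, rel_level = 0.5, min_area = 8,
                          gate = 5) {
  if (!inherits(seq, "pressure_sequence")) stop("`seq` must be a pressure_sequence")
  if (identical(posture, "auto")) {
    if (is.null(model)) stop("posture = 'auto' requires a fitted posture model")
    posture <- predict_posture(model, seq$frames[[1]])
  }
  posture <- match.arg(posture, POSTURE_LEVELS)

  tracks <- list()   # label -> list(timestamp, mean_pressure, centroid, gaps)
  for (fr in seq$frames) {
    regions <- detect_regions(fr, posture, min_height = min_height,
                              rel_level = rel_level, min_area = min_area)
    seen <- character(0)
    for (reg in regions) {
      if (reg$label == "unlabelled" || reg$label %in% seen) next
      tr <- tracks[[reg$label]]
      if (is.null(tr)) {
        tr <- list(timestamp = numeric(0), mean_pressure = numeric(0),
                   centroid_row = numeric(0), centroid_col = numeric(0),
                   gaps = numeric(0))
      }
      if (length(tr$timestamp) > 0) {
        last <- c(tail(tr$centroid_row, 1), tail(tr$centroid_col, 1))
        if (sqrt(sum((reg$centroid - last)^2)) > gate) {
          tr$gaps <- c(tr$gaps, fr$timestamp)
          tracks[[reg$label]] <- tr
          seen <- c(seen, reg$label)
          next
        }
      }
      tr$timestamp <- c(tr$timestamp, fr$timestamp)
      tr$mean_pressure <- c(tr$mean_pressure, reg$mean_pressure)
      tr$centroid_row <- c(tr$centroid_row, reg$centroid[["row"]])
      tr$centroid_col <- c(tr$centroid_col, reg$centroid[["col"]])
      tracks[[reg$label]] <- tr
      seen <- c(seen, reg$label)
    }
    # labels tracked before but absent in this frame -> gap
    for (lab in setdiff(names(tracks), seen)) {
      tracks[[lab]]$gaps <- c(tracks[[lab]]$gaps, fr$timestamp)
    }
  }
  tracks <- lapply(names(tracks), function(lab) {
    structure(c(list(label = lab), tracks[[lab]]), class = "track_record")
  })
  structure(list(tracks = tracks, posture = posture), class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %s posture, %d tracks\n", x$posture, length(x$tracks)))
  for (tr in x$tracks) {
    cat(sprintf("  %-14s %3d points, %2d gaps, mean %.1f mmHg\n", tr$label,
                length(tr$timestamp), length(tr$gaps), mean(tr$mean_pressure)))
  }
  invisible(x)
}

#' Flatten a track set into a data frame
#'
#' One row per (timestamp, label) observation with columns `timestamp_s`,
#' `label`, `mean_pressure_mmHg`, `centroid_row`, `centroid_col` — the layout
#' written by the command-line `track` subcommand.
#'
#' @param tracks a `track_set` from [track_regions()].
#' @return a data frame, ordered by timestamp then label.
#' @export
track_table <- function(tracks) {
  rows <- lapply(tracks$tracks, function(tr) {
    if (length(tr$timestamp) == 0) return(NULL)
    data.frame(timestamp_s = tr$timestamp, label = tr$label,
               mean_pressure_mmHg = tr$mean_pressure,
               centroid_row = tr$centroid_row, centroid_col = tr$centroid_col,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(timestamp_s = numeric(0), label = character(0),
                      mean_pressure_mmHg = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  out <- out[order(out$timestamp_s, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
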