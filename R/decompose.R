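#' Remove external objects from a pressure frame by trend decomposition
#'
#' Pillows and wedges present as broad low-relief plateaus, while the body
#' produces narrow high-amplitude bumps. The frame is unfolded into 1-D
#' line(s); per line, the Savitzky-Golay trend `f(S)` of the raw line `S` is
#' computed, the absolute deviation of the trend from its per-line mean,
#' `S' = |f(S) - avg(f(S))|`, is thresholded, and only raw samples where
#' `S' > th` are retained: `b = S * (S' > th)`. The smoothed trend over
#' object plateaus stays close to the line average while the body's bumps
#' deflect it strongly, so thresholding the deviation separates the two.
#'
#' Default filter parameters: a low polynomial degree (2) suffices to capture
#' the trend, and the half window is tied to the mat width, `M = round(r/2) +
#' eps_adjust` with `r` the number of sensels in the horizontal direction
#' (default 32, so M = 16). `eps_adjust` is a small window adjustment
#' depending on the type and number of objects present; default 0.
#'
#' @param frame a [pressure_frame()] or numeric matrix.
#' @param spec an [sg_filter_spec()]; `NULL` builds the default above.
#' @param th retention threshold on the trend deviation, mmHg (>= 0). `NULL`
#'   uses the documented default of 5\% of `sensor_max` (50 mmHg); prefer
#'   calibrating with [grid_search_threshold()] when ground truth is
#'   available.
#' @param line_axis `"unfolded"` (single row-major signal, default — the
#'   fast axis of the unfolding is the horizontal direction the window rule
#'   is tied to) or `"columns"` (one signal per sensor column).
#' @param degree,eps_adjust used to build the default filter spec.
#' @return a `decomposition_result` with fields `body_frame` (raw values on
#'   the retained mask, 0 elsewhere), `trend` (per-line smoothed signal,
#'   assembled to frame shape), `trend_mean` (per-line scalar), `deviation`
#'   (`S'`), `retained_mask` (logical grid), `threshold`, `filter_spec`,
#'   `line_axis`.
#' @seealso [grid_search_threshold()], [rmse()], [psnr()]
#' @export
remove_external_objects <- function(frame, spec = NULL, th = NULL,
                                    line_axis = c("unfolded", "columns"),
                                    degree = 2, eps_adjust = 0) {
  line_axis <- match.arg(line_axis)
  frame <- as_frame(frame)
  m <- frame$values
  if (is.null(spec)) {
    r <- ncol(m)  # sensels in the horizontal direction
    spec <- sg_filter_spec(degree, round(r / 2) + eps_adjust)
  }
  if (is.null(th)) th <- 0.05 * frame$sensor_max
  if (th < 0) stop("threshold must be >= 0")

  lines <- extract_lines(frame, line_axis)
  if (any(lengths(lines) < spec$window)) {
    stop(sprintf("filter window %d does not fit line length %d",
                 spec$window, min(lengths(lines))))
  }
  trends <- lapply(lines, sg_smooth, spec = spec)
  means <- vapply(trends, mean, numeric(1))
  deviations <- Map(function(tr, mu) abs(tr - mu), trends, means)
  masks <- lapply(deviations, function(d) d > th)

  gs <- dim(m)
  trend <- assemble_lines(trends, gs, line_axis)
  deviation <- assemble_lines(deviations, gs, line_axis)
  mask <- assemble_lines(lapply(masks, as.numeric), gs, line_axis) > 0
  body <- m * mask

  structure(list(
    body_frame = pressure_frame(body, timestamp = frame$timestamp,
                                sensor_max = frame$sensor_max),
    trend = trend, trend_mean = means, deviation = deviation,
    retained_mask = mask, threshold = th, filter_spec = spec,
    line_axis = line_axis
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> %d/%d sensels retained, th = %g mmHg (degree %d, M = %d, %s)\n",
              sum(x$retained_mask), length(x$retained_mask), x$threshold,
              x$filter_spec$degree, x$filter_spec$half_window, x$line_axis))
  invisible(x)
}

#' Calibrate the removal threshold by grid search
#'
#' Scans candidate thresholds on calibration scenes with ground truth and
#' returns the value maximizing the mean supervised recovery objective
#'
#' \deqn{J(th) = E_{body}(th) - E_{object}(th)}
#'
#' where `E_body` is the fraction of body-mask energy (sum of squared
#' pressures) retained in the cleaned frame and `E_object` the fraction of
#' object-only-mask energy surviving — i.e. keep the body signal, drop the
#' object signal, which is exactly what the decomposition is for. On scenes
#' without objects the objective reduces to body retention alone and the
#' search selects the smallest workable threshold. Ties are broken toward
#' the smaller threshold (retain more body). The trend deviation is computed
#' once per scene; only the thresholding is repeated.
#'
#' The threshold is a property of the scene ensemble: it depends on the
#' type and number of external objects present, so it should be calibrated
#' per recording setup.
#'
#' @param scenes list of scenes, each `list(frame =, truth =)` as returned by
#'   [generate_scene()]; `truth` must carry `body_mask` and (optionally)
#'   `object_mask`.
#' @param spec an [sg_filter_spec()]; `NULL` for the module default.
#' @param th_grid numeric vector of candidate thresholds, mmHg.
#' @param line_axis passed to [remove_external_objects()].
#' @return the selected threshold (scalar), with the per-candidate mean
#'   objective curve attached as attribute `"objective"`.
#' @export
grid_search_threshold <- function(scenes, spec = NULL,
                                  th_grid = seq(0, 100, by = 2),
                                  line_axis = c("unfolded", "columns")) {
  line_axis <- match.arg(line_axis)
  if (length(scenes) < 1) stop("at least one calibration scene is required")
  if (length(th_grid) < 1) stop("threshold grid must be non-empty")
  th_grid <- sort(th_grid)

  devs <- lapply(scenes, function(sc) {
    remove_external_objects(sc$frame, spec = spec, th = 0,
                            line_axis = line_axis)$deviation
  })

  curve <- vapply(th_grid, function(th) {
    mean(mapply(function(d, sc) {
      raw <- as_frame(sc$frame)$values
      kept <- raw * (d > th)
      bm <- sc$truth$body_mask
      e_body <- sum(kept[bm]^2) / max(sum(raw[bm]^2), .Machine$double.eps)
      om <- sc$truth$object_mask
      e_obj <- if (is.null(om) || !any(om & !bm)) 0 else {
        oo <- om & !bm
        sum(kept[oo]^2) / max(sum(raw[oo]^2), .Machine$double.eps)
      }
      e_body - e_obj
    }, devs, scenes))
  }, numeric(1))

  best <- th_grid[which.max(curve)]  # which.max takes the first (smallest) tie
  attr(best, "objective") <- setNames(curve, th_grid)
  best
}

#' Root-mean-square error between two frames
#'
#' @param reference,estimate frames (or matrices) of identical shape.
#' @param normalize if `TRUE`, both frames are divided by the reference
#'   frame's `sensor_max` first, giving the dimensionless 0-1 scale on which
#'   mat-cleaning errors are usually reported.
#' @return scalar RMSE.
#' @export
rmse <- function(reference, estimate, normalize = FALSE) {
  reference <- as_frame(reference); estimate <- as_frame(estimate)
  a <- reference$values; b <- estimate$values
  if (!all(dim(a) == dim(b))) stop("frames must have the same shape")
  if (normalize) {
    a <- a / reference$sensor_max
    b <- b / reference$sensor_max
  }
  sqrt(mean((a - b)^2))
}

#' Peak signal-to-noise ratio between two frames
#'
#' Computed as `20 * log10(peak / rmse)` on the normalized (0-1) scale, where
#' `peak` is the maximum of the normalized reference frame — the reference
#' frame's own dynamic peak, not the nominal sensor ceiling. Identical frames
#' return `Inf`.
#'
#' @inheritParams rmse
#' @return PSNR in decibels.
#' @export
psnr <- function(reference, estimate) {
  reference <- as_frame(reference); estimate <- as_frame(estimate)
  e <- rmse(reference, estimate, normalize = TRUE)
  if (e == 0) return(Inf)
  peak <- max(reference$values) / reference$sensor_max
  20 * log10(peak / e)
}
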