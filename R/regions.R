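#' Spatial gradient field of a pressure frame
#'
#' Per-sensel gradient `(df/dx, df/dy)` of the pressure image, computed by
#' central differences in the interior and one-sided differences at the
#' edges. `d_row` is the derivative down the rows (head-to-foot), `d_col`
#' across the columns.
#'
#' @param frame a [pressure_frame()] or matrix, at least 3 x 3.
#' @return a `gradient_field` with matrices `d_row` and `d_col`.
#' @export
gradient_field <- function(frame) {
  m <- as_frame(frame)$values
  if (nrow(m) < 3 || ncol(m) < 3) stop("frame must be at least 3 x 3")
  g <- pracma::gradient(m)
  structure(list(d_row = g$Y, d_col = g$X), class = "gradient_field")
}

# Label connected components of a logical mask (4- or 8-connectivity) with a
# simple stack-based flood fill; grids are small (64 x 32) so this is cheap.
cc_label <- function(mask, connectivity = 4) {
  R <- nrow(mask); C <- ncol(mask)
  lab <- matrix(0L, R, C)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3); dc <- rep(c(-1L, 0L, 1L), each = 3)
    keep <- !(dr == 0 & dc == 0); dr <- dr[keep]; dc <- dc[keep]
  }
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack) > 0) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      r0 <- ((s - 1L) %% R) + 1L; c0 <- ((s - 1L) %/% R) + 1L
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]; c <- c0 + dc[k]
        if (r >= 1 && r <= R && c >= 1 && c <= C) {
          i <- (c - 1L) * R + r
          if (mask[i] && lab[i] == 0L) {
            lab[i] <- cur
            stack <- c(stack, i)
          }
        }
      }
    }
  }
  lab
}

#' Find local pressure maxima by gradient zero crossings
#'
#' A sensel is a candidate maximum where the row-gradient changes sign from
#' positive to negative down the rows AND the column-gradient does so across
#' the columns (a zero crossing of both components, i.e. a 2-D local
#' maximum), with at least one strict sign change per axis so flat background
#' does not qualify. Candidates below `min_height` are discarded; plateau
#' candidates (8-connected candidate clusters) are resolved to their rounded
#' centroid.
#'
#' @param gfield a [gradient_field()].
#' @param frame the frame the field came from.
#' @param min_height minimum pressure for a maximum to count, mmHg.
#' @return integer matrix with columns `row`, `col` (possibly 0 rows).
#' @export
find_maxima <- function(gfield, frame, min_height = 20) {
  m <- as_frame(frame)$values
  dr <- gfield$d_row; dc <- gfield$d_col
  R <- nrow(m); C <- ncol(m)
  cand <- matrix(FALSE, R, C)
  ri <- 2:(R - 1); ci <- 2:(C - 1)
  up    <- dr[ri - 1, ci, drop = FALSE]; down  <- dr[ri + 1, ci, drop = FALSE]
  left  <- dc[ri, ci - 1, drop = FALSE]; right <- dc[ri, ci + 1, drop = FALSE]
  cand[ri, ci] <-
    (up >= 0 & down <= 0 & (up > 0 | down < 0)) &
    (left >= 0 & right <= 0 & (left > 0 | right < 0))
  cand <- cand & (m >= min_height)
  if (!any(cand)) return(matrix(integer(0), 0, 2,
                                dimnames = list(NULL, c("row", "col"))))
  lab <- cc_label(cand, connectivity = 8)
  out <- t(vapply(seq_len(max(lab)), function(l) {
    idx <- which(lab == l)
    r <- ((idx - 1L) %% R) + 1L; c <- ((idx - 1L) %/% R) + 1L
    c(round(mean(r)), round(mean(c)))
  }, numeric(2)))
  colnames(out) <- c("row", "col")
  storage.mode(out) <- "integer"
  out
}

new_region <- function(pixels, raw, label = "unlabelled") {
  r <- pixels[, 1]; c <- pixels[, 2]
  structure(list(
    label = label,
    pixels = pixels,
    centroid = c(row = mean(r), col = mean(c)),
    mean_pressure = mean(raw[cbind(r, c)])
  ), class = "body_region")
}

#' @export
print.body_region <- function(x, ...) {
  cat(sprintf("<body_region> %s: %d sensels, centroid (%.1f, %.1f), mean %.1f mmHg\n",
              x$label, nrow(x$pixels), x$centroid[1], x$centroid[2],
              x$mean_pressure))
  invisible(x)
}

#' Grow regions around detected maxima by relative-level flood fill
#'
#' Each seed grows into the 4-connected component, containing the seed, of
#' sensels at or above `rel_level` times the seed's value (the half-maximum
#' disc at the default 0.5). Regions sharing sensels are merged and their
#' seeds pooled. The reported `mean_pressure` of every region is the
#' arithmetic mean of `raw_frame` over its sensels — kept in physical mmHg
#' even when detection runs on an enhanced frame.
#'
#' @param frame frame on which to grow (typically the enhanced frame).
#' @param maxima integer matrix of seeds (`row`, `col`), e.g. from
#'   [find_maxima()].
#' @param rel_level fraction of the seed value, in (0, 1).
#' @param raw_frame frame for the pressure statistics; defaults to `frame`.
#' @return list of unlabelled `body_region`s.
#' @export
grow_regions <- function(frame, maxima, rel_level = 0.5, raw_frame = frame) {
  if (rel_level <= 0 || rel_level >= 1) stop("rel_level must be in (0, 1)")
  m <- as_frame(frame)$values
  raw <- as_frame(raw_frame)$values
  R <- nrow(m); C <- ncol(m)
  if (nrow(maxima) == 0) return(list())
  if (any(maxima[, 1] < 1 | maxima[, 1] > R | maxima[, 2] < 1 | maxima[, 2] > C)) {
    stop("seed outside the grid")
  }
  masks <- vector("list", nrow(maxima))
  for (s in seq_len(nrow(maxima))) {
    thr <- rel_level * m[maxima[s, 1], maxima[s, 2]]
    above <- m >= thr
    lab <- cc_label(above, connectivity = 4)
    masks[[s]] <- lab == lab[maxima[s, 1], maxima[s, 2]]
  }
  # merge overlapping regions (union-find over the seed list)
  parent <- seq_len(length(masks))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(masks)) {
    for (j in seq_len(i - 1)) {
      if (any(masks[[i]] & masks[[j]])) {
        parent[find(i)] <- find(j)
      }
    }
  }
  groups <- split(seq_along(masks), vapply(seq_along(masks), find, integer(1)))
  lapply(groups, function(g) {
    u <- Reduce(`|`, masks[g])
    idx <- which(u)
    pix <- cbind(row = ((idx - 1L) %% R) + 1L, col = ((idx - 1L) %/% R) + 1L)
    new_region(pix, raw)
  })
}

# Plausible row bands (fractions of the grid length) for each landmark in a
# lying posture; used by filter_regions to discard detections in rows where
# no high-risk landmark can be.
TEMPLATE_BANDS <- list(head = c(0, 0.18), shoulders = c(0.15, 0.35),
                       sacrum = c(0.40, 0.70), feet = c(0.80, 1))

#' Filter detected regions by size and plausibility
#'
#' Cleans the raw detections the way small spurious regions (hands, elbows,
#' noise blobs) are removed: a morphological opening with a 3 x 3 box is
#' applied to each region mask, regions whose remaining area is below
#' `min_area` are discarded, and — when a posture is given — regions whose
#' centroid row falls outside every plausible landmark band of the lying
#' template are discarded.
#'
#' @param regions list of `body_region`s.
#' @param min_area minimum sensel count after opening. The default 8 sits
#'   below the opened footprint of the smallest genuine landmark (a heel,
#'   ~13 sensels at half maximum); hand/elbow-scale contacts (half-max
#'   radius ~1.5 sensels) are erased entirely by the 3 x 3 opening.
#' @param posture posture label, or `NULL` to skip the band filter.
#' @param grid_shape grid dimensions the regions live on.
#' @param raw_frame optional frame to recompute mean pressures from after
#'   opening.
#' @return filtered list of `body_region`s.
#' @export
filter_regions <- function(regions, min_area = 8, posture = NULL,
                           grid_shape = c(64L, 32L), raw_frame = NULL) {
  brush <- EBImage::makeBrush(3, "box")
  keep <- list()
  for (reg in regions) {
    mask <- matrix(0, grid_shape[1], grid_shape[2])
    mask[reg$pixels] <- 1
    opened <- EBImage::opening(mask, brush)
    idx <- which(opened > 0)
    if (length(idx) < min_area) next
    pix <- cbind(row = ((idx - 1L) %% grid_shape[1]) + 1L,
                 col = ((idx - 1L) %/% grid_shape[1]) + 1L)
    raw <- if (is.null(raw_frame)) NULL else as_frame(raw_frame)$values
    reg2 <- if (is.null(raw)) {
      r <- reg
      r$pixels <- pix
      r$centroid <- c(row = mean(pix[, 1]), col = mean(pix[, 2]))
      r
    } else {
      new_region(pix, raw, reg$label)
    }
    if (!is.null(posture)) {
      fr <- reg2$centroid[["row"]] / grid_shape[1]
      ok <- any(vapply(TEMPLATE_BANDS,
                       function(b) fr >= b[1] && fr <= b[2], logical(1)))
      if (!ok) next
    }
    keep[[length(keep) + 1]] <- reg2
  }
  keep
}

#' Label detected regions by spatial relations
#'
#' Assigns anatomical labels by the template of a lying body, assuming the
#' patient's position and orientation on the mattress are stable: the topmost
#' region is the head; the bottommost one or two are the feet (supine gets
#' two, split left/right about the body-axis column; lateral postures get the
#' single loaded foot); of the rest, the region nearest the 0.55 R row is the
#' sacrum; remaining regions in the shoulder band become shoulders, split (or
#' sided, for lateral postures) the same way. Anything left is `unlabelled`.
#' Left/right are image-frame.
#'
#' @param regions list of `body_region`s.
#' @param posture `"supine"`, `"left_lateral"` or `"right_lateral"`.
#' @param grid_shape grid dimensions.
#' @return the regions with `label` fields assigned.
#' @export
label_regions <- function(regions, posture, grid_shape = c(64L, 32L)) {
  posture <- match.arg(posture, POSTURE_LEVELS)
  n <- length(regions)
  if (n == 0) return(list())
  rows <- vapply(regions, function(r) r$centroid[["row"]], numeric(1))
  cols <- vapply(regions, function(r) r$centroid[["col"]], numeric(1))
  ord <- order(rows)
  labels <- rep("unlabelled", n)
  axis_col <- mean(cols)
  R <- grid_shape[1]

  labels[ord[1]] <- "head"
  assigned <- rep(FALSE, n); assigned[ord[1]] <- TRUE

  # feet: bottommost region(s), required to sit in the feet band so that a
  # missing foot does not pull the sacrum into the feet label
  n_feet <- if (posture == "supine") 2L else 1L
  bottom <- rev(ord)[!rev(ord) %in% which(assigned)]
  bottom <- bottom[rows[bottom] >= 0.75 * R]
  bottom <- head(bottom, n_feet)
  if (posture == "supine") {
    for (i in bottom) {
      labels[i] <- if (cols[i] <= axis_col) "left_foot" else "right_foot"
      assigned[i] <- TRUE
    }
    if (length(bottom) == 2 && labels[bottom[1]] == labels[bottom[2]]) {
      # both on one side of the axis: split by relative order
      sides <- order(cols[bottom])
      labels[bottom[sides[1]]] <- "left_foot"
      labels[bottom[sides[2]]] <- "right_foot"
    }
  } else if (length(bottom) == 1) {
    labels[bottom] <- if (posture == "left_lateral") "left_foot" else "right_foot"
    assigned[bottom] <- TRUE
  }
  assigned[bottom] <- TRUE

  # sacrum: nearest to the 0.55 R band centre among the rest
  rest <- which(!assigned)
  if (length(rest) > 0) {
    sac <- rest[which.min(abs(rows[rest] - 0.55 * R))]
    if (abs(rows[sac] - 0.55 * R) <= 0.15 * R) {
      labels[sac] <- "sacrum"; assigned[sac] <- TRUE
    }
  }

  # shoulders: remaining regions in the shoulder band
  rest <- which(!assigned & rows >= TEMPLATE_BANDS$shoulders[1] * R &
                  rows <= TEMPLATE_BANDS$shoulders[2] * R)
  if (posture == "supine") {
    for (i in rest) {
      labels[i] <- if (cols[i] <= axis_col) "left_shoulder" else "right_shoulder"
      assigned[i] <- TRUE
    }
    if (length(rest) == 2 && labels[rest[1]] == labels[rest[2]]) {
      sides <- order(cols[rest])
      labels[rest[sides[1]]] <- "left_shoulder"
      labels[rest[sides[2]]] <- "right_shoulder"
    }
  } else if (length(rest) > 0) {
    i <- rest[which.min(rows[rest])]
    labels[i] <- if (posture == "left_lateral") "left_shoulder" else "right_shoulder"
    assigned[i] <- TRUE
  }

  for (i in seq_len(n)) regions[[i]]$label <- labels[i]
  regions
}

# One frame through the detection chain; shared by track_regions and the CLI.
# Maxima are sought on the enhanced frame (stable against sensor noise);
# regions are grown and measured on the raw frame, where landmark bumps are
# steepest, so neighbouring landmarks do not merge at the half-maximum level
# and pressures stay physical.
detect_regions <- function(frame, posture, min_height = 20, rel_level = 0.5,
                           min_area = 8) {
  enh <- enhance_chain(frame)
  gf <- gradient_field(enh)
  maxima <- find_maxima(gf, enh, min_height = min_height)
  regions <- grow_regions(frame, maxima, rel_level = rel_level)
  regions <- filter_regions(regions, min_area = min_area, posture = posture,
                            grid_shape = dim(as_frame(frame)$values),
                            raw_frame = frame)
  label_regions(regions, posture, grid_shape = dim(as_frame(frame)$values))
}
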