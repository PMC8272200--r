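#' HOG descriptor configuration
#'
#' Defaults are sized so that a 64 x 32 sensel frame, upsampled x4 to
#' 256 x 128, yields a 32 x 16 grid of 8 x 8 cells and 31 x 15 overlapping
#' 2 x 2-cell blocks — a 14,880-element descriptor with plenty of spatial
#' structure for posture discrimination.
#'
#' @param orientations number of (unsigned) orientation bins over 0..180
#'   degrees; >= 2.
#' @param cell sensels per cell side.
#' @param block cells per block side.
#' @param upsample integer zoom factor (bilinear) applied before gradients.
#' @return a `hog_config`.
#' @export
hog_config <- function(orientations = 8, cell = 8, block = 2, upsample = 4) {
  stopifnot(orientations >= 2, cell >= 1, block >= 1, upsample >= 1)
  structure(list(orientations = as.integer(orientations),
                 cell = as.integer(cell), block = as.integer(block),
                 upsample = as.integer(upsample)),
            class = "hog_config")
}

#' Crop the sacrum band from a frame
#'
#' Returns the fixed fractional window of rows `[0.45 R, 0.65 R)` (the pelvis
#' band; rows 28..40 in 0-based terms on a 64-row grid) over all columns.
#' The sacrum carries the highest pressure-injury risk in lying postures and
#' stays in mattress contact in supine and both lateral poses, which makes
#' this band a candidate minimal feature region. Cropping a crop re-applies
#' the fractions to the smaller grid (the operation is not idempotent).
#'
#' @param frame a [pressure_frame()] or matrix.
#' @param row_frac numeric length-2 fractional row window.
#' @return the cropped [pressure_frame()].
#' @export
crop_sacrum <- function(frame, row_frac = c(0.45, 0.65)) {
  frame <- as_frame(frame)
  R <- nrow(frame$values)
  rows <- (floor(row_frac[1] * R) + 1):floor(row_frac[2] * R)
  pressure_frame(frame$values[rows, , drop = FALSE],
                 timestamp = frame$timestamp, sensor_max = frame$sensor_max)
}

#' Extract histogram-of-oriented-gradients features from a frame
#'
#' Standard HOG: the frame is bilinearly upsampled, per-sensel gradients are
#' taken by central differences, gradient magnitudes are accumulated into
#' per-cell histograms of unsigned orientation (hard assignment), and
#' overlapping blocks of cells are L2-normalized and concatenated. A constant
#' frame has zero gradients everywhere and maps to the all-zero vector
#' (normalization is guarded). Because blocks are normalized, the descriptor
#' is invariant to multiplying the frame by a positive constant.
#'
#' @param frame a [pressure_frame()] or matrix.
#' @param config a [hog_config()].
#' @return numeric feature vector of fixed length
#'   `(nR - block + 1) * (nC - block + 1) * block^2 * orientations`, where
#'   `nR, nC` are the cell-grid dimensions.
#' @export
extract_hog <- function(frame, config = hog_config()) {
  m <- as_frame(frame)$values
  if (config$upsample > 1) {
    m <- EBImage::resize(m, w = nrow(m) * config$upsample,
                         h = ncol(m) * config$upsample)
  }
  cs <- config$cell
  nR <- nrow(m) %/% cs; nC <- ncol(m) %/% cs
  if (nR < 1 || nC < 1) stop("frame (after upsampling) smaller than one cell")
  m <- m[seq_len(nR * cs), seq_len(nC * cs), drop = FALSE]

  g <- pracma::gradient(m)
  mag <- sqrt(g$X^2 + g$Y^2)
  ang <- atan2(g$Y, g$X) %% pi                       # unsigned orientation
  nb <- config$orientations
  bin <- pmin(floor(ang / (pi / nb)), nb - 1) + 1L

  row_cell <- (row(m) - 1L) %/% cs
  col_cell <- (col(m) - 1L) %/% cs
  cell_id <- row_cell + nR * col_cell                # 0-based, column-major cells
  group <- cell_id * nb + (bin - 1L)                 # cell x orientation bucket
  hist_flat <- numeric(nR * nC * nb)
  acc <- rowsum(as.numeric(mag), group = as.integer(group))
  hist_flat[as.integer(rownames(acc)) + 1L] <- acc
  H <- array(hist_flat, dim = c(nb, nR, nC))         # [bin, cell_row, cell_col]

  bk <- config$block
  nBr <- nR - bk + 1L; nBc <- nC - bk + 1L
  if (nBr < 1 || nBc < 1) stop("cell grid smaller than one block")
  blen <- bk * bk * nb
  blocks <- matrix(0, blen, nBr * nBc)
  k <- 0L
  for (bc in seq_len(nBc)) {
    for (br in seq_len(nBr)) {
      k <- k + 1L
      blocks[, k] <- as.numeric(H[, br:(br + bk - 1L), bc:(bc + bk - 1L)])
    }
  }
  # L2 normalization with an epsilon tied to the frame's strongest block, so
  # near-empty blocks (sensor noise over bare mattress) are damped toward
  # zero instead of being amplified to unit vectors; tying it to the frame
  # keeps the descriptor invariant to positive rescaling of the frame.
  norms <- sqrt(colSums(blocks^2))
  eps <- 0.02 * max(norms)
  if (eps > 0) {
    blocks <- sweep(blocks, 2, sqrt(norms^2 + eps^2), `/`)
  }
  as.numeric(blocks)
}
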