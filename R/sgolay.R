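#' Savitzky-Golay smoothing weights from the least-squares definition
#'
#' The Savitzky-Golay filter fits, in each window of `2M + 1` samples centred
#' at `n = 0`, a polynomial of order `degree` by least squares and takes the
#' fitted value at the window centre. Because the normal equations
#' `a = (A'A)^{-1} A' x` are linear in the samples, the centre evaluation is
#' a fixed linear combination of the window: this function returns those
#' weights, i.e. the first row of `(A'A)^{-1} A'` with the Vandermonde design
#' matrix `A` built on abscissae `-M .. M`.
#'
#' The weights always sum to 1 (a degree-0 signal is reproduced exactly) and
#' are symmetric about the centre. Odd-degree basis columns are orthogonal to
#' the centre evaluation on a symmetric window, so degree `2k + 1` gives the
#' same weights as degree `2k`.
#'
#' @param degree polynomial order `k`, `0 <= degree <= 2M`.
#' @param half_window half window `M` (window length `2M + 1`), `M >= 1`.
#' @return numeric weight vector of length `2M + 1`.
#' @examples
#' sg_impulse_response(0, 1)     # the 3-point moving average
#' sg_impulse_response(2, 2) * 35  # the classic (-3, 12, 17, 12, -3)
#' @export
sg_impulse_response <- function(degree, half_window) {
  spec <- sg_filter_spec(degree, half_window)
  spec$impulse_response
}

#' Construct a Savitzky-Golay filter specification
#'
#' Precomputes everything the smoother needs for a given `(degree, M)`: the
#' Vandermonde design matrix on `-M .. M`, the centre-evaluation impulse
#' response, and the full projection (hat) matrix used for the polynomial
#' boundary rule.
#'
#' @inheritParams sg_impulse_response
#' @return an `sg_filter_spec` with fields `degree`, `half_window`,
#'   `impulse_response`, `design_matrix`, `projection` and `window` (length
#'   `2M + 1`).
#' @export
sg_filter_spec <- function(degree = 2, half_window = 16) {
  degree <- as.integer(degree); M <- as.integer(half_window)
  if (M < 1) stop("half_window must be >= 1")
  if (degree < 0) stop("degree must be >= 0")
  if (degree > 2 * M) {
    stop("degree must not exceed 2 * half_window (least-squares system unsolvable)")
  }
  n <- -M:M
  A <- outer(n, 0:degree, `^`)             # Vandermonde on the window
  AtA_inv_At <- solve(crossprod(A), t(A))  # (A'A)^{-1} A'
  h <- AtA_inv_At[1, ]                     # fitted polynomial at n = 0
  structure(list(
    degree = degree, half_window = M, window = 2L * M + 1L,
    impulse_response = h,
    design_matrix = A,
    projection = A %*% AtA_inv_At          # hat matrix, for boundary windows
  ), class = "sg_filter_spec")
}

#' @export
print.sg_filter_spec <- function(x, ...) {
  cat(sprintf("<sg_filter_spec> degree %d, window %d (M = %d)\n",
              x$degree, x$window, x$half_window))
  invisible(x)
}

#' Smooth a 1-D signal with a Savitzky-Golay filter
#'
#' Interior samples are the discrete convolution of the signal with the
#' centre-evaluation impulse response. Boundary samples (the first and last
#' `M` positions, where the centred window does not fit) are handled per
#' `boundary`:
#'
#' * `"polynomial"` (default): fit the edge window's least-squares polynomial
#'   once and evaluate it at the off-centre positions — i.e. apply the
#'   corresponding rows of the projection matrix to the first/last window.
#'   This avoids the spurious edge spikes that zero padding would create in
#'   the trend-deviation statistic.
#' * `"none"`: leave boundary samples equal to the input.
#'
#' @param signal numeric vector, length at least `2M + 1`.
#' @param spec an [sg_filter_spec()] (or it is built from `degree`/`half_window`).
#' @param boundary `"polynomial"` or `"none"`.
#' @param degree,half_window used only when `spec` is `NULL`.
#' @return smoothed numeric vector, same length as `signal`.
#' @export
sg_smooth <- function(signal, spec = NULL, boundary = c("polynomial", "none"),
                      degree = 2, half_window = 16) {
  boundary <- match.arg(boundary)
  if (is.null(spec)) spec <- sg_filter_spec(degree, half_window)
  M <- spec$half_window
  L <- length(signal)
  if (L < spec$window) {
    stop(sprintf("signal length %d shorter than filter window %d", L, spec$window))
  }
  out <- as.numeric(stats::filter(signal, spec$impulse_response,
                                  method = "convolution", sides = 2))
  if (M > 0) {
    if (boundary == "polynomial") {
      first <- spec$projection %*% signal[1:(2 * M + 1)]
      last <- spec$projection %*% signal[(L - 2 * M):L]
      out[1:M] <- first[1:M]
      out[(L - M + 1):L] <- last[(M + 2):(2 * M + 1)]
    } else {
      out[1:M] <- signal[1:M]
      out[(L - M + 1):L] <- signal[(L - M + 1):L]
    }
  }
  out
}

#' Unfold a pressure frame into 1-D signals
#'
#' The trend decomposition treats the 2-D pressure image as a set of 1-D
#' signals. `"columns"` mode (default) yields one signal per sensor column,
#' running head-to-foot — matching how the bed's long axis exposes the body
#' trend; `"unfolded"` mode concatenates the frame row-major into a single
#' signal.
#'
#' @param frame a [pressure_frame()] or numeric matrix.
#' @param line_axis `"columns"` or `"unfolded"`.
#' @return list of numeric vectors.
#' @export
extract_lines <- function(frame, line_axis = c("columns", "unfolded")) {
  line_axis <- match.arg(line_axis)
  m <- as_frame(frame)$values
  if (line_axis == "columns") {
    lapply(seq_len(ncol(m)), function(j) m[, j])
  } else {
    list(as.numeric(t(m)))  # row-major concatenation
  }
}

# Inverse of extract_lines: reassemble a matrix of the given shape.
assemble_lines <- function(lines, grid_shape, line_axis) {
  if (line_axis == "columns") {
    do.call(cbind, lines)
  } else {
    matrix(lines[[1]], nrow = grid_shape[1], ncol = grid_shape[2], byrow = TRUE)
  }
}
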