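#' Specify a frame-enhancement filter
#'
#' Two smoothers are supported for denoising cleaned frames: an isotropic
#' Gaussian (better body silhouettes for visualization) and a separable 2-D
#' Savitzky-Golay filter (preserves local maxima/minima, hence better for
#' quantitative analysis). An even SG window cannot be symmetric about a
#' centre sample, so even values are normalized up to the next odd window
#' (the reference setting "degree 2, window 6" becomes window 7, M = 3).
#'
#' @param method `"gaussian"` or `"savitzky_golay_2d"`.
#' @param sigma Gaussian standard deviation, sensels.
#' @param degree,window SG polynomial degree and window length (odd).
#' @return an `enhancement_spec`.
#' @export
enhancement_spec <- function(method = c("gaussian", "savitzky_golay_2d"),
                             sigma = 1.4, degree = 2, window = 7) {
  method <- match.arg(method)
  if (method == "gaussian") {
    if (sigma <= 0) stop("sigma must be positive")
  } else {
    window <- as.integer(window)
    if (window %% 2 == 0) {
      window <- window + 1L
      message("even SG window normalized to ", window)
    }
    if (window <= degree) stop("SG window must exceed the polynomial degree")
  }
  structure(list(method = method, sigma = sigma, degree = degree,
                 window = window),
            class = "enhancement_spec")
}

# Reflect-pad a matrix by k samples on every side.
pad_reflect <- function(m, k) {
  ri <- c(rev(seq_len(k) + 1L), seq_len(nrow(m)), nrow(m) - seq_len(k))
  ci <- c(rev(seq_len(k) + 1L), seq_len(ncol(m)), ncol(m) - seq_len(k))
  m[ri, ci, drop = FALSE]
}

# Separable convolution with a symmetric 1-D kernel, reflect boundary.
conv_separable <- function(m, kern) {
  k <- (length(kern) - 1L) / 2L
  n_r <- nrow(m); n_c <- ncol(m)
  p <- pad_reflect(m, k)
  out <- matrix(0, n_r, ncol(p))          # convolve down the rows
  for (a in seq_along(kern)) {
    out <- out + kern[a] * p[a:(a + n_r - 1), , drop = FALSE]
  }
  res <- matrix(0, n_r, n_c)              # then across the columns
  for (a in seq_along(kern)) {
    res <- res + kern[a] * out[, a:(a + n_c - 1), drop = FALSE]
  }
  res
}

#' Enhance (denoise) a pressure frame
#'
#' Gaussian mode convolves with a normalized isotropic kernel (radius
#' `ceiling(3.5 * sigma)`) under a reflect boundary; the separable SG mode
#' applies the verified 1-D Savitzky-Golay smoother along every row, then
#' every column, with polynomial boundary handling. The output is clipped to
#' `[0, sensor_max]`.
#'
#' @param frame a [pressure_frame()] or matrix.
#' @param spec an [enhancement_spec()].
#' @return the enhanced [pressure_frame()].
#' @export
enhance <- function(frame, spec = enhancement_spec()) {
  frame <- as_frame(frame)
  m <- frame$values
  if (spec$method == "gaussian") {
    k <- ceiling(3.5 * spec$sigma)
    if (2 * k + 1 > min(dim(m))) stop("Gaussian kernel larger than the frame")
    kern <- exp(-((-k:k)^2) / (2 * spec$sigma^2))
    kern <- kern / sum(kern)
    out <- conv_separable(m, kern)
  } else {
    M <- (spec$window - 1L) / 2L
    if (spec$window > min(dim(m))) stop("SG window larger than the frame")
    sgspec <- sg_filter_spec(spec$degree, M)
    out <- apply(m, 2, sg_smooth, spec = sgspec)            # along columns
    out <- t(apply(out, 1, sg_smooth, spec = sgspec))       # along rows
  }
  out <- pmin(pmax(out, 0), frame$sensor_max)
  pressure_frame(out, timestamp = frame$timestamp,
                 sensor_max = frame$sensor_max)
}

#' Default enhancement chain
#'
#' The pipeline's standard polish before detection: separable Savitzky-Golay
#' (degree 2, window 7) to suppress sensor noise while keeping local extrema,
#' then a Gaussian of sigma 1.4 sensels for a smooth silhouette.
#'
#' @param frame a [pressure_frame()] or matrix.
#' @return the enhanced [pressure_frame()].
#' @export
enhance_chain <- function(frame) {
  f <- enhance(frame, enhancement_spec("savitzky_golay_2d", degree = 2, window = 7))
  enhance(f, enhancement_spec("gaussian", sigma = 1.4))
}
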