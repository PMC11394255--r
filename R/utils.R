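# Shared geometry and numeric helpers.
#
# Angle convention used throughout the package: theta is measured in radians
# CLOCKWISE from image-up ("12 o'clock"), so theta = pi/2 points right
# (3 o'clock) and theta = pi points down (6 o'clock). In (row, col) matrix
# coordinates (row 1 at the top) the unit direction is
# (drow, dcol) = (-cos(theta), sin(theta)).

#' Uniform clock-angle grid
#'
#' @param n_angles number of angles.
#' @return numeric vector of `n_angles` angles in `[0, 2*pi)`, clockwise from
#'   12 o'clock.
#' @keywords internal
angle_grid <- function(n_angles) {
  2 * pi * (seq_len(n_angles) - 1) / n_angles
}

# (drow, dcol) unit direction for clock angle theta
angle_direction <- function(theta) {
  cbind(drow = -cos(theta), dcol = sin(theta))
}

# clock angle of displacement (drow, dcol), in [0, 2*pi)
displacement_angle <- function(drow, dcol) {
  atan2(dcol, -drow) %% (2 * pi)
}

#' Round half away from zero
#'
#' Decimal rounding with halves going up (7.865 -> 7.87), the convention used
#' for report parity with printed clinical tables; base `round()` rounds half
#' to even. A tiny epsilon guards against binary representation of decimal
#' halves.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Bilinear interpolation on a matrix
#'
#' Samples `img` at real-valued (row, col) positions. Positions are clamped to
#' the image domain. If `mask` is supplied, interpolation weights are
#' restricted to pixels where `mask` is TRUE and renormalized, so values
#' outside the mask never bleed into the sample; points with no masked pixel
#' in their 2x2 neighbourhood return NA.
#'
#' @param img numeric matrix.
#' @param row,col equal-length numeric vectors of positions (1-based).
#' @param mask optional logical matrix of the same shape as `img`.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, row, col, mask = NULL) {
  h <- nrow(img)
  w <- ncol(img)
  row <- pmin(pmax(row, 1), h)
  col <- pmin(pmax(col, 1), w)
  r0 <- pmin(floor(row), h - 1L)
  c0 <- pmin(floor(col), w - 1L)
  fr <- row - r0
  fc <- col - c0
  i00 <- cbind(r0, c0)
  i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1)
  i11 <- cbind(r0 + 1, c0 + 1)
  w00 <- (1 - fr) * (1 - fc)
  w10 <- fr * (1 - fc)
  w01 <- (1 - fr) * fc
  w11 <- fr * fc
  if (!is.null(mask)) {
    w00 <- w00 * mask[i00]
    w10 <- w10 * mask[i10]
    w01 <- w01 * mask[i01]
    w11 <- w11 * mask[i11]
  }
  tot <- w00 + w10 + w01 + w11
  val <- w00 * img[i00] + w10 * img[i10] + w01 * img[i01] + w11 * img[i11]
  out <- val / tot
  out[tot == 0] <- NA_real_
  out
}

# circular moving average with odd window
circular_smooth <- function(x, window) {
  if (window <= 1) return(x)
  stopifnot(window %% 2 == 1, window < length(x))
  half <- (window - 1) / 2
  n <- length(x)
  idx <- outer(seq_len(n), -half:half, "+")
  idx <- ((idx - 1) %% n) + 1
  rowMeans(matrix(x[idx], nrow = n))
}

# rotate a matrix 90 degrees clockwise (row 1 on top convention)
rotate90_cw <- function(m) {
  t(m[nrow(m):1, , drop = FALSE])
}
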