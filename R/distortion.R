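# Radial + tangential lens distortion by forward pixel remapping.

#' Distortion coefficients
#'
#' @param p1,p2 Radial distortion coefficients.
#' @param p3,p4 Tangential distortion coefficients.
#' @return An object of class `crt_distortion`.
#' @export
distortion_coefficients <- function(p1 = 0, p2 = 0, p3 = 0, p4 = 0) {
  v <- c(p1, p2, p3, p4)
  if (any(!is.finite(v))) stop("distortion coefficients must be finite")
  structure(list(p1 = p1, p2 = p2, p3 = p3, p4 = p4),
            class = "crt_distortion")
}

#' Pixel displacement under the distortion model
#'
#' For a pixel at centered coordinates `(u, v)` (principal point at the
#' image center) with `r^2 = u^2 + v^2`:
#' `du = u (p1 r^2 + p2 r^4) + 2 p3 u v + p4 (r^2 + 2 u^2)` and
#' `dv = v (p1 r^2 + p2 r^4) + 2 p4 u v + p3 (r^2 + 2 v^2)`.
#'
#' @param u,v Centered pixel coordinates (vectorized).
#' @param coeffs A [distortion_coefficients()].
#' @return `list(du=, dv=)`.
#' @export
distortion_shift <- function(u, v, coeffs) {
  r2 <- u^2 + v^2
  rad <- coeffs$p1 * r2 + coeffs$p2 * r2^2
  list(du = u * rad + 2 * coeffs$p3 * u * v + coeffs$p4 * (r2 + 2 * u^2),
       dv = v * rad + 2 * coeffs$p4 * u * v + coeffs$p3 * (r2 + 2 * v^2))
}

#' Apply lens distortion to a raster
#'
#' Forward remap: every source pixel moves by its [distortion_shift()],
#' the destination is rounded to the nearest pixel, unfilled destinations
#' keep the `background` value (producing the characteristic dark gaps
#' around the border for barrel parameters), and collisions resolve by
#' last write in row-major order. With all coefficients zero the output is
#' bitwise identical to the input. Works on band images and label maps
#' alike.
#'
#' @param image `H x W` matrix.
#' @param coeffs A [distortion_coefficients()].
#' @param background Fill value for unmapped destination pixels.
#' @return Distorted `H x W` matrix.
#' @export
apply_distortion <- function(image, coeffs, background = 0) {
  stopifnot(is.matrix(image), inherits(coeffs, "crt_distortion"))
  if (coeffs$p1 == 0 && coeffs$p2 == 0 && coeffs$p3 == 0 && coeffs$p4 == 0) {
    return(image)
  }
  H <- nrow(image); W <- ncol(image)
  # row-major traversal so later (row, col) writes win collisions
  col <- rep(seq_len(W), times = H)
  row <- rep(seq_len(H), each = W)
  u <- col - (W + 1) / 2
  v <- row - (H + 1) / 2
  sh <- distortion_shift(u, v, coeffs)
  dc <- round(col + sh$du)
  dr <- round(row + sh$dv)
  ok <- dc >= 1 & dc <= W & dr >= 1 & dr <= H
  out <- matrix(background, H, W)
  out[cbind(dr[ok], dc[ok])] <- image[cbind(row[ok], col[ok])]
  out
}
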