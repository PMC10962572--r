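#' Orientation angles and eigenvector frames
#'
#' The shared eigenvector frame of both compartments is charted by three
#' angles: `theta`, the polar angle of the primary axis u1 from the z-axis;
#' `phi`, the azimuth of u1 in the xy-plane; and `alpha`, the rotation of
#' the cross-section axes (u2, u3) about u1. The `alpha = 0` reference for
#' u2 is u1 rotated by 90 degrees about the z-axis, projected onto the
#' plane perpendicular to u1 and normalised; at the pole (u1 parallel to z)
#' that projection vanishes and the y-axis is used instead. Any fixed
#' convention gives the same model family; this one is documented and
#' invertible.
#'
#' @param theta,phi,alpha angles in radians.
#' @return `angles_to_frame`: a 3x3 matrix with columns u1, u2, u3
#'   (orthonormal, right-handed). `frame_to_angles`: a named numeric vector
#'   `c(theta, phi, alpha)` such that `angles_to_frame` reproduces the
#'   frame.
#' @examples
#' R <- angles_to_frame(pi / 3, 0.4, -0.2)
#' crossprod(R)  # identity
#' @export
angles_to_frame <- function(theta, phi, alpha) {
  u1 <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  ref <- .alpha_reference(u1)
  u2 <- cos(alpha) * ref$v1 + sin(alpha) * ref$v2
  u3 <- .cross3(u1, u2)
  cbind(u1 = u1, u2 = u2, u3 = u3)
}

# Reference pair (v1, v2) spanning the plane perpendicular to u1, with
# v2 = u1 x v1, so u2(alpha) = cos(a) v1 + sin(a) v2.
.alpha_reference <- function(u1) {
  w <- c(-u1[2], u1[1], u1[3])          # u1 rotated 90 deg about z
  w <- w - sum(w * u1) * u1             # project off u1
  n <- sqrt(sum(w^2))
  if (n < 1e-8) {                       # pole: u1 ~ +/- z
    w <- c(0, 1, 0) - sum(c(0, 1, 0) * u1) * u1
    n <- sqrt(sum(w^2))
  }
  v1 <- w / n
  list(v1 = v1, v2 = .cross3(u1, v1))
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @rdname angles_to_frame
#' @param frame a 3x3 matrix with orthonormal columns u1, u2, u3.
#' @export
frame_to_angles <- function(frame) {
  u1 <- frame[, 1]; u2 <- frame[, 2]
  theta <- acos(clamp(u1[3], -1, 1))
  phi <- if (abs(sin(theta)) < 1e-12) 0 else atan2(u1[2], u1[1])
  ref <- .alpha_reference(c(sin(theta) * cos(phi), sin(theta) * sin(phi),
                            cos(theta)))
  alpha <- atan2(sum(u2 * ref$v2), sum(u2 * ref$v1))
  c(theta = theta, phi = phi, alpha = alpha)
}
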