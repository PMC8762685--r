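#' Synthetic rabbit-like silhouette
#'
#' A closed "body plus ears" contour built parametrically: an elliptical body
#' with two narrow Gaussian ear lobes added to the radius near the top. It is
#' a stand-in natural-shape target in the spirit of an animal silhouette -- a
#' recognizable part structure (one elongated blob, two thin protrusions)
#' whose exact radial-frequency representation needs many more than 10
#' frequencies. It is entirely synthetic and reproduces no published asset.
#'
#' @param n_points number of contour points (default 360).
#' @param body_a,body_b ellipse semi-axes in pixels (default 28 and 18).
#' @param ear_height ear lobe height in pixels (default 26).
#' @param ear_width ear angular half-width in radians (default 0.09).
#' @param ear_angles ear center angles in degrees (default 70 and 105).
#' @return A `shape_contour` with `source = "rabbit-synthetic"`.
#' @export
rabbit_silhouette <- function(n_points = 360L, body_a = 28, body_b = 18,
                              ear_height = 26, ear_width = 0.09,
                              ear_angles = c(70, 105)) {
  theta <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  # radius of an axis-aligned ellipse in polar form
  r <- body_a * body_b / sqrt((body_b * cos(theta))^2 + (body_a * sin(theta))^2)
  for (a0 in ear_angles * pi / 180) {
    d <- atan2(sin(theta - a0), cos(theta - a0))  # wrapped angular offset
    r <- r + ear_height * exp(-(d / ear_width)^2 / 2)
  }
  shape_contour(cbind(x = r * cos(theta), y = r * sin(theta)),
                source = "rabbit-synthetic", base_radius = mean(r))
}
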