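#' Shape synthesis settings
#'
#' @param base_radius base circle radius in pixels (default 30).
#' @param n_points number of contour samples over one revolution (default 360).
#' @param amp_scale pixels per amplitude unit (default `base_radius / 100`, so
#'   an amplitude of 100 modulates the radius by one full base radius).
#' @param canvas raster canvas side length in pixels (default 128).
#' @return An object of class `rf_synth_config`.
#' @export
synth_config <- function(base_radius = 30, n_points = 360L,
                         amp_scale = base_radius / 100, canvas = 128L) {
  if (!is_scalar_num(base_radius) || base_radius <= 0) stopf("base_radius must be > 0")
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 32L) stopf("n_points must be >= 32")
  if (!is_scalar_num(amp_scale) || amp_scale <= 0) stopf("amp_scale must be > 0")
  canvas <- as.integer(canvas)
  if (is.na(canvas) || canvas < 8L) stopf("canvas must be >= 8 pixels")
  structure(list(base_radius = base_radius, n_points = n_points,
                 amp_scale = amp_scale, canvas = canvas),
            class = "rf_synth_config")
}

#' Closed shape contours
#'
#' A contour is an ordered list of planar points in pixel units, implicitly
#' closed (the last point connects back to the first). Consecutive duplicate
#' points are dropped.
#'
#' @param points two-column numeric matrix of (x, y) coordinates.
#' @param source id of the generating genome, or `"silhouette"`.
#' @param base_radius nominal base radius in pixels (may be `NA` for silhouettes).
#' @return An object of class `shape_contour`.
#' @export
shape_contour <- function(points, source = "silhouette", base_radius = NA_real_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || !is.numeric(points))
    stopf("contour points must be a two-column numeric matrix")
  # drop the closing duplicate and any consecutive duplicates
  n <- nrow(points)
  if (n >= 2L && all(points[n, ] == points[1L, ])) points <- points[-n, , drop = FALSE]
  keep <- c(TRUE, rowSums(abs(diff(points))) > 0)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 3L) stopf("contour needs at least 3 distinct points")
  structure(list(points = points, source = source, base_radius = base_radius),
            class = "shape_contour")
}

#' @export
print.shape_contour <- function(x, ...) {
  pa <- perimeter_area(x)
  cat(sprintf("shape contour <%s>: %d points, perimeter %.1f px, area %.1f px^2\n",
              x$source, nrow(x$points), pa[["perimeter"]], pa[["area"]]))
  invisible(x)
}

#' Synthesize the contour of an RF genome
#'
#' Samples the radius function
#' `r(theta) = base_radius + amp_scale * sum_f gate_f * amp_f * sin(f*theta + phase_f)`
#' (phases converted from degrees to radians) at `n_points` equally spaced
#' angles. A negative radius reflects the point through the origin, which is
#' how internal loops arise when the modulation exceeds the base radius.
#'
#' @param g an `rf_genome`.
#' @param cfg a [synth_config()].
#' @return A `shape_contour` whose `source` is the genome id.
#' @export
synthesize_contour <- function(g, cfg = synth_config()) {
  stopifnot(inherits(g, "rf_genome"), inherits(cfg, "rf_synth_config"))
  theta <- 2 * pi * (seq_len(cfg$n_points) - 1L) / cfg$n_points
  amps <- effective_spectrum(g)
  r <- rep(cfg$base_radius, cfg$n_points)
  for (f in which(amps > 0))
    r <- r + cfg$amp_scale * amps[f] * sin(f * theta + g$phases[f] * pi / 180)
  if (max(abs(r)) < 1e-9) stopf("null contour: radius is identically zero")
  shape_contour(cbind(x = r * cos(theta), y = r * sin(theta)),
                source = g$id, base_radius = cfg$base_radius)
}

closed_segments <- function(points) {
  n <- nrow(points)
  j <- c(seq_len(n)[-1L], 1L)
  list(x1 = points[, 1L], y1 = points[, 2L],
       x2 = points[j, 1L], y2 = points[j, 2L], n = n)
}

#' Test whether a closed contour is a simple polygon
#'
#' Checks all non-adjacent segment pairs for proper crossings (strictly
#' opposite orientation signs), vectorized over pairs. Tangential touching at
#' a single point is not counted as a crossing.
#'
#' @param c a `shape_contour`.
#' @return `TRUE` when no two non-adjacent edges cross.
#' @export
is_simple_polygon <- function(c) {
  stopifnot(inherits(c, "shape_contour"))
  s <- closed_segments(c$points)
  n <- s$n
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(s$x1[i], s$y1[i], s$x2[i], s$y2[i], s$x1[j], s$y1[j])
  d2 <- cross(s$x1[i], s$y1[i], s$x2[i], s$y2[i], s$x2[j], s$y2[j])
  d3 <- cross(s$x1[j], s$y1[j], s$x2[j], s$y2[j], s$x1[i], s$y1[i])
  d4 <- cross(s$x1[j], s$y1[j], s$x2[j], s$y2[j], s$x2[i], s$y2[i])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Perimeter and area of a closed contour
#'
#' Perimeter is the sum of consecutive-point Euclidean distances (including
#' the closing segment). For a simple polygon the area is the absolute
#' shoelace sum divided by two; for a self-intersecting contour (e.g. an RF
#' shape with an internal loop) the area falls back to the foreground pixel
#' count of the nonzero-winding filled mask, so loop interiors are counted
#' once.
#'
#' @param c a `shape_contour`.
#' @return Named numeric vector with elements `perimeter` (px) and `area` (px^2).
#' @seealso [curvature_distance()] for the isoperimetric-ratio comparison.
#' @export
perimeter_area <- function(c) {
  stopifnot(inherits(c, "shape_contour"))
  s <- closed_segments(c$points)
  perimeter <- sum(sqrt((s$x2 - s$x1)^2 + (s$y2 - s$y1)^2))
  if (is_simple_polygon(c)) {
    area <- abs(sum(s$x1 * s$y2 - s$x2 * s$y1)) / 2
  } else {
    ctr <- colMeans(c$points)
    ext <- 2 * max(abs(sweep(c$points, 2, ctr))) + 8
    m <- rasterize(c, synth_config(canvas = as.integer(ceiling(ext))), fill = TRUE)
    area <- sum(m$grid) / attr(m, "scale")^2
  }
  c(perimeter = perimeter, area = area)
}

#' Isoperimetric ratio perimeter^2 / area
#'
#' A dimensionless total-curvature index: 4*pi for a circle, larger for every
#' other simple shape, invariant to rigid motion and uniform scaling.
#'
#' @param c a `shape_contour`.
#' @return The ratio as a single number.
#' @export
isoperimetric_ratio <- function(c) {
  pa <- perimeter_area(c)
  unname(pa[["perimeter"]]^2 / pa[["area"]])
}

#' Resample a closed contour by arc length
#'
#' @param c a `shape_contour`.
#' @param n number of output points, equally spaced along the closed perimeter
#'   starting at the first input point.
#' @return A `shape_contour` with `n` points.
#' @export
resample_contour <- function(c, n) {
  stopifnot(inherits(c, "shape_contour"))
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stopf("n must be >= 3")
  p <- rbind(c$points, c$points[1L, ])
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target_s <- total * (seq_len(n) - 1L) / n
  x <- stats::approx(s, p[, 1L], xout = target_s)$y
  y <- stats::approx(s, p[, 2L], xout = target_s)$y
  shape_contour(cbind(x, y), source = c$source, base_radius = c$base_radius)
}

#' Load a silhouette contour from CSV
#'
#' The file lists one `x,y` pair per line (pixel units, no header). An open
#' polyline (first point distinct from the last) is closed automatically, and
#' the contour is resampled to `n_points` equally spaced arc-length positions
#' unless it already has that many points.
#'
#' @param path CSV file path.
#' @param n_points number of points in the returned contour (default 360).
#' @return A `shape_contour` with `source = "silhouette"`.
#' @export
load_silhouette <- function(path, n_points = 360L) {
  raw <- tryCatch(utils::read.table(path, sep = ",", header = FALSE,
                                    colClasses = "numeric"),
                  error = function(e) stopf("cannot parse silhouette %s: %s",
                                            path, conditionMessage(e)))
  if (ncol(raw) != 2L) stopf("silhouette %s must have two columns (x, y)", path)
  if (any(!is.finite(as.matrix(raw)))) stopf("silhouette %s has non-numeric rows", path)
  if (nrow(raw) < 3L) stopf("silhouette %s needs at least 3 points", path)
  c <- shape_contour(as.matrix(raw))
  if (nrow(c$points) == n_points) c else resample_contour(c, n_points)
}
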