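#' Medial-axis skeleton by iterated morphological thinning
#'
#' Zhang-Suen thinning applied to the binary mask until no pixel changes
#' between passes (i.e. the iteration count is effectively unbounded). The
#' result is a 1-px-wide skeleton: a subset of the foreground with no 2x2
#' foreground block.
#'
#' @param m a `shape_mask` with at least one foreground pixel, or a logical
#'   matrix.
#' @return An object of class `skeleton_points`: list with `points` (matrix of
#'   (x, y) = (column, row) raster coordinates) and `dim` (the mask dimensions).
#' @export
skeletonize <- function(m) {
  grid <- if (inherits(m, "shape_mask")) m$grid else m
  if (!is.matrix(grid) || !is.logical(grid)) stopf("mask must be a logical matrix")
  if (!any(grid)) stopf("empty mask: nothing to skeletonize")
  img <- matrix(0L, nrow(grid) + 2L, ncol(grid) + 2L)
  img[2:(nrow(grid) + 1L), 2:(ncol(grid) + 1L)] <- grid * 1L
  nr <- nrow(img); nc <- ncol(img)
  ri <- 2:(nr - 1L); ci <- 2:(nc - 1L)
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p  <- img[ri, ci]
      p2 <- img[ri - 1L, ci]      # north
      p3 <- img[ri - 1L, ci + 1L] # north-east
      p4 <- img[ri, ci + 1L]      # east
      p5 <- img[ri + 1L, ci + 1L] # south-east
      p6 <- img[ri + 1L, ci]      # south
      p7 <- img[ri + 1L, ci - 1L] # south-west
      p8 <- img[ri, ci - 1L]      # west
      p9 <- img[ri - 1L, ci - 1L] # north-west
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      cond <- p == 1L & b >= 2L & b <= 6L & a == 1L
      if (sub == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        inner <- img[ri, ci]
        # a perfectly symmetric terminal cluster can be flagged in its
        # entirety; keep one pixel so the skeleton is never empty
        if (sum(cond) == sum(inner)) cond[which(cond)[1L]] <- FALSE
        if (any(cond)) {
          inner[cond] <- 0L
          img[ri, ci] <- inner
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  core <- img[ri, ci] == 1L
  idx <- which(core, arr.ind = TRUE)
  structure(list(points = cbind(x = idx[, 2L], y = idx[, 1L]),
                 dim = dim(grid)),
            class = "skeleton_points")
}

#' @export
print.skeleton_points <- function(x, ...) {
  cat(sprintf("skeleton: %d points on a %d x %d grid\n",
              nrow(x$points), x$dim[1L], x$dim[2L]))
  invisible(x)
}

#' Skeleton alignment settings
#'
#' @param rotation_step rotation search increment in degrees (default 1).
#' @param allow_reflection also search the mirrored point set (default FALSE).
#' @param center alignment center; only `"centroid"` is supported.
#' @return An object of class `rf_alignment_config`.
#' @export
alignment_config <- function(rotation_step = 1, allow_reflection = FALSE,
                             center = "centroid") {
  if (!is_scalar_num(rotation_step) || rotation_step <= 0 || rotation_step > 90)
    stopf("rotation_step must be in (0, 90] degrees")
  center <- match.arg(center)
  structure(list(rotation_step = rotation_step,
                 allow_reflection = isTRUE(allow_reflection), center = center),
            class = "rf_alignment_config")
}

mean_nn_distance <- function(a, b, b_sq = rowSums(b^2), tb = t(b)) {
  # mean over rows of a of the distance to the nearest row of b
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    matrix(b_sq, nrow(a), nrow(b), byrow = TRUE) - 2 * (a %*% tb)
  mean(sqrt(pmax(apply(d2, 1L, min), 0)))
}

#' Skeleton distance after best rigid alignment
#'
#' Both skeleton point sets are translated to a common centroid; the
#' distractor set is then rotated through the full circle in
#' `cfg$rotation_step` increments (and mirrored as well when
#' `allow_reflection`). For each candidate alignment the mean, over distractor
#' points, of the Euclidean distance to the closest target point is computed;
#' the minimum over the alignment search is returned. The measure is directed
#' (distractor toward target); `symmetric = TRUE` averages both directions.
#'
#' @param distractor,target `skeleton_points` objects (see [skeletonize()]),
#'   or two-column point matrices.
#' @param cfg an [alignment_config()].
#' @param symmetric average the two directed distances (default FALSE).
#' @return Non-negative distance in pixels.
#' @export
skeleton_distance <- function(distractor, target, cfg = alignment_config(),
                              symmetric = FALSE) {
  dp <- if (inherits(distractor, "skeleton_points")) distractor$points else as.matrix(distractor)
  tp <- if (inherits(target, "skeleton_points")) target$points else as.matrix(target)
  if (!nrow(dp) || !nrow(tp)) stopf("skeletons must be non-empty")
  if (symmetric)
    return((skeleton_distance(distractor, target, cfg) +
            skeleton_distance(target, distractor, cfg)) / 2)
  dp <- sweep(dp, 2, colMeans(dp))
  tp <- sweep(tp, 2, colMeans(tp))
  b_sq <- rowSums(tp^2); tb <- t(tp)
  angles <- seq(0, 360 - cfg$rotation_step, by = cfg$rotation_step) * pi / 180
  cands <- list(dp)
  if (cfg$allow_reflection) cands <- c(cands, list(dp %*% diag(c(-1, 1))))
  best <- Inf
  for (pts in cands) {
    for (a in angles) {
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
      d <- mean_nn_distance(pts %*% R, tp, b_sq, tb)
      if (d < best) best <- d
    }
  }
  best
}

#' Total-curvature difference between two shapes
#'
#' Absolute difference of the isoperimetric ratios perimeter^2/area of the
#' two contours; invariant to rigid motion and uniform scaling of either
#' argument.
#'
#' @param a,b `shape_contour` objects.
#' @return Non-negative difference.
#' @export
curvature_distance <- function(a, b) {
  abs(isoperimetric_ratio(a) - isoperimetric_ratio(b))
}

#' Radial Fourier amplitude spectrum of a contour
#'
#' The contour is read as a radius sequence (distance of each point from the
#' contour centroid, in traversal order); the amplitude at frequency f is
#' twice the magnitude of the f-th discrete Fourier coefficient divided by
#' the number of points. With that scaling, a shape synthesized from a genome
#' recovers `amp_scale * amplitude[f]` at each active frequency. The DC term
#' (mean radius) is excluded.
#'
#' @param c a `shape_contour`.
#' @param K highest frequency returned; must satisfy `1 <= K <= n_points - 1`.
#' @return Numeric vector of `K` non-negative amplitudes indexed by frequency.
#' @export
contour_spectrum <- function(c, K = 179L) {
  stopifnot(inherits(c, "shape_contour"))
  n <- nrow(c$points)
  K <- as.integer(K)
  if (is.na(K) || K < 1L || K > n - 1L)
    stopf("K must be between 1 and %d for a %d-point contour", n - 1L, n)
  ctr <- colMeans(c$points)
  r <- sqrt(rowSums(sweep(c$points, 2, ctr)^2))
  ft <- stats::fft(r)
  2 * Mod(ft[2:(K + 1L)]) / n
}

#' L2 distance between amplitude spectra
#'
#' Spectra of unequal length are zero-padded to a common length before the
#' Euclidean norm of the element-wise difference is taken. Satisfies the
#' metric axioms.
#'
#' @param a,b non-negative numeric amplitude vectors.
#' @return Non-negative distance.
#' @export
spectrum_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  sqrt(sum((a - b)^2))
}

#' Coerce a genome or contour to a contour
#'
#' @param x an `rf_genome` or `shape_contour`.
#' @param cfg a [synth_config()] used when synthesis is needed.
#' @return A `shape_contour`.
#' @export
as_contour <- function(x, cfg = synth_config()) {
  if (inherits(x, "shape_contour")) return(x)
  if (inherits(x, "rf_genome")) return(synthesize_contour(x, cfg))
  stopf("cannot interpret object of class '%s' as a shape", class(x)[1L])
}

#' Target-distractor distance under a chosen parameterization
#'
#' One entry point for the three similarity parameterizations used to analyze
#' evolution: `"skeleton"` (mean nearest-point distance between thinned
#' skeletons after best rigid alignment), `"curvature"` (difference of
#' perimeter^2/area), and `"spectrum"` (L2 distance between radial Fourier
#' amplitude spectra). Inputs may be genomes or contours.
#'
#' @param a,b `rf_genome` or `shape_contour` objects (a = distractor,
#'   b = target for the directed skeleton measure).
#' @param metric one of `"skeleton"`, `"curvature"`, `"spectrum"`.
#' @param cfg a [synth_config()].
#' @param align an [alignment_config()] for the skeleton metric.
#' @param K spectrum length for the spectrum metric.
#' @param normalize_scale rescale both shapes to unit mean radius before the
#'   skeleton metric (needed when stimuli are size-jittered); default FALSE
#'   since evolved stimuli share one base radius.
#' @return Non-negative distance.
#' @export
shape_distance <- function(a, b, metric = c("spectrum", "skeleton", "curvature"),
                           cfg = synth_config(), align = alignment_config(),
                           K = 179L, normalize_scale = FALSE) {
  metric <- match.arg(metric)
  ca <- as_contour(a, cfg); cb <- as_contour(b, cfg)
  switch(metric,
    spectrum = {
      Kmax <- min(K, nrow(ca$points) - 1L, nrow(cb$points) - 1L)
      spectrum_distance(contour_spectrum(ca, Kmax), contour_spectrum(cb, Kmax))
    },
    curvature = curvature_distance(ca, cb),
    skeleton = {
      if (normalize_scale) {
        ca <- rescale_to_unit_radius(ca, cfg$base_radius)
        cb <- rescale_to_unit_radius(cb, cfg$base_radius)
      }
      skeleton_distance(skeletonize(rasterize(ca, cfg, fill = TRUE)),
                        skeletonize(rasterize(cb, cfg, fill = TRUE)),
                        align)
    })
}

rescale_to_unit_radius <- function(c, base_radius) {
  ctr <- colMeans(c$points)
  r <- mean(sqrt(rowSums(sweep(c$points, 2, ctr)^2)))
  shape_contour(sweep(sweep(c$points, 2, ctr), 2, rep(base_radius / r, 2), `*`),
                source = c$source, base_radius = base_radius)
}

#' All three shape distances at once
#'
#' @inheritParams shape_distance
#' @return Named numeric vector with elements `skeleton`, `curvature`,
#'   `spectrum`.
#' @export
compare_shapes <- function(a, b, cfg = synth_config(), align = alignment_config(),
                           K = 179L) {
  c(skeleton = shape_distance(a, b, "skeleton", cfg, align),
    curvature = shape_distance(a, b, "curvature", cfg),
    spectrum = shape_distance(a, b, "spectrum", cfg, K = K))
}
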