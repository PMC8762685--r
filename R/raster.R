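#' Rasterize a contour to a binary mask
#'
#' The contour is centered on its centroid at the middle of a square canvas.
#' If it does not fit, it is uniformly shrunk (never enlarged) and the scale
#' factor is reported in a warning and stored as the `"scale"` attribute.
#' With `fill = TRUE` the interior is filled under the nonzero-winding rule,
#' so the internal loops of self-intersecting RF contours render as filled
#' lobes rather than holes. With `fill = FALSE` a 1-px outline is traced.
#'
#' @param c a `shape_contour`.
#' @param cfg a [synth_config()]; only `canvas` is used here.
#' @param fill fill the interior (`TRUE`, default) or trace the outline.
#' @return An object of class `shape_mask`: a list with `grid` (logical
#'   matrix, rows indexed by y), `pixel_size` and `origin`, with attribute
#'   `"scale"` giving the shrink factor applied (1 when none).
#' @export
rasterize <- function(c, cfg = synth_config(), fill = TRUE) {
  stopifnot(inherits(c, "shape_contour"), inherits(cfg, "rf_synth_config"))
  canvas <- cfg$canvas
  ctr <- colMeans(c$points)
  pts <- sweep(c$points, 2, ctr)
  half <- canvas / 2 - 1.5
  ext <- max(abs(pts))
  scale <- 1
  if (ext > half) {
    scale <- half / ext
    if (scale < 1e-3) stopf("canvas too small for contour (shrink factor %.2g)", scale)
    warning(sprintf("contour shrunk by factor %.4f to fit %d px canvas",
                    scale, canvas), call. = FALSE)
    pts <- pts * scale
  }
  mid <- (canvas + 1) / 2
  xs <- pts[, 1L] + mid
  ys <- pts[, 2L] + mid
  grid <- matrix(FALSE, canvas, canvas)
  if (fill) {
    w <- matrix(0L, canvas, canvas)
    n <- length(xs)
    j <- c(seq_len(n)[-1L], 1L)
    for (k in seq_len(n)) {
      y1 <- ys[k]; y2 <- ys[j[k]]
      if (y1 == y2) next
      x1 <- xs[k]; x2 <- xs[j[k]]
      sgn <- if (y2 > y1) 1L else -1L
      lo <- min(y1, y2); hi <- max(y1, y2)
      # pixel-center rows crossed by the edge: lo <= row < hi
      r_lo <- ceiling(lo); r_hi <- ceiling(hi) - 1L
      if (r_hi < r_lo) next
      rows <- seq.int(r_lo, r_hi)
      rows <- rows[rows >= 1L & rows <= canvas]
      if (!length(rows)) next
      xint <- x1 + (rows - y1) * (x2 - x1) / (y2 - y1)
      for (ri in seq_along(rows)) {
        m <- min(canvas, ceiling(xint[ri]) - 1L)  # columns strictly left of the edge
        if (m >= 1L) w[rows[ri], seq_len(m)] <- w[rows[ri], seq_len(m)] + sgn
      }
    }
    grid <- w != 0L
  } else {
    n <- length(xs)
    j <- c(seq_len(n)[-1L], 1L)
    for (k in seq_len(n)) {
      len <- sqrt((xs[j[k]] - xs[k])^2 + (ys[j[k]] - ys[k])^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
      px <- round(xs[k] + t * (xs[j[k]] - xs[k]))
      py <- round(ys[k] + t * (ys[j[k]] - ys[k]))
      ok <- px >= 1 & px <= canvas & py >= 1 & py <= canvas
      grid[cbind(py[ok], px[ok])] <- TRUE
    }
  }
  if (!any(grid)) stopf("rasterization produced an empty mask")
  structure(list(grid = grid, pixel_size = 1, origin = c(0, 0)),
            class = "shape_mask", scale = scale)
}

#' @export
print.shape_mask <- function(x, ...) {
  cat(sprintf("shape mask: %d x %d px, %d foreground\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Write a binary mask as a PNG image
#'
#' White foreground on black background.
#'
#' @param m a `shape_mask`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(m, path) {
  stopifnot(inherits(m, "shape_mask"))
  # flip vertically so +y points up in the image
  img <- m$grid[rev(seq_len(nrow(m$grid))), , drop = FALSE] * 1
  png::writePNG(img, path)
  invisible(path)
}

#' Render a search display to a raster
#'
#' Stamps each item's outline (rotated by its orientation, scaled by its size
#' factor) at its display position. Intended for inspection of composed
#' displays; stimuli are rendered as outlines so filled-area luminance cues
#' are absent, as in outline search displays.
#'
#' @param display a `display_spec` from [compose_display()].
#' @param shapes named list mapping item ids to `shape_contour` (or
#'   `rf_genome`, synthesized with `cfg`) objects.
#' @param cfg a [synth_config()] used for genome synthesis.
#' @param canvas canvas side in pixels (default 512).
#' @param path optional PNG output path; items are drawn as green outlines
#'   (RGB 83, 187, 121) on black.
#' @return Logical canvas matrix, invisibly when `path` is given.
#' @export
render_display <- function(display, shapes, cfg = synth_config(),
                           canvas = 512L, path = NULL) {
  stopifnot(inherits(display, "display_spec"))
  canvas <- as.integer(canvas)
  grid <- matrix(FALSE, canvas, canvas)
  mid <- (canvas + 1) / 2
  for (i in seq_len(display$set_size)) {
    shp <- shapes[[display$item_ids[i]]]
    if (is.null(shp)) stopf("no shape supplied for item id '%s'", display$item_ids[i])
    ct <- as_contour(shp, cfg)
    a <- display$orientations[i] * pi / 180
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
    pts <- sweep(ct$points, 2, colMeans(ct$points)) %*% R * display$sizes[i]
    pts <- sweep(pts, 2, c(display$positions[i, 1L] + mid,
                           display$positions[i, 2L] + mid), `+`)
    n <- nrow(pts); j <- c(seq_len(n)[-1L], 1L)
    for (k in seq_len(n)) {
      len <- sqrt(sum((pts[j[k], ] - pts[k, ])^2))
      t <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
      px <- round(pts[k, 1L] + t * (pts[j[k], 1L] - pts[k, 1L]))
      py <- round(pts[k, 2L] + t * (pts[j[k], 2L] - pts[k, 2L]))
      ok <- px >= 1 & px <= canvas & py >= 1 & py <= canvas
      grid[cbind(py[ok], px[ok])] <- TRUE
    }
  }
  if (!is.null(path)) {
    img <- array(0, dim = c(canvas, canvas, 3L))
    fg <- grid[rev(seq_len(canvas)), , drop = FALSE]
    line_rgb <- c(83, 187, 121) / 255
    for (ch in 1:3) img[, , ch][fg] <- line_rgb[ch]
    png::writePNG(img, path)
    return(invisible(grid))
  }
  grid
}
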