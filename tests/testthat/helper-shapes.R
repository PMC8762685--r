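# shared fixtures built in code

zero_genome <- function(n = 10L) rf_genome(rep(0, n), rep(90, n), rep(1, n))

single_freq_genome <- function(f, amplitude, phase = 90, n = 10L) {
  a <- rep(0, n); a[f] <- amplitude
  rf_genome(a, rep(phase, n), rep(1, n))
}

circle_contour <- function(r = 30, n = 360L) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  shape_contour(cbind(r * cos(theta), r * sin(theta)), source = "circle")
}

unit_square <- function() {
  shape_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), source = "square")
}

disc_mask <- function(size = 61L, radius = 28) {
  mid <- (size + 1) / 2
  px <- matrix(rep(seq_len(size), each = size), size)
  py <- matrix(rep(seq_len(size), size), size)
  (px - mid)^2 + (py - mid)^2 <= radius^2
}

has_2x2_block <- function(grid) {
  any(grid[-nrow(grid), -ncol(grid)] & grid[-1, -ncol(grid)] &
      grid[-nrow(grid), -1] & grid[-1, -1])
}

# independent brute-force oracle for the skeleton alignment search:
# explicit loops over the same centroid-translation + rotation-grid lattice
brute_force_skeleton_distance <- function(dp, tp, step_deg = 1) {
  dp <- sweep(dp, 2, colMeans(dp))
  tp <- sweep(tp, 2, colMeans(tp))
  best <- Inf
  for (deg in seq(0, 360 - step_deg, by = step_deg)) {
    a <- deg * pi / 180
    total <- 0
    for (i in seq_len(nrow(dp))) {
      x <- dp[i, 1] * cos(a) + dp[i, 2] * sin(a)
      y <- -dp[i, 1] * sin(a) + dp[i, 2] * cos(a)
      dmin <- Inf
      for (j in seq_len(nrow(tp))) {
        d <- sqrt((x - tp[j, 1])^2 + (y - tp[j, 2])^2)
        if (d < dmin) dmin <- d
      }
      total <- total + dmin
    }
    if (total / nrow(dp) < best) best <- total / nrow(dp)
  }
  best
}

rigid_transform <- function(points, deg = 0, shift = c(0, 0)) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  sweep(points %*% R, 2, shift, `+`)
}
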