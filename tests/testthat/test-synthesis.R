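test_that("zero-amplitude genome synthesizes a 30 px circle", {
  c0 <- synthesize_contour(zero_genome())
  radii <- sqrt(rowSums(c0$points^2))
  expect_true(all(abs(radii - 30) < 1e-9))
  expect_equal(nrow(c0$points), 360L)
})

test_that("a single active frequency gives that many radial maxima", {
  g <- single_freq_genome(4, 20)
  ct <- synthesize_contour(g)
  r <- sqrt(rowSums(ct$points^2))
  # local maxima over the closed radius sequence
  rp <- c(r[length(r)], r, r[1])
  n_max <- sum(rp[2:(length(rp) - 1)] > rp[1:(length(rp) - 2)] &
               rp[2:(length(rp) - 1)] > rp[3:length(rp)])
  expect_equal(n_max, 4L)
})

test_that("modulation exceeding the base radius drives the radius negative", {
  # amp_scale * amplitude = 0.3 * 150 = 45 > 30
  g <- single_freq_genome(3, 150)
  cfg <- synth_config()
  theta <- 2 * pi * (0:3599) / 3600
  r <- cfg$base_radius + cfg$amp_scale * 150 * sin(3 * theta + pi / 2)
  expect_lt(min(r), 0)
  ct <- synthesize_contour(g, cfg)
  expect_false(is_simple_polygon(ct))
  # modest amplitude stays simple
  expect_true(is_simple_polygon(synthesize_contour(single_freq_genome(3, 40))))
})

test_that("null contour is rejected", {
  g <- zero_genome()
  expect_error(synthesize_contour(g, synth_config(base_radius = 1e-12)),
               "null contour")
})

test_that("perimeter and area match closed forms", {
  pa <- perimeter_area(circle_contour())
  expect_equal(unname(pa["perimeter"]), 2 * pi * 30, tolerance = 1e-4)
  expect_equal(unname(pa["area"]), pi * 900, tolerance = 1e-3)
  expect_equal(isoperimetric_ratio(circle_contour()), 4 * pi, tolerance = 1e-3)

  sq <- unit_square()
  pa <- perimeter_area(sq)
  expect_equal(unname(pa["perimeter"]), 4)
  expect_equal(unname(pa["area"]), 1)
  expect_equal(isoperimetric_ratio(sq), 16)
})

test_that("isoperimetric ratio is invariant to scaling and rigid motion", {
  set.seed(5)
  g <- random_genome(init_config(amp_low = 10, amp_high = 40))
  ct <- synthesize_contour(g)
  r0 <- isoperimetric_ratio(ct)
  scaled <- shape_contour(ct$points * 2, source = "s")
  moved <- shape_contour(rigid_transform(ct$points, deg = 33, shift = c(12, -5)),
                         source = "m")
  expect_equal(isoperimetric_ratio(scaled), r0, tolerance = 1e-9)
  expect_equal(isoperimetric_ratio(moved), r0, tolerance = 1e-9)
})

test_that("isoperimetric inequality holds for random simple contours", {
  set.seed(17)
  cfg <- init_config(amp_low = 5, amp_high = 35)
  n_checked <- 0
  while (n_checked < 200) {
    ct <- synthesize_contour(random_genome(cfg))
    if (!is_simple_polygon(ct)) next
    expect_gte(isoperimetric_ratio(ct), 4 * pi - 1e-6)
    n_checked <- n_checked + 1
  }
})

test_that("rotating a genome in phase space leaves perimeter, area and spectrum unchanged", {
  set.seed(8)
  g <- random_genome(init_config(amp_low = 10, amp_high = 40))
  delta <- 37
  rotated <- g
  rotated$phases <- (g$phases + (1:10) * delta - 1) %% 360 + 1
  pa0 <- perimeter_area(synthesize_contour(g))
  pa1 <- perimeter_area(synthesize_contour(rotated))
  expect_equal(pa0, pa1, tolerance = 1e-6)
  expect_identical(effective_spectrum(g), effective_spectrum(rotated))
})

test_that("silhouettes load, close and resample by arc length", {
  path <- system.file("extdata", "rabbit_synthetic.csv", package = "rfevolve")
  rb <- load_silhouette(path)
  expect_equal(nrow(rb$points), 360L)

  # a 100-point polygon resampled to 360 points keeps its perimeter
  set.seed(2)
  poly <- resample_contour(circle_contour(25, 100), 100)
  p_before <- perimeter_area(poly)["perimeter"]
  resampled <- resample_contour(poly, 360)
  p_after <- perimeter_area(resampled)["perimeter"]
  expect_lt(abs(p_after - p_before) / p_before, 0.005)
  expect_equal(nrow(resampled$points), 360L)

  # open polyline is closed automatically; explicit closure is dropped
  f <- tempfile(fileext = ".csv")
  pts <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  write.table(pts, f, sep = ",", row.names = FALSE, col.names = FALSE)
  sq <- load_silhouette(f, n_points = 4)
  expect_equal(nrow(sq$points), 4L)
  expect_equal(unname(perimeter_area(sq)["perimeter"]), 40)

  # parse errors
  bad <- tempfile(fileext = ".csv")
  writeLines(c("1,2", "a,b", "3,4"), bad)
  expect_error(load_silhouette(bad), "parse|numeric")
  two <- tempfile(fileext = ".csv")
  writeLines(c("1,2", "3,4"), two)
  expect_error(load_silhouette(two), "3 points")
})

test_that("rasterization fills the expected area and is centering-invariant", {
  ct <- circle_contour()
  m <- rasterize(ct)
  expect_lt(abs(sum(m$grid) - pi * 900) / (pi * 900), 0.02)

  shifted <- shape_contour(sweep(ct$points, 2, c(5, 5), `+`), source = "shift")
  m2 <- rasterize(shifted)
  expect_identical(m$grid, m2$grid)

  # identical genomes give bitwise-identical masks
  set.seed(4)
  g <- random_genome(init_config(amp_low = 10, amp_high = 40))
  expect_identical(rasterize(synthesize_contour(g))$grid,
                   rasterize(synthesize_contour(g))$grid)
})

test_that("outline raster lies on or near the filled mask boundary", {
  ct <- circle_contour()
  filled <- rasterize(ct, fill = TRUE)$grid
  outline <- rasterize(ct, fill = FALSE)$grid
  # dilate the filled mask by one pixel; every outline pixel must fall inside
  dil <- filled
  dil[-1, ] <- dil[-1, ] | filled[-nrow(filled), ]
  dil[-nrow(dil), ] <- dil[-nrow(dil), ] | filled[-1, ]
  dil[, -1] <- dil[, -1] | filled[, -ncol(filled)]
  dil[, -ncol(dil)] <- dil[, -ncol(dil)] | filled[, -1]
  expect_true(all(dil[outline]))
})

test_that("oversized contours are shrunk with a warning, never enlarged", {
  big <- circle_contour(200)
  expect_warning(m <- rasterize(big), "shrunk")
  expect_lt(attr(m, "scale"), 1)
  small <- circle_contour(10)
  expect_silent(m2 <- rasterize(small))
  expect_equal(attr(m2, "scale"), 1)
})

test_that("self-intersecting contours fall back to mask-count area", {
  g <- single_freq_genome(3, 150)
  ct <- synthesize_contour(g)
  pa <- perimeter_area(ct)
  expect_gt(pa[["area"]], 0)
  # mask-count area counts loop interiors once: bounded by the shoelace value,
  # which double-counts regions of winding number 2
  s <- nrow(ct$points)
  j <- c(2:s, 1)
  shoelace <- abs(sum(ct$points[, 1] * ct$points[j, 2] -
                      ct$points[j, 1] * ct$points[, 2])) / 2
  expect_lt(pa[["area"]], shoelace * 1.02)
})
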