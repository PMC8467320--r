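test_that("component labeling respects connectivity and scan order", {
  m <- matrix(0L, 4, 4); m[2, 2] <- 1L; m[3, 3] <- 1L
  expect_equal(label_components(binary_mask(m, 1), 8)$n, 1)
  expect_equal(label_components(binary_mask(m, 1), 4)$n, 2)

  empty <- label_components(binary_mask(matrix(0L, 5, 5), 1))
  expect_equal(empty$n, 0)

  # labels are assigned in row-major first-seen order
  m2 <- matrix(0L, 5, 9)
  m2[4, 2] <- 1L; m2[2, 5] <- 1L; m2[3, 8] <- 1L
  lab <- label_components(binary_mask(m2, 1))
  expect_equal(lab$labels[2, 5], 1L)
  expect_equal(lab$labels[3, 8], 2L)
  expect_equal(lab$labels[4, 2], 3L)

  # random non-touching rectangles are all recovered
  set.seed(4)
  m3 <- matrix(0L, 100, 100)
  n_placed <- 0L
  for (k in 1:100) {
    r0 <- sample(1:95, 1); c0 <- sample(1:95, 1)
    block <- m3[max(1, r0 - 1):min(100, r0 + 3),
                max(1, c0 - 1):min(100, c0 + 3)]
    if (!any(block != 0L)) {
      m3[r0 + 0:2, c0 + 0:2] <- 1L
      n_placed <- n_placed + 1L
    }
  }
  expect_equal(label_components(binary_mask(m3, 1))$n, n_placed)
})

test_that("boundary polygons follow the pixel-corner lattice", {
  m1 <- matrix(0L, 3, 3); m1[2, 2] <- 1L
  p1 <- trace_boundary(label_components(binary_mask(m1, 1)), 1)
  expect_equal(nrow(p1), 4)
  expect_equal(abs(ppdxdeg:::polygon_signed_area(p1)), 1)

  m2 <- matrix(0L, 8, 8); m2[3:4, 2:4] <- 1L
  p2 <- trace_boundary(label_components(binary_mask(m2, 1)), 1)
  expect_equal(nrow(p2), 4)
  per <- sum(sqrt(rowSums((p2 - p2[c(2:nrow(p2), 1), ])^2)))
  expect_equal(per, 10)

  disk <- raster_disk(40)
  pd <- trace_boundary(label_components(disk), 1)
  expect_equal(abs(ppdxdeg:::polygon_signed_area(pd)), pi * 40^2, tolerance = 0.01)

  expect_error(trace_boundary(label_components(binary_mask(m1, 1)), 5),
               "label")
})

test_that("convex hull matches independent oracles", {
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4), c(2, 2))
  expect_equal(nrow(convex_hull(sq)), 4)

  col <- cbind(1:7, 2 * (1:7))
  seg <- convex_hull(col)
  expect_equal(nrow(seg), 2)
  expect_equal(unname(seg[, 1]), c(1, 7))

  expect_error(convex_hull(matrix(numeric(0), ncol = 2)), "empty")

  # grDevices::chull as oracle on a large random set
  set.seed(2)
  pts <- cbind(runif(500), runif(500))
  h <- convex_hull(pts)
  o <- pts[grDevices::chull(pts), , drop = FALSE]
  expect_equal(nrow(h), nrow(o))
  for (k in seq_len(nrow(o)))
    expect_true(any(abs(h[, 1] - o[k, 1]) < 1e-12 &
                      abs(h[, 2] - o[k, 2]) < 1e-12))

  # brute-force half-plane test on a small set: every returned vertex is
  # extreme, and no input point falls outside any hull edge
  set.seed(9)
  small <- cbind(rnorm(30), rnorm(30))
  hs <- convex_hull(small)
  nh <- nrow(hs)
  for (i in seq_len(nh)) {
    a <- hs[i, ]; b <- hs[if (i == nh) 1 else i + 1, ]
    crossz <- (b[1] - a[1]) * (small[, 2] - a[2]) -
      (b[2] - a[2]) * (small[, 1] - a[1])
    expect_true(all(crossz >= -1e-9))  # CCW hull: all points on the left
  }
})

test_that("feret equals the exhaustive pairwise maximum with conventional angles", {
  seg <- rbind(c(0, 0), c(10, 0))
  f <- feret(seg)
  expect_equal(f$diameter, 10)
  expect_equal(f$angle, 0)

  vseg <- rbind(c(3, -2), c(3, 6))
  expect_equal(feret(vseg)$angle, 90)

  f1 <- feret(rbind(c(2, 5)))
  expect_equal(f1$diameter, 0)
  expect_true(f1$degenerate)

  set.seed(3)
  for (i in 1:300) {
    h <- convex_hull(cbind(rnorm(25), rnorm(25)))
    expect_equal(feret(h)$diameter, max(dist(h)), tolerance = 1e-12)
  }
})

test_that("moment ellipse recovers analytic aspect ratios", {
  lab <- label_components(raster_ellipse(60, 20))
  e <- fit_ellipse(lab, 1)
  expect_equal(e$major / e$minor, 3, tolerance = 0.05)
  expect_equal(e$orientation, 0, tolerance = 0.5)

  d <- fit_ellipse(label_components(raster_disk(30)), 1)
  expect_equal(d$major / d$minor, 1, tolerance = 0.02)

  sq <- fit_ellipse(label_components(raster_rect(10, 10)), 1)
  expect_equal(sq$major / sq$minor, 1, tolerance = 1e-6)

  rot <- fit_ellipse(label_components(raster_ellipse(60, 20, 35)), 1)
  expect_equal(rot$orientation, 35, tolerance = 1)
})

test_that("descriptors of analytic shapes match closed forms", {
  disk <- measure_first(raster_disk(40, pixel_size = 0.1))
  expect_equal(disk$area, pi * 4^2, tolerance = 0.01)
  expect_gte(disk$circularity, 0.95)
  expect_gte(disk$solidity, 0.98)
  expect_equal(disk$feret_diameter, 8, tolerance = 0.02)

  rect <- measure_first(raster_rect(20, 40))
  expect_equal(rect$solidity, 1, tolerance = 0.02)
  expect_equal(rect$feret_diameter, sqrt(20^2 + 40^2), tolerance = 0.03)

  thin <- measure_first(raster_rect(10, 100))
  expect_lt(thin$circularity, 0.4)
  expect_equal(thin$circularity, 4 * pi * 1000 / 220^2, tolerance = 0.12)
  expect_equal(thin$aspect_ratio, 10, tolerance = 0.05)
})

test_that("descriptors are scale equivariant and bounded", {
  lab <- label_components(raster_ellipse(40, 12, 25))
  r1 <- measure_crack(lab, 1, 0.05)
  r2 <- measure_crack(lab, 1, 0.10)
  expect_equal(r2$feret_diameter, 2 * r1$feret_diameter)
  expect_equal(r2$perimeter, 2 * r1$perimeter)
  expect_equal(r2$area, 4 * r1$area)
  expect_equal(r2$aspect_ratio, r1$aspect_ratio)
  expect_equal(r2$circularity, r1$circularity)
  expect_equal(r2$solidity, r1$solidity)

  set.seed(11)
  for (k in 1:5) {
    spec <- crack_population_spec(5, dist_lognormal(3, 0.5),
                                  dist_uniform(1.5, 8),
                                  dist_uniform(0, 180),
                                  pixel_size = 0.08,
                                  field_size = c(40, 30))
    recs <- measure_all_cracks(generate_crack_mask(spec, seed = k)$mask)
    expect_true(all(recs$circularity >= 0 & recs$circularity <= 1))
    expect_true(all(recs$solidity > 0 & recs$solidity <= 1))
    expect_true(all(recs$aspect_ratio >= 1))
    expect_true(all(recs$feret_angle >= 0 & recs$feret_angle < 180))
  }
})

test_that("descriptors of a digitized ellipse are rotation robust", {
  vals <- sapply(c(0, 17, 45, 71, 123), function(ang) {
    r <- measure_first(raster_ellipse(60, 20, ang))
    c(r$feret_diameter, r$aspect_ratio, r$circularity, r$solidity)
  })
  rel_range <- apply(vals, 1, function(v) (max(v) - min(v)) / mean(v))
  expect_true(all(rel_range < 0.03))
})

test_that("crack population summaries follow hand arithmetic", {
  one <- data.frame(area = 5)
  s1 <- summarize_cracks(one, "area")$summary
  expect_equal(s1$mean, 5)
  expect_equal(s1$median, 5)
  expect_equal(s1$sd, 0)

  three <- data.frame(area = c(1, 2, 3))
  s3 <- summarize_cracks(three, "area",
                         breaks = list(area = c(0, 1.5, 2.5, 3.5)))
  expect_equal(s3$summary$mean, 2)
  expect_equal(s3$summary$median, 2)
  expect_equal(s3$summary$sd, 1)
  expect_equal(s3$histograms$area$counts, c(1, 1, 1))

  expect_error(summarize_cracks(data.frame(area = numeric(0)), "area"),
               "no crack")
  expect_error(summarize_cracks(three, "volume"), "unknown")
})
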