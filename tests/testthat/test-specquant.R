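test_that("asls removes smooth backgrounds without distorting peaks", {
  ramp <- generate_spectrum(list(), baseline_coeffs = c(5, 0.05))
  corr <- correct_baseline(ramp)
  expect_lt(max(abs(corr$intensities)),
            0.01 * diff(range(ramp$intensities)))

  clean <- generate_spectrum(list(peak_model(1000, 200, 12, 0.3)))
  h0 <- peak_height(clean, 1000, 6)$height
  h1 <- peak_height(correct_baseline(clean), 1000, 6)$height
  expect_lt(abs(h1 - h0) / h0, 0.005)

  expect_error(
    correct_baseline(ramp, params = list(max_iter = 1L, tol = 0)),
    "iteration")
})

test_that("linear anchor baseline recovers a triangle on a ramp exactly", {
  wn <- seq(200, 1800, by = 1)
  tri <- pmax(0, 50 - abs(wn - 1000) * 0.5)
  ramp <- 3 + 0.02 * wn
  sp <- spectrum(wn, tri + ramp)
  corr <- correct_baseline(sp, method = "linear_anchors",
                           params = list(anchors = c(200, 1800)))
  expect_equal(corr$intensities, tri, tolerance = 1e-10)
  expect_error(
    correct_baseline(sp, method = "linear_anchors",
                     params = list(anchors = 500)),
    "anchor")
})

test_that("peak_height takes the window argmax with lowest-wavenumber ties", {
  sp <- generate_spectrum(list(peak_model(1732, 80, 10, 0)))
  ph <- peak_height(sp, 1732, 5)
  expect_equal(ph$height, 80)
  expect_equal(ph$position, 1732)

  flat <- spectrum(seq(1700, 1760), rep(0, 61))
  pf <- peak_height(flat, 1732, 5)
  expect_equal(pf$height, 0)
  expect_equal(pf$position, 1727)  # tie broken to the lowest wavenumber

  off <- generate_spectrum(list(peak_model(1731, 80, 10, 0)))
  expect_equal(peak_height(off, 1732, 5)$position, 1731)

  expect_error(peak_height(sp, 1799, 5), "outside")
})

test_that("shoulder_area integrates the normalized window correctly", {
  # normalized intensity identically 1 over the window: area = width = 13
  wn <- seq(1700, 1760)
  sp1 <- spectrum(wn, rep(7.5, 61))
  expect_equal(shoulder_area(sp1)$normalized_area, 13)

  # narrow peak at 1732, nothing in the window: area ~ 0
  sp0 <- generate_spectrum(list(peak_model(1732, 100, 2, 0)))
  expect_lt(shoulder_area(sp0)$normalized_area, 1e-4)

  expect_error(shoulder_area(spectrum(wn, rep(0, 61))), "non-positive")
  expect_error(shoulder_area(generate_spectrum(list(), wn_min = 1740,
                                               wn_max = 1800)),
               "cover")
})

test_that("shoulder_area is scale invariant and monotone in shoulder level", {
  sp <- generate_spectrum(ppdx_peaks(0.8))
  a1 <- shoulder_area(sp)$normalized_area
  sp2 <- sp; sp2$intensities <- sp$intensities * 37.5
  expect_equal(shoulder_area(sp2)$normalized_area, a1, tolerance = 1e-12)

  lv <- c(0, 0.2, 0.5, 0.8, 1.2)
  areas <- vapply(lv, function(s)
    shoulder_area(generate_spectrum(ppdx_peaks(s)))$normalized_area,
    numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("trapezoid integration matches an oversampled Riemann oracle", {
  sp <- generate_spectrum(ppdx_peaks(0.9), step = 1)
  a_trap <- shoulder_area(sp)$normalized_area
  # 10x oversampled midpoint Riemann sum on the same normalized signal
  fine <- generate_spectrum(ppdx_peaks(0.9), step = 0.1)
  h <- peak_height(sp, 1732, 5)$height
  mid <- seq(1736.005, 1748.995, by = 0.01)
  y <- approx(fine$wavenumbers, fine$intensities / h, xout = mid)$y
  a_riemann <- sum(y) * 0.01
  expect_equal(a_trap, a_riemann, tolerance = 0.005)
})

test_that("baseline correction plus shoulder metric is robust to linear backgrounds", {
  clean <- generate_spectrum(ppdx_peaks(0.9))
  a0 <- shoulder_area(clean)$normalized_area
  dirty <- generate_spectrum(ppdx_peaks(0.9), baseline_coeffs = c(30, 0.05))
  a1 <- shoulder_area(
    correct_baseline(dirty, method = "linear_anchors",
                     params = list(anchors = c(250, 650, 1550, 1680, 1795),
                                   anchor_halfwin = 3)))$normalized_area
  expect_equal(a1, a0, tolerance = 0.02)
  a2 <- shoulder_area(correct_baseline(dirty))$normalized_area
  expect_equal(a2, a0, tolerance = 0.02)
})

test_that("grid metrics preserve order and report failing positions", {
  sp <- generate_spectrum(ppdx_peaks(0.7))
  grid <- spectrum_grid(rep(list(sp), 64))
  df <- grid_shoulder_metrics(grid, method = "none")
  expect_equal(nrow(df), 64)
  expect_equal(length(unique(df$normalized_area)), 1)
  expect_equal(df$row, rep(1:8, each = 8))

  bad <- rep(list(sp), 64)
  bad[[11]] <- spectrum(sp$wavenumbers, rep(0, length(sp$wavenumbers)))
  expect_error(grid_shoulder_metrics(spectrum_grid(bad), method = "none"),
               "row 2, col 3")
})

test_that("grid mean tracks the noiseless reference metric", {
  prof <- list(degradation_profile(0, 0.8, noise_sd_rel = 0.02))
  g <- generate_degradation_series(prof, cv = 0.05, seed = 21)[[1]]
  ref <- shoulder_area(reference_spectrum(g))$normalized_area
  df <- grid_shoulder_metrics(g)
  sem <- sd(df$normalized_area) / sqrt(nrow(df))
  expect_lt(abs(mean(df$normalized_area) - ref), 2 * sem)
})

test_that("dye peak tracking is ratiometric against the 870 band", {
  full <- correct_baseline(
    generate_spectrum(ppdx_peaks(0.8, dye_level = 1),
                      baseline_coeffs = c(20, 0.01)))
  halved <- correct_baseline(
    generate_spectrum(ppdx_peaks(0.8, dye_level = 0.5),
                      baseline_coeffs = c(20, 0.01)))
  h1 <- dye_peak_heights(full)
  h2 <- dye_peak_heights(halved)
  expect_equal(unname(h2 / h1), rep(0.5, 5), tolerance = 0.05)

  short <- generate_spectrum(ppdx_peaks(0.8), wn_min = 600)
  expect_error(dye_peak_heights(short), "483")
})

test_that("band emergence scores a weak carboxylate band against its local baseline", {
  carbonyl <- list(peak_model(1733, 200, 12, 0))
  none <- generate_spectrum(carbonyl, kind = "ftir")
  expect_lt(band_emergence(none), 1e-6)

  with_band <- generate_spectrum(c(carbonyl, list(peak_model(1605, 10, 10, 0))),
                                 kind = "ftir")
  expect_equal(band_emergence(with_band), 0.05, tolerance = 0.01)

  # a sloping background inflates the raw window max but not the score
  sloped <- generate_spectrum(carbonyl, baseline_coeffs = c(0, 0.1),
                              kind = "ftir")
  sel <- sloped$wavenumbers >= 1585 & sloped$wavenumbers <= 1625
  raw_max <- max(sloped$intensities[sel])
  score <- band_emergence(sloped)
  ref_h <- peak_height(sloped, 1733, 5)$height
  expect_lt(score * ref_h, raw_max)
})
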