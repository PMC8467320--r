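test_that("single noiseless peaks reproduce closed-form heights and areas", {
  sp <- generate_spectrum(list(peak_model(870, 100, 10, 0)))
  expect_equal(max(sp$intensities), 100)
  expect_equal(sp$wavenumbers[which.max(sp$intensities)], 870)

  flat <- generate_spectrum(list(), baseline_coeffs = 5)
  expect_true(all(flat$intensities == 5))

  # Lorentzian area: closed form A*(w/2)*atan(2(x-c)/w) over the grid span
  # (the full-line area is A*w*pi/2; Cauchy tails outside the grid matter)
  lor <- generate_spectrum(list(peak_model(1000, 50, 8, 1)),
                           wn_min = 200, wn_max = 1800, step = 0.2)
  num <- sum(diff(lor$wavenumbers) *
               (head(lor$intensities, -1) + tail(lor$intensities, -1)) / 2)
  closed <- 50 * (8 / 2) * (atan(2 * (1800 - 1000) / 8) -
                              atan(2 * (200 - 1000) / 8))
  expect_equal(num, closed, tolerance = 1e-3)
  expect_equal(closed, 50 * 8 * pi / 2, tolerance = 0.005)

  # pseudo-Voigt blend interpolates between the two shapes
  g <- pseudo_voigt(872, peak_model(870, 1, 10, 0))
  l <- pseudo_voigt(872, peak_model(870, 1, 10, 1))
  h <- pseudo_voigt(872, peak_model(870, 1, 10, 0.5))
  expect_equal(h, (g + l) / 2)
})

test_that("spectrum generation rejects invalid inputs", {
  expect_error(generate_spectrum(list(), wn_min = 500, wn_max = 400),
               "empty")
  expect_error(generate_spectrum(list(), noise_sd = -1), "noise_sd")
  expect_error(peak_model(870, 10, -1), "fwhm")
  expect_error(peak_model(870, -2, 1), "amplitude")
  expect_error(peak_model(870, 1, 1, 1.5), "shape_mix")
})

test_that("degradation series has monotone reference metric and fixed seed determinism", {
  profiles <- default_profiles()
  grids <- generate_degradation_series(profiles, seed = 7)
  ref_areas <- vapply(grids, function(g)
    shoulder_area(reference_spectrum(g))$normalized_area, numeric(1))
  expect_true(all(diff(ref_areas) < 0))

  grids2 <- generate_degradation_series(profiles, seed = 7)
  expect_identical(
    lapply(grids, function(g) lapply(g$spectra, `[[`, "intensities")),
    lapply(grids2, function(g) lapply(g$spectra, `[[`, "intensities")))

  expect_error(
    generate_degradation_series(list(degradation_profile(0, 1),
                                     degradation_profile(0, 0.5))),
    "duplicate")
})

test_that("dye peaks vanish at dye_level 0", {
  prof <- degradation_profile(0, 0.9, dye_level = 0, noise_sd_rel = 0.02)
  g <- generate_degradation_series(list(prof), seed = 3)[[1]]
  sp <- correct_baseline(g$spectra[[1]])
  noise_sd <- 0.02 * 400
  for (ctr in c(483, 1242, 1403, 1610, 1638)) {
    h <- peak_height(sp, ctr, 6)$height
    expect_lt(h, 3 * noise_sd)
  }
})

test_that("generated crack masks agree with their ground truth", {
  empty <- generate_crack_mask(
    crack_population_spec(0, dist_fixed(1), dist_fixed(1), dist_fixed(0)),
    seed = 1)
  expect_equal(sum(empty$mask$pixels), 0)
  expect_equal(nrow(empty$truth), 0)

  one <- generate_crack_mask(
    crack_population_spec(1, dist_fixed(10), dist_fixed(5), dist_fixed(90),
                          pixel_size = 0.05, field_size = c(30, 30)),
    seed = 2)
  rec <- measure_all_cracks(one$mask)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$feret_diameter, 10, tolerance = 0.03)
  expect_equal(rec$feret_angle, 90, tolerance = 0.02)

  # non-overlapping population: one labeled component per drawn crack
  pop <- generate_crack_mask(
    crack_population_spec(40, dist_lognormal(2, 0.4), dist_fixed(4),
                          dist_normal(90, 20)),
    seed = 5)
  expect_equal(label_components(pop$mask)$n, 40)

  # forced merge of two collinear cracks gives one component
  merged <- generate_crack_mask(
    crack_population_spec(2, dist_fixed(10), dist_fixed(5), dist_fixed(0),
                          merge_prob = 1, pixel_size = 0.1,
                          field_size = c(40, 20)),
    seed = 3)
  expect_equal(label_components(merged$mask)$n, 1)

  # determinism
  again <- generate_crack_mask(
    crack_population_spec(40, dist_lognormal(2, 0.4), dist_fixed(4),
                          dist_normal(90, 20)),
    seed = 5)
  expect_identical(pop$mask$pixels, again$mask$pixels)
})

test_that("synthetic thermograms carry the requested enthalpy", {
  none <- generate_thermogram(0)
  expect_equal(integrate_endotherm(none, 81, 129), 0, tolerance = 1e-10)

  half <- generate_thermogram(50, dH_ref = 141)
  expect_equal(integrate_endotherm(half, 81, 129), 70.5, tolerance = 1e-3)

  t1 <- generate_thermogram(40, noise_sd = 0.01, seed = 9)
  t2 <- generate_thermogram(40, noise_sd = 0.01, seed = 9)
  expect_identical(t1$heat_flow, t2$heat_flow)

  expect_error(generate_thermogram(120), "crystallinity_pct")
  expect_error(generate_thermogram(50, melt_center = 145), "inside")
})
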