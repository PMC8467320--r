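#' Describe one spectral band
#'
#' A pseudo-Voigt band: `shape_mix` blends a Gaussian (`0`) and a Lorentzian
#' (`1`) of common center, height and full width at half maximum.
#'
#' @param center Band center, cm-1.
#' @param amplitude Peak height, counts (>= 0).
#' @param fwhm Full width at half maximum, cm-1 (> 0).
#' @param shape_mix Lorentzian fraction in `[0, 1]`.
#' @return A `peak_model` object (named list).
#' @export
peak_model <- function(center, amplitude, fwhm, shape_mix = 0) {
  if (!is.finite(center)) stop("center must be finite")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (fwhm <= 0) stop("fwhm must be > 0")
  if (shape_mix < 0 || shape_mix > 1) stop("shape_mix must lie in [0, 1]")
  structure(list(center = center, amplitude = amplitude,
                 fwhm = fwhm, shape_mix = shape_mix),
            class = "peak_model")
}

#' Evaluate a pseudo-Voigt profile
#'
#' Height-normalized blend: `amplitude * ((1 - m) * G(x) + m * L(x))` where
#' G and L are unit-height Gaussian and Lorentzian profiles sharing the
#' band's center and FWHM.
#'
#' @param x Wavenumbers, cm-1.
#' @param peak A [peak_model()].
#' @return Intensities at `x`.
#' @export
pseudo_voigt <- function(x, peak) {
  u <- (x - peak$center) / peak$fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  peak$amplitude * ((1 - peak$shape_mix) * g + peak$shape_mix * l)
}

#' Synthesize one spectrum from band models
#'
#' Sum of pseudo-Voigt bands plus a polynomial baseline plus additive
#' Gaussian noise, on a uniform wavenumber grid.
#'
#' @param peaks List of [peak_model()] objects (may be empty).
#' @param baseline_coeffs Polynomial coefficients in increasing order
#'   (`c(a0, a1, ...)` gives `a0 + a1*wn + ...`). Default `0`.
#' @param noise_sd Standard deviation of additive Gaussian noise, counts.
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched and is
#'   only allowed when `noise_sd == 0`.
#' @param wn_min,wn_max,step Wavenumber grid, cm-1. Defaults 200-1800 step 1.
#' @param kind,meta Passed to [spectrum()].
#' @return A `ppdx_spectrum`.
#' @export
generate_spectrum <- function(peaks, baseline_coeffs = 0, noise_sd = 0,
                              seed = NULL, wn_min = 200, wn_max = 1800,
                              step = 1, kind = "raman", meta = list()) {
  if (step <= 0) stop("step must be > 0")
  if (wn_max <= wn_min) stop("empty wavenumber grid (wn_max <= wn_min)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  wn <- seq(wn_min, wn_max, by = step)
  if (length(wn) < 2L) stop("wavenumber grid has fewer than 2 points")
  y <- numeric(length(wn))
  for (p in peaks) y <- y + pseudo_voigt(wn, p)
  for (i in seq_along(baseline_coeffs))
    y <- y + baseline_coeffs[i] * wn^(i - 1L)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(wn), sd = noise_sd)
  }
  spectrum(wn, y, kind = kind, meta = meta)
}

# Band positions (cm-1) of the semicrystalline PPDX fiber and of the
# Solvent Violet 13 dye, with default heights in counts. The C-O-C symmetric
# stretch at 870 is the strongest band and serves as the internal standard;
# the ester carbonyl sits at 1732 with the amorphous-phase C=O contribution
# as a broad shoulder on its high-wavenumber flank.
ppdx_band_defaults <- function() {
  list(
    ppdx = data.frame(
      center = c(870, 1048, 1451, 1732),
      amplitude = c(1000, 450, 350, 400),
      fwhm = c(12, 14, 16, 10),
      shape_mix = c(0.3, 0.3, 0.3, 0.2)
    ),
    dye = data.frame(
      center = c(483, 1242, 1403, 1610, 1638),
      amplitude = c(60, 40, 50, 45, 55),
      fwhm = c(10, 10, 10, 9, 9),
      shape_mix = rep(0.3, 5)
    ),
    shoulder = data.frame(center = 1742, fwhm = 14, shape_mix = 0)
  )
}

#' PPDX peak set for a given degradation state
#'
#' Builds the full band list for a synthetic stent-fiber Raman spectrum:
#' the four PPDX bands (870, 1048, 1451, 1732 cm-1), the five dye bands
#' (483, 1242, 1403, 1610, 1638 cm-1) scaled by `dye_level`, and one broad
#' Gaussian shoulder component at 1742 cm-1 (FWHM 14 cm-1) representing the
#' amorphous-phase carbonyl, with height `shoulder_level` times the
#' 1732 cm-1 band height.
#'
#' @param shoulder_level Dimensionless scale of the amorphous shoulder
#'   component (>= 0).
#' @param dye_level Dimensionless scale of the dye bands (>= 0).
#' @param bands Band table as returned by `ppdx_band_defaults()`; exposed for
#'   tests.
#' @return List of [peak_model()] objects.
#' @export
ppdx_peaks <- function(shoulder_level, dye_level = 1,
                       bands = ppdx_band_defaults()) {
  if (shoulder_level < 0) stop("shoulder_level must be >= 0")
  if (dye_level < 0) stop("dye_level must be >= 0")
  pk <- list()
  for (i in seq_len(nrow(bands$ppdx))) {
    b <- bands$ppdx[i, ]
    pk[[length(pk) + 1L]] <- peak_model(b$center, b$amplitude, b$fwhm,
                                        b$shape_mix)
  }
  amp_1732 <- bands$ppdx$amplitude[bands$ppdx$center == 1732]
  s <- bands$shoulder
  pk[[length(pk) + 1L]] <- peak_model(s$center, shoulder_level * amp_1732,
                                      s$fwhm, s$shape_mix)
  for (i in seq_len(nrow(bands$dye))) {
    b <- bands$dye[i, ]
    pk[[length(pk) + 1L]] <- peak_model(b$center, dye_level * b$amplitude,
                                        b$fwhm, b$shape_mix)
  }
  pk
}

#' Degradation profile for one period
#'
#' Ground-truth state of one degradation period: the scale of the amorphous
#' shoulder, the dye level, the crystalline fraction and the relative noise
#' level (fraction of the 1732 cm-1 band height).
#'
#' @param week Integer >= 0.
#' @param shoulder_level Amorphous shoulder scale (>= 0).
#' @param dye_level Dye band scale (>= 0).
#' @param crystallinity_pct Percent crystalline phase, in `[0, 100]`.
#' @param noise_sd_rel Additive noise SD as a fraction of the 1732 cm-1 band
#'   height. Default 0.02.
#' @return A `degradation_profile` object.
#' @export
degradation_profile <- function(week, shoulder_level, dye_level = 1,
                                crystallinity_pct = 50, noise_sd_rel = 0.02) {
  week <- as.integer(week)
  if (week < 0) stop("week must be >= 0")
  if (shoulder_level < 0) stop("shoulder_level must be >= 0")
  if (dye_level < 0) stop("dye_level must be >= 0")
  if (crystallinity_pct < 0 || crystallinity_pct > 100)
    stop("crystallinity_pct must lie in [0, 100]")
  if (noise_sd_rel < 0) stop("noise_sd_rel must be >= 0")
  structure(list(week = week, shoulder_level = shoulder_level,
                 dye_level = dye_level,
                 crystallinity_pct = crystallinity_pct,
                 noise_sd_rel = noise_sd_rel),
            class = "degradation_profile")
}

#' Calibrate the shoulder scale to a target normalized area
#'
#' Solves for the `shoulder_level` at which the noiseless reference spectrum
#' yields exactly the requested normalized shoulder area (cm-1) under
#' [shoulder_area()]. The metric is strictly increasing in the shoulder
#' scale, so the root is unique; it is found by `uniroot` to 1e-8.
#'
#' @param target_area Target normalized shoulder area, cm-1.
#' @param dye_level Dye scale used in the reference spectrum.
#' @param upper Upper search bound for the shoulder scale.
#' @return The calibrated `shoulder_level`.
#' @export
calibrate_shoulder_level <- function(target_area, dye_level = 1, upper = 5) {
  f <- function(s) {
    sp <- generate_spectrum(ppdx_peaks(s, dye_level), noise_sd = 0)
    shoulder_area(sp)$normalized_area - target_area
  }
  if (f(0) > 0)
    stop("target area ", target_area,
         " is below the bare carbonyl tail contribution")
  if (f(upper) < 0)
    stop("target area ", target_area, " not reachable with shoulder_level <= ",
         upper)
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

#' Default degradation series profiles
#'
#' The five study conditions the generator emulates: non-degraded and 4, 8,
#' 16, 24 weeks in PBS at 37 degrees C. Shoulder scales are calibrated so the
#' noiseless reference metric equals the reference normalized shoulder areas
#' (9.83, 9.24, 7.97, 6.65, 6.30 cm-1); crystallinity follows the measured
#' series (47.6, 54.8, 60.9, 69.7, 59.2 percent); the dye level declines
#' monotonically as the dye is eluted.
#'
#' @param noise_sd_rel Relative noise level passed to every profile.
#' @return List of [degradation_profile()] objects.
#' @export
default_profiles <- function(noise_sd_rel = 0.02) {
  weeks <- c(0L, 4L, 8L, 16L, 24L)
  areas <- c(9.83, 9.24, 7.97, 6.65, 6.30)
  cryst <- c(47.6, 54.8, 60.9, 69.7, 59.2)
  dye <- c(1, 0.75, 0.5, 0.3, 0.15)
  Map(function(w, a, x, d) {
    degradation_profile(w, calibrate_shoulder_level(a, dye_level = d),
                        dye_level = d, crystallinity_pct = x,
                        noise_sd_rel = noise_sd_rel)
  }, weeks, areas, cryst, dye)
}

#' Generate a multi-period series of spectrum grids
#'
#' For each degradation profile, synthesizes an `n_rows x n_cols` grid of
#' spectra. The PPDX band set is fixed across periods; the shoulder and dye
#' components are scaled by the profile. Each band's height receives an
#' independent per-spot lognormal factor (mean 1, coefficient of variation
#' `cv`), emulating spot-to-spot variation of the sampled volume; additive
#' Gaussian noise has SD `noise_sd_rel` times the nominal 1732 cm-1 height.
#' Each grid carries its noiseless, baseline-free reference spectrum
#' (see [reference_spectrum()]).
#'
#' @param profiles List of [degradation_profile()] objects, distinct weeks.
#' @param n_rows,n_cols Grid layout (default 8 x 8).
#' @param dx,dy Grid spacings, micrometers (defaults 12.9, 11.4).
#' @param cv Coefficient of variation of the per-spot lognormal amplitude
#'   factors. Default 0.05.
#' @param baseline_coeffs Polynomial baseline added to every noisy spectrum
#'   (the reference spectrum never includes it). Default gentle linear ramp.
#' @param seed Integer seed for the whole series.
#' @return Named list (names = week) of `ppdx_spectrum_grid` objects.
#' @export
generate_degradation_series <- function(profiles, n_rows = 8L, n_cols = 8L,
                                        dx = 12.9, dy = 11.4, cv = 0.05,
                                        baseline_coeffs = c(20, 0.01),
                                        seed = 1L) {
  weeks <- vapply(profiles, function(p) p$week, integer(1))
  if (anyDuplicated(weeks)) stop("duplicate week values in profiles")
  if (dx <= 0 || dy <= 0) stop("grid spacings must be positive")
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  amp_1732 <- ppdx_band_defaults()$ppdx$amplitude[4]
  out <- vector("list", length(profiles))
  for (k in seq_along(profiles)) {
    prof <- profiles[[k]]
    base_peaks <- ppdx_peaks(prof$shoulder_level, prof$dye_level)
    noise_sd <- prof$noise_sd_rel * amp_1732
    spectra <- vector("list", n_rows * n_cols)
    for (i in seq_len(n_rows * n_cols)) {
      pk <- lapply(base_peaks, function(p) {
        f <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        peak_model(p$center, p$amplitude * f, p$fwhm, p$shape_mix)
      })
      row <- (i - 1L) %/% n_cols + 1L
      col <- (i - 1L) %% n_cols + 1L
      sp <- generate_spectrum(pk, baseline_coeffs = baseline_coeffs,
                              noise_sd = 0,
                              meta = list(week = prof$week,
                                          row = row, col = col))
      if (noise_sd > 0)
        sp$intensities <- sp$intensities +
          stats::rnorm(length(sp$intensities), sd = noise_sd)
      spectra[[i]] <- sp
    }
    grid <- spectrum_grid(spectra, n_rows, n_cols, dx, dy,
                          meta = list(week = prof$week,
                                      profile = prof, seed = seed))
    attr(grid, "reference_spectrum") <-
      generate_spectrum(base_peaks, noise_sd = 0,
                        meta = list(week = prof$week, reference = TRUE))
    out[[k]] <- grid
  }
  names(out) <- as.character(weeks)
  out
}
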