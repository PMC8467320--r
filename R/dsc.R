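#' Construct a thermogram
#'
#' One DSC heating scan: specific heat flow (W per gram) on a strictly
#' ascending temperature grid, with the scan rate needed to convert the
#' temperature integral into a specific enthalpy. Endothermic transitions
#' are positive when `endo_up = TRUE` (the package convention).
#'
#' @param temperature Degrees C, strictly increasing, length >= 2.
#' @param heat_flow W per gram, same length.
#' @param scan_rate Degrees C per minute (> 0). Default 5.
#' @param endo_up Logical; `FALSE` flips the heat-flow sign on input.
#' @param meta Named list (sample mass, period, ...).
#' @return A `ppdx_thermogram` object.
#' @export
thermogram <- function(temperature, heat_flow, scan_rate = 5,
                       endo_up = TRUE, meta = list()) {
  temperature <- as.numeric(temperature)
  heat_flow <- as.numeric(heat_flow)
  if (length(temperature) < 2L) stop("a thermogram needs at least 2 points")
  if (length(temperature) != length(heat_flow))
    stop("temperature and heat_flow differ in length")
  if (any(diff(temperature) <= 0))
    stop("temperatures must be strictly increasing")
  if (scan_rate <= 0) stop("scan_rate must be > 0")
  if (!endo_up) heat_flow <- -heat_flow
  structure(list(temperature = temperature, heat_flow = heat_flow,
                 scan_rate = scan_rate, meta = meta),
            class = "ppdx_thermogram")
}

#' @export
print.ppdx_thermogram <- function(x, ...) {
  cat(sprintf("<thermogram: %d points, %.0f to %.0f degC at %g degC/min>\n",
              length(x$temperature), min(x$temperature),
              max(x$temperature), x$scan_rate))
  invisible(x)
}

#' Generate a synthetic melting thermogram
#'
#' Gaussian melting endotherm over a flat (optionally sloped) instrumental
#' baseline, with the peak amplitude chosen so the integrated specific
#' enthalpy equals `crystallinity_pct / 100 * dH_ref`.
#'
#' @param crystallinity_pct Percent crystalline phase, in `[0, 100]`.
#' @param dH_ref Melting enthalpy of the fully crystalline polymer, J per
#'   gram. Default 141.
#' @param melt_center Peak temperature, degrees C. Default 105.
#' @param melt_fwhm Peak FWHM, degrees C. Default 8.
#' @param noise_sd Additive Gaussian noise SD, W per gram. Default 0.
#' @param seed Integer seed (only used when `noise_sd > 0`).
#' @param T_min,T_max,step Temperature grid, degrees C. Defaults -30 to 150,
#'   step 0.1.
#' @param scan_rate Degrees C per minute. Default 5.
#' @param baseline Length-2 vector `c(intercept, slope)` of the instrumental
#'   baseline in W per gram (slope per degree C). Default `c(0, 0)`.
#' @return A `ppdx_thermogram`; the true enthalpy is attached as attribute
#'   `"true_delta_H"`.
#' @export
generate_thermogram <- function(crystallinity_pct, dH_ref = 141,
                                melt_center = 105, melt_fwhm = 8,
                                noise_sd = 0, seed = NULL,
                                T_min = -30, T_max = 150, step = 0.1,
                                scan_rate = 5, baseline = c(0, 0)) {
  if (crystallinity_pct < 0 || crystallinity_pct > 100)
    stop("crystallinity_pct must lie in [0, 100]")
  if (dH_ref <= 0) stop("dH_ref must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (melt_center - 3 * melt_fwhm < T_min ||
      melt_center + 3 * melt_fwhm > T_max)
    stop("melting peak (center ", melt_center, ", FWHM ", melt_fwhm,
         ") not fully inside the scan range")
  tt <- seq(T_min, T_max, by = step)
  delta_H <- crystallinity_pct / 100 * dH_ref          # J/g
  rate_s <- scan_rate / 60                             # degC per second
  sigma <- melt_fwhm / (2 * sqrt(2 * log(2)))
  amp <- delta_H * rate_s / (sigma * sqrt(2 * pi))     # W/g peak height
  hf <- amp * exp(-(tt - melt_center)^2 / (2 * sigma^2)) +
    baseline[1L] + baseline[2L] * tt
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    hf <- hf + stats::rnorm(length(tt), sd = noise_sd)
  }
  tg <- thermogram(tt, hf, scan_rate = scan_rate,
                   meta = list(crystallinity_pct = crystallinity_pct,
                               dH_ref = dH_ref))
  attr(tg, "true_delta_H") <- delta_H
  tg
}

#' Integrate a melting endotherm
#'
#' Specific melting enthalpy over an explicit temperature window: a linear
#' baseline is drawn between the heat-flow values at the window endpoints,
#' the excess heat flow is trapezoid-integrated over temperature, and the
#' result is divided by the scan rate (converted to degrees C per second) so
#' units close to J per gram.
#'
#' @param tg A [thermogram()].
#' @param T_lo,T_hi Integration window, degrees C, inside the scan range.
#' @param edge_halfwin Half width (degrees C) of the neighborhood around
#'   each window limit over which the baseline anchor level is averaged;
#'   anchoring on single noisy samples would propagate their noise across
#'   the whole window. 0 uses the interpolated endpoint values only.
#'   Default 1.
#' @param sign_tol Tolerance (J/g) below which a negative net area raises an
#'   error as a wrong-sign-convention signal. Default 0.5.
#' @return `delta_H` in J per gram.
#' @export
integrate_endotherm <- function(tg, T_lo, T_hi, edge_halfwin = 1,
                                sign_tol = 0.5) {
  stopifnot(inherits(tg, "ppdx_thermogram"))
  if (T_lo >= T_hi) stop("T_lo must be < T_hi")
  tt <- tg$temperature
  if (T_lo < min(tt) || T_hi > max(tt))
    stop("integration window [", T_lo, ", ", T_hi,
         "] outside the scan range")
  anchor <- function(T0) {
    sel <- which(abs(tt - T0) <= edge_halfwin)
    if (length(sel) < 2L) stats::approx(tt, tg$heat_flow, xout = T0)$y
    else mean(tg$heat_flow[sel])
  }
  y_lo <- anchor(T_lo)
  y_hi <- anchor(T_hi)
  inside <- which(tt > T_lo & tt < T_hi)
  xs <- c(T_lo, tt[inside], T_hi)
  ys <- c(y_lo, tg$heat_flow[inside], y_hi)
  base <- y_lo + (y_hi - y_lo) * (xs - T_lo) / (T_hi - T_lo)
  excess <- ys - base
  area <- sum(diff(xs) * (utils::head(excess, -1) + utils::tail(excess, -1)) / 2)
  delta_H <- area / (tg$scan_rate / 60)
  if (delta_H < -sign_tol)
    stop("net endotherm area is negative (", signif(delta_H, 4),
         " J/g); check the endo_up sign convention")
  delta_H
}

#' Convert a melting enthalpy to percent crystallinity
#'
#' @param delta_H Measured specific melting enthalpy, J per gram.
#' @param dH_ref Reference enthalpy of the fully crystalline polymer, J per
#'   gram (> 0). The packaged default of 141 J/g is a literature convention
#'   for polydioxanone, not a measured value.
#' @param window Optional integration window recorded in the result.
#' @return A `crystallinity_result` list: `delta_H`, `dH_ref`,
#'   `crystallinity_pct`, `window`.
#' @export
crystallinity <- function(delta_H, dH_ref = 141, window = c(NA_real_, NA_real_)) {
  if (dH_ref <= 0) stop("dH_ref must be > 0")
  structure(list(delta_H = delta_H, dH_ref = dH_ref,
                 crystallinity_pct = 100 * delta_H / dH_ref,
                 window = window),
            class = "crystallinity_result")
}

#' @export
print.crystallinity_result <- function(x, ...) {
  cat(sprintf("<crystallinity: %.1f %% (delta_H %.1f J/g, ref %.0f J/g)>\n",
              x$crystallinity_pct, x$delta_H, x$dH_ref))
  invisible(x)
}

#' Crystallinity over replicate thermograms
#'
#' Integrates each replicate over the same window and reports per-replicate
#' crystallinity plus mean and SD (SD is `NA` for a single replicate, never
#' reported as 0).
#'
#' @param tgs List of [thermogram()] objects (>= 1).
#' @param T_lo,T_hi Integration window, degrees C.
#' @param dH_ref Reference enthalpy, J per gram.
#' @return List with `per_replicate` (numeric vector of percent), `mean`,
#'   `sd`.
#' @export
replicate_crystallinity <- function(tgs, T_lo, T_hi, dH_ref = 141) {
  if (!length(tgs)) stop("need at least one thermogram")
  pct <- vapply(tgs, function(tg)
    crystallinity(integrate_endotherm(tg, T_lo, T_hi), dH_ref,
                  window = c(T_lo, T_hi))$crystallinity_pct, numeric(1))
  list(per_replicate = pct, mean = mean(pct),
       sd = if (length(pct) > 1L) stats::sd(pct) else NA_real_)
}
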