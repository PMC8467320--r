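#' Peak height within a window
#'
#' Height of the local maximum inside `[center - half_window,
#' center + half_window]` on a baseline-corrected spectrum, together with the
#' wavenumber at which it occurs. Ties are broken toward the lowest
#' wavenumber.
#'
#' @param spec A baseline-corrected [spectrum()].
#' @param center Window center, cm-1.
#' @param half_window Half width of the search window, cm-1.
#' @return List with `height` (counts) and `position` (cm-1).
#' @export
peak_height <- function(spec, center, half_window = 5) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  wn <- spec$wavenumbers
  if (center - half_window < min(wn) || center + half_window > max(wn))
    stop("peak window [", center - half_window, ", ", center + half_window,
         "] outside the spectral range")
  sel <- which(wn >= center - half_window & wn <= center + half_window)
  i <- sel[which.max(spec$intensities[sel])]  # which.max: first = lowest wn
  list(height = spec$intensities[i], position = wn[i])
}

# Trapezoid integral of (wn, y) restricted to [lo, hi], with linear
# interpolation at the window edges so the limits are honored exactly even
# when they fall between grid points.
trapz_window <- function(wn, y, lo, hi) {
  if (lo < min(wn) || hi > max(wn)) stop("integration window outside range")
  inside <- which(wn > lo & wn < hi)
  xs <- c(lo, wn[inside], hi)
  ys <- c(stats::approx(wn, y, xout = lo)$y, y[inside],
          stats::approx(wn, y, xout = hi)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

#' Normalized shoulder area of the 1732 cm-1 carbonyl peak
#'
#' The degradation metric: the spectrum is divided by the height of the
#' 1732 cm-1 ester carbonyl peak, then the normalized intensity is
#' trapezoid-integrated over the shoulder window 1736-1749 cm-1 (linear
#' interpolation at the window edges). The result has units of cm-1 and
#' shrinks as the amorphous-phase carbonyl contribution is lost to
#' hydrolysis.
#'
#' @param spec A baseline-corrected [spectrum()] covering at least
#'   1725-1755 cm-1.
#' @param window Integration window, cm-1. Default `c(1736, 1749)`.
#' @param peak_center Carbonyl peak center, cm-1. Default 1732.
#' @param peak_half_window Search half-window for the peak height. Default 5.
#' @param peak_mode `"argmax"` (default) takes the local maximum in the
#'   window; `"fixed"` reads the intensity at the grid point nearest
#'   `peak_center`.
#' @return A `shoulder_metric` list: `normalized_area` (cm-1),
#'   `peak_height_1732` (counts, pre-normalization), `peak_position`,
#'   `window`.
#' @export
shoulder_area <- function(spec, window = c(1736, 1749), peak_center = 1732,
                          peak_half_window = 5,
                          peak_mode = c("argmax", "fixed")) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  peak_mode <- match.arg(peak_mode)
  wn <- spec$wavenumbers
  if (min(wn) > 1725 || max(wn) < 1755)
    stop("spectrum must cover 1725-1755 cm-1 for the shoulder metric")
  if (peak_mode == "argmax") {
    ph <- peak_height(spec, peak_center, peak_half_window)
  } else {
    i <- which.min(abs(wn - peak_center))
    ph <- list(height = spec$intensities[i], position = wn[i])
  }
  if (ph$height <= 0)
    stop("non-positive 1732 cm-1 peak height (", signif(ph$height, 4),
         "); shoulder metric undefined")
  ynorm <- spec$intensities / ph$height
  area <- trapz_window(wn, ynorm, window[1], window[2])
  structure(list(normalized_area = area, peak_height_1732 = ph$height,
                 peak_position = ph$position, window = window),
            class = "shoulder_metric")
}

#' Shoulder metric for every spectrum of a grid
#'
#' Applies baseline correction followed by [shoulder_area()] to each grid
#' spectrum, preserving row-major order. Failures are collected per grid
#' position and raised together, never dropped silently.
#'
#' @param grid A [spectrum_grid()].
#' @param method,params Baseline correction, as in [correct_baseline()];
#'   `method = "none"` skips correction (already-corrected input).
#' @return A data.frame with one row per grid point: `row`, `col`,
#'   `normalized_area`, `peak_height`.
#' @export
grid_shoulder_metrics <- function(grid, method = "asls", params = list()) {
  stopifnot(inherits(grid, "ppdx_spectrum_grid"))
  n <- length(grid$spectra)
  res <- vector("list", n)
  failures <- character(0)
  for (i in seq_len(n)) {
    row <- (i - 1L) %/% grid$n_cols + 1L
    col <- (i - 1L) %% grid$n_cols + 1L
    m <- tryCatch({
      sp <- grid$spectra[[i]]
      if (!identical(method, "none"))
        sp <- correct_baseline(sp, method, params)
      shoulder_area(sp)
    }, error = function(e) e)
    if (inherits(m, "error")) {
      failures <- c(failures,
                    sprintf("(row %d, col %d): %s", row, col,
                            conditionMessage(m)))
    } else {
      res[[i]] <- data.frame(row = row, col = col,
                             normalized_area = m$normalized_area,
                             peak_height = m$peak_height_1732)
    }
  }
  if (length(failures))
    stop("shoulder metric failed at ", length(failures),
         " grid position(s):\n  ", paste(failures, collapse = "\n  "))
  do.call(rbind, res)
}

#' Dye band heights normalized to the 870 cm-1 PPDX band
#'
#' Heights of the five Solvent Violet 13 dye bands (483, 1242, 1403, 1610,
#' 1638 cm-1), each divided by the height of the 870 cm-1 C-O-C band, which
#' serves as internal standard since the PPDX bands are stable under
#' degradation.
#'
#' @param spec A baseline-corrected Raman [spectrum()].
#' @param centers Dye band centers, cm-1.
#' @param half_window Search half-window per band, cm-1. Default 6.
#' @param ref_center Internal-standard band center. Default 870.
#' @return Named numeric vector of normalized heights (names = centers).
#' @export
dye_peak_heights <- function(spec, centers = c(483, 1242, 1403, 1610, 1638),
                             half_window = 6, ref_center = 870) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  wn <- spec$wavenumbers
  for (ctr in c(centers, ref_center)) {
    if (ctr - half_window < min(wn) || ctr + half_window > max(wn))
      stop("spectrum does not cover the window around ", ctr, " cm-1")
  }
  ref <- peak_height(spec, ref_center, half_window)
  if (ref$height <= 0)
    stop("non-positive 870 cm-1 reference peak height")
  h <- vapply(centers, function(ctr)
    peak_height(spec, ctr, half_window)$height / ref$height, numeric(1))
  stats::setNames(h, as.character(centers))
}

#' Score the emergence of a band against a local baseline
#'
#' Detects a weak band growing in a previously featureless region (default:
#' the 1605 cm-1 carboxylate band of FT-IR spectra of hydrolyzed PPDX). A
#' local linear baseline through the two window edges is subtracted, the
#' maximum of the residual inside the window is taken, and the result is
#' normalized to the carbonyl peak height.
#'
#' @param spec A [spectrum()] covering the window and the carbonyl band.
#' @param center Band center, cm-1. Default 1605.
#' @param half_window Half width of the search window, cm-1. Default 20.
#' @param ref_center Carbonyl reference band, cm-1. Default 1733.
#' @param ref_half_window Search half-window for the reference. Default 5.
#' @param edge_points Number of grid points averaged (median) at each window
#'   edge for the local baseline. Default 3.
#' @return Normalized emergence score (dimensionless).
#' @export
band_emergence <- function(spec, center = 1605, half_window = 20,
                           ref_center = 1733, ref_half_window = 5,
                           edge_points = 3L) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  wn <- spec$wavenumbers
  lo <- center - half_window; hi <- center + half_window
  if (lo < min(wn) || hi > max(wn))
    stop("band window [", lo, ", ", hi, "] outside the spectral range")
  ref <- peak_height(spec, ref_center, ref_half_window)
  if (ref$height <= 0) stop("non-positive carbonyl reference height")
  sel <- which(wn >= lo & wn <= hi)
  nlo <- utils::head(sel, edge_points)
  nhi <- utils::tail(sel, edge_points)
  x0 <- stats::median(wn[nlo]); y0 <- stats::median(spec$intensities[nlo])
  x1 <- stats::median(wn[nhi]); y1 <- stats::median(spec$intensities[nhi])
  base <- y0 + (y1 - y0) * (wn[sel] - x0) / (x1 - x0)
  max(spec$intensities[sel] - base) / ref$height
}
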