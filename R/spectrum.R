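#' Construct a spectrum object
#'
#' A `ppdx_spectrum` holds one vibrational spectrum: a strictly ascending
#' wavenumber grid (cm-1) and the matching intensity trace (arbitrary counts).
#' Raman and FT-IR traces share the container; `kind` is metadata only.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm-1, strictly
#'   increasing, length >= 2.
#' @param intensities Numeric vector of intensities (counts), same length,
#'   all finite.
#' @param kind `"raman"` or `"ftir"`.
#' @param meta Named list of free-form metadata (degradation period, grid
#'   position, ...).
#' @return An object of class `ppdx_spectrum`.
#' @export
spectrum <- function(wavenumbers, intensities, kind = c("raman", "ftir"),
                     meta = list()) {
  kind <- match.arg(kind)
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points")
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities differ in length (",
         length(wavenumbers), " vs ", length(intensities), ")")
  if (any(!is.finite(wavenumbers)) || any(!is.finite(intensities)))
    stop("spectrum contains non-finite values")
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         kind = kind, meta = meta),
    class = "ppdx_spectrum"
  )
}

#' @export
print.ppdx_spectrum <- function(x, ...) {
  cat(sprintf("<%s spectrum: %d points, %.0f-%.0f cm-1>\n",
              x$kind, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a spatial grid of spectra
#'
#' Mirrors the acquisition layout used for stent mapping: spectra collected in
#' a regular rectangular grid on the fiber top surface, stored row-major.
#'
#' @param spectra List of [spectrum()] objects, row-major, length
#'   `n_rows * n_cols`.
#' @param n_rows,n_cols Grid dimensions.
#' @param dx,dy Grid spacings in micrometers (defaults 12.9 and 11.4).
#' @param meta Named list of grid-level metadata (e.g. `week`).
#' @return An object of class `ppdx_spectrum_grid`.
#' @export
spectrum_grid <- function(spectra, n_rows = 8L, n_cols = 8L,
                          dx = 12.9, dy = 11.4, meta = list()) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (length(spectra) != n_rows * n_cols)
    stop("expected ", n_rows * n_cols, " spectra, got ", length(spectra))
  if (!all(vapply(spectra, inherits, logical(1), "ppdx_spectrum")))
    stop("all elements must be ppdx_spectrum objects")
  if (dx <= 0 || dy <= 0) stop("grid spacings must be positive")
  structure(
    list(spectra = spectra, n_rows = n_rows, n_cols = n_cols,
         dx = dx, dy = dy, meta = meta),
    class = "ppdx_spectrum_grid"
  )
}

#' @export
print.ppdx_spectrum_grid <- function(x, ...) {
  cat(sprintf("<spectrum grid: %d x %d, spacing %.1f x %.1f um>\n",
              x$n_rows, x$n_cols, x$dx, x$dy))
  invisible(x)
}

#' Noiseless reference spectrum of a generated grid
#'
#' Grids produced by [generate_degradation_series()] carry the noiseless,
#' baseline-free spectrum built from the unperturbed peak amplitudes of their
#' degradation profile; it defines the ground-truth shoulder metric for the
#' period.
#'
#' @param grid A `ppdx_spectrum_grid` from the generator.
#' @return A `ppdx_spectrum`, or an error for grids without a stored
#'   reference.
#' @export
reference_spectrum <- function(grid) {
  ref <- attr(grid, "reference_spectrum")
  if (is.null(ref))
    stop("grid carries no noiseless reference spectrum")
  ref
}
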