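#' Asymmetric least squares baseline estimate
#'
#' Eilers-style AsLS: iteratively reweighted Whittaker smoothing where points
#' above the running baseline get weight `p` and points below `1 - p`, so the
#' smooth curve hugs the lower envelope of the spectrum. The smoother solves
#' `(W + lambda * D'D) z = W y` with D the second-difference operator, using
#' sparse matrices.
#'
#' With a strongly asymmetric `p` the curvature penalty does not prevent the
#' whole baseline from settling on the lower noise envelope (a constant
#' shift is penalty-free), which would bias peak quantification upward. The
#' baseline is therefore estimated on a lightly moving-average-smoothed copy
#' of the trace (`smooth_halfwin` points to each side) and subtracted from
#' the raw trace; the spectrum itself is never smoothed.
#'
#' @param y Intensity vector.
#' @param lambda Smoothness penalty (default 1e6).
#' @param p Asymmetry weight for points above the baseline (default 0.001).
#' @param max_iter Maximum reweighting iterations (default 50).
#' @param tol Relative baseline-change convergence threshold (default 1e-6).
#' @param smooth_halfwin Half width (points) of the moving average applied
#'   to the copy on which the baseline is estimated; 0 disables. Default 7.
#' @return Numeric baseline vector, same length as `y`.
#' @keywords internal
asls_baseline <- function(y, lambda = 1e6, p = 0.001, max_iter = 50L,
                          tol = 1e-6, smooth_halfwin = 7L) {
  if (smooth_halfwin > 0L) {
    k <- rep(1 / (2 * smooth_halfwin + 1), 2 * smooth_halfwin + 1)
    ys <- as.numeric(stats::filter(y, k, sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
    y <- ys
  }
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L),
                                           rep(-2, m - 2L),
                                           rep(1, m - 2L)))
  P <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(m, w)
    z_new <- as.numeric(Matrix::solve(W + P, w * y))
    delta <- max(abs(z_new - z)) / max(abs(z_new), 1e-12)
    z <- z_new
    w_new <- ifelse(y > z, p, 1 - p)
    if (delta < tol || all(w_new == w)) return(z)
    w <- w_new
  }
  stop("AsLS baseline did not converge within ", max_iter,
       " iterations (last relative change ", signif(delta, 3), ")")
}

#' Remove the baseline from a spectrum
#'
#' Two estimators are offered. `"asls"` (default) is asymmetric least
#' squares, a smooth lower-envelope fit suitable for broad fluorescence-like
#' backgrounds. `"linear_anchors"` fits a piecewise-linear baseline through
#' anchor points: at each anchor wavenumber the local baseline level is taken
#' as the median intensity within `anchor_halfwin` cm-1, and levels are
#' linearly interpolated between anchors (constant extrapolation outside).
#'
#' @param spec A [spectrum()].
#' @param method `"asls"` or `"linear_anchors"`.
#' @param params Named list of estimator parameters. For `asls`: `lambda`,
#'   `p`, `max_iter`, `tol`, `smooth_halfwin`. For `linear_anchors`: `anchors` (>= 2
#'   wavenumbers inside the spectral range, required) and `anchor_halfwin`
#'   (cm-1, default 0 = use the nearest grid point only).
#' @return A new baseline-corrected `ppdx_spectrum`; the input is untouched.
#'   The estimated baseline is attached as attribute `"baseline"`.
#' @export
correct_baseline <- function(spec, method = c("asls", "linear_anchors"),
                             params = list()) {
  stopifnot(inherits(spec, "ppdx_spectrum"))
  method <- match.arg(method)
  wn <- spec$wavenumbers
  y <- spec$intensities
  if (method == "asls") {
    base <- asls_baseline(y,
                          lambda = params$lambda %||% 1e6,
                          p = params$p %||% 0.001,
                          max_iter = params$max_iter %||% 50L,
                          tol = params$tol %||% 1e-6,
                          smooth_halfwin = params$smooth_halfwin %||% 7L)
  } else {
    anchors <- params$anchors
    if (is.null(anchors) || length(anchors) < 2L)
      stop("linear_anchors needs >= 2 anchor wavenumbers")
    if (any(anchors < min(wn)) || any(anchors > max(wn)))
      stop("anchor wavenumbers outside the spectral range")
    hw <- params$anchor_halfwin %||% 0
    anchors <- sort(anchors)
    levels <- vapply(anchors, function(a) {
      sel <- abs(wn - a) <= hw
      if (!any(sel)) sel[which.min(abs(wn - a))] <- TRUE
      stats::median(y[sel])
    }, numeric(1))
    base <- stats::approx(anchors, levels, xout = wn, rule = 2)$y
  }
  out <- spec
  out$intensities <- y - base
  attr(out, "baseline") <- base
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
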