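#' Distribution specification for crack population parameters
#'
#' Small tagged lists describing how a crack property is drawn:
#' `dist_lognormal(median, sigma)` (median on the natural scale, log-scale
#' SD), `dist_normal(mean, sd)`, `dist_uniform(min, max)`,
#' `dist_fixed(value)`.
#'
#' @param median,sigma,mean,sd,min,max,value Distribution parameters.
#' @return A `dist_spec` list.
#' @export
dist_lognormal <- function(median, sigma) {
  if (median <= 0 || sigma < 0) stop("invalid lognormal parameters")
  structure(list(kind = "lognormal", meanlog = log(median), sdlog = sigma),
            class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_normal <- function(mean, sd) {
  if (sd < 0) stop("sd must be >= 0")
  structure(list(kind = "normal", mean = mean, sd = sd), class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_uniform <- function(min, max) {
  if (max < min) stop("max < min")
  structure(list(kind = "uniform", min = min, max = max), class = "dist_spec")
}

#' @rdname dist_lognormal
#' @export
dist_fixed <- function(value) {
  structure(list(kind = "fixed", value = value), class = "dist_spec")
}

draw_dist <- function(spec, n) {
  switch(spec$kind,
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         normal = stats::rnorm(n, spec$mean, spec$sd),
         uniform = stats::runif(n, spec$min, spec$max),
         fixed = rep(spec$value, n),
         stop("unknown distribution kind: ", spec$kind))
}

#' Crack population specification
#'
#' Describes a synthetic population of surface cracks, rasterized as filled
#' ellipses into a binary field. The default field is the 84 x 63 um SEM
#' region; orientations are wrapped to `[0, 180)` degrees measured
#' counterclockwise from the horizontal in the mathematical (y up) frame.
#'
#' @param n_cracks Number of cracks (>= 0).
#' @param length_dist `dist_spec` for the major-axis length, um.
#' @param aspect_dist `dist_spec` for the major/minor axis ratio (>= 1).
#' @param angle_dist `dist_spec` for the orientation, degrees.
#' @param merge_prob Probability that a crack is chained end-to-end onto the
#'   previous one (forming a single connected component). Default 0.
#' @param pixel_size Micrometers per pixel. Default 0.066.
#' @param field_size `c(width, height)` in micrometers. Default `c(84, 63)`.
#' @return A `crack_population_spec` object.
#' @export
crack_population_spec <- function(n_cracks, length_dist, aspect_dist,
                                  angle_dist, merge_prob = 0,
                                  pixel_size = 0.066,
                                  field_size = c(84, 63)) {
  if (n_cracks < 0) stop("n_cracks must be >= 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (merge_prob < 0 || merge_prob > 1) stop("merge_prob must lie in [0, 1]")
  if (length(field_size) != 2L || any(field_size <= 0))
    stop("field_size must be two positive lengths")
  structure(list(n_cracks = as.integer(n_cracks), length_dist = length_dist,
                 aspect_dist = aspect_dist, angle_dist = angle_dist,
                 merge_prob = merge_prob, pixel_size = pixel_size,
                 field_size = field_size),
            class = "crack_population_spec")
}

# Rasterize one ellipse into logical values over a pixel bounding box.
# Coordinates: x right, y up, in micrometers; pixel (r, c) center at
# ((c - 0.5) * ps, (nr - r + 0.5) * ps).
ellipse_pixels <- function(cx, cy, a, b, theta_deg, ps, nr, nc) {
  th <- theta_deg * pi / 180
  half <- max(a, b)
  c_lo <- max(1L, floor((cx - half) / ps))
  c_hi <- min(nc, ceiling((cx + half) / ps))
  r_lo <- max(1L, nr - ceiling((cy + half) / ps) + 1L)
  r_hi <- min(nr, nr - floor((cy - half) / ps))
  if (c_lo > c_hi || r_lo > r_hi) return(integer(0))
  cc <- rep(c_lo:c_hi, each = r_hi - r_lo + 1L)
  rr <- rep(r_lo:r_hi, times = c_hi - c_lo + 1L)
  x <- (cc - 0.5) * ps - cx
  y <- (nr - rr + 0.5) * ps - cy
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  keep <- u^2 + v^2 <= 1
  (cc[keep] - 1L) * nr + rr[keep]             # column-major linear indices
}

# 8-neighborhood dilation of a set of linear indices (clipped to the field)
dilate_idx <- function(idx, nr, nc) {
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  out <- integer(0)
  for (dr in -1L:1L) for (dc in -1L:1L) {
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- c(out, (cc[ok] - 1L) * nr + rr[ok])
  }
  unique(out)
}

#' Generate a synthetic crack mask with ground truth
#'
#' Rasterizes `n_cracks` filled ellipses into a binary field. By default
#' cracks are placed by rejection sampling so that no two touch (not even
#' diagonally), keeping the ground truth unambiguous: labeling the mask
#' recovers exactly one component per crack. With `merge_prob > 0`, a crack
#' may instead be chained onto the end of the previous one (same
#' orientation, touching), emulating cracks merging into longer gaps.
#'
#' @param spec A [crack_population_spec()].
#' @param seed Integer seed.
#' @param max_attempts Placement attempts per crack before giving up.
#' @return List with `mask` (a [binary_mask()]) and `truth` (data.frame:
#'   one row per drawn crack with `length`, `aspect`, `angle`, `cx`, `cy`,
#'   `merged_with_prev`).
#' @export
generate_crack_mask <- function(spec, seed = 1L, max_attempts = 500L) {
  stopifnot(inherits(spec, "crack_population_spec"))
  set.seed(seed)
  ps <- spec$pixel_size
  W <- spec$field_size[1L]; H <- spec$field_size[2L]
  nc <- as.integer(round(W / ps)); nr <- as.integer(round(H / ps))
  mask <- matrix(0L, nr, nc)
  truth <- vector("list", spec$n_cracks)
  if (spec$n_cracks == 0L)
    return(list(mask = binary_mask(mask, ps),
                truth = data.frame(length = numeric(0), aspect = numeric(0),
                                   angle = numeric(0), cx = numeric(0),
                                   cy = numeric(0),
                                   merged_with_prev = logical(0))))
  # Draw the whole population first, then place by rejection over positions
  # only; redrawing sizes on rejection would bias the placed population
  # toward small cracks. Larger cracks are placed first to ease packing.
  n <- spec$n_cracks
  L <- draw_dist(spec$length_dist, n)
  A <- pmax(1, draw_dist(spec$aspect_dist, n))
  th <- draw_dist(spec$angle_dist, n) %% 180
  merge_flag <- c(FALSE, stats::runif(max(0L, n - 1L)) < spec$merge_prob)
  if (any(L > min(W, H)))
    stop("field ", W, " x ", H, " um too small for a drawn crack of ",
         signif(max(L), 3), " um")
  min_len_px <- min(L) / ps
  ord <- c(which(!merge_flag)[order(-L[!merge_flag])], which(merge_flag))
  cx_out <- cy_out <- numeric(n)
  prev_end <- NULL
  for (i in ord) {
    a <- L[i] / 2; b <- L[i] / (2 * A[i])
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      if (merge_flag[i] && !is.null(prev_end)) {
        # continue from the previous crack's end along its direction
        thp <- prev_end$angle * pi / 180
        # small overlap: tangent tips rasterize with a gap otherwise
        reach <- a - min(a, max(3 * ps, 0.05 * a))
        cx <- prev_end$x + reach * cos(thp)
        cy <- prev_end$y + reach * sin(thp)
        th[i] <- prev_end$angle
        if (cx - a < 0 || cx + a > W || cy - a < 0 || cy + a > H) {
          # forward extension leaves the field: chain off the other end
          cx <- prev_end$x0 - reach * cos(thp)
          cy <- prev_end$y0 - reach * sin(thp)
        }
        if (cx - a < 0 || cx + a > W || cy - a < 0 || cy + a > H) {
          merge_flag[i] <- FALSE              # chain left the field: fall back
          next
        }
      } else {
        cx <- stats::runif(1L, a, W - a)
        cy <- stats::runif(1L, a, H - a)
      }
      idx <- ellipse_pixels(cx, cy, a, b, th[i], ps, nr, nc)
      if (!length(idx)) next
      if (merge_flag[i] && !is.null(prev_end)) {
        if (!any(mask[idx] != 0L)) {          # must actually touch the chain
          merge_flag[i] <- FALSE
          next
        }
      } else {
        grown <- dilate_idx(idx, nr, nc)
        if (any(mask[grown] != 0L)) next      # reject touching placements
      }
      mask[idx] <- 1L
      thr <- th[i] * pi / 180
      prev_end <- list(x = cx + a * cos(thr), y = cy + a * sin(thr),
                       x0 = cx - a * cos(thr), y0 = cy - a * sin(thr),
                       angle = th[i])
      cx_out[i] <- cx; cy_out[i] <- cy
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place crack ", i, " (length ", signif(L[i], 3),
           " um) after ", max_attempts,
           " attempts; field too small or too crowded")
  }
  truth <- list(data.frame(length = L, aspect = A, angle = th,
                           cx = cx_out, cy = cy_out,
                           merged_with_prev = merge_flag))
  if (min_len_px < 5)
    warning("shortest drawn crack spans only ", signif(min_len_px, 3),
            " pixels; consider a smaller pixel_size")
  list(mask = binary_mask(mask, ps), truth = do.call(rbind, truth))
}

#' Default crack population specs for the degradation series
#'
#' The three periods on which cracks are observed (8, 16 and 24 weeks).
#' Major-axis lengths are lognormal with the period's median Feret diameter
#' (0.85, 1.87, 5.21 um) and log-SD 0.6; orientations are normal around the
#' period's mean Feret angle (87.3 +/- 28.5, 89.6 +/- 27.0,
#' 89.0 +/- 19.1 degrees), i.e. near-perpendicular to the fiber axis;
#' aspect ratios are fixed at the period's mean (4.0, 3.9, 6.05).
#'
#' @param n_cracks Cracks per field (default 200).
#' @param pixel_size Micrometers per pixel (default 0.066).
#' @return Named list (week) of [crack_population_spec()] objects.
#' @export
default_crack_specs <- function(n_cracks = 200L, pixel_size = 0.066) {
  mk <- function(med, ang_mean, ang_sd, aspect)
    crack_population_spec(n_cracks,
                          length_dist = dist_lognormal(med, 0.6),
                          aspect_dist = dist_fixed(aspect),
                          angle_dist = dist_normal(ang_mean, ang_sd),
                          pixel_size = pixel_size)
  list(`8` = mk(0.85, 87.3, 28.5, 4.0),
       `16` = mk(1.87, 89.6, 27.0, 3.9),
       `24` = mk(5.21, 89.0, 19.1, 6.05))
}
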