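#' Construct a binary mask
#'
#' Foreground/background image for crack morphometry. Row 1 is the top of
#' the image, column 1 the left; pixels are isotropic squares of side
#' `pixel_size` micrometers. All geometric outputs are reported in a
#' conventional mathematical frame (y increasing upward), so orientation
#' angles fall in `[0, 180)` measured counterclockwise from the positive
#' horizontal axis.
#'
#' @param pixels Integer/logical matrix; non-zero = foreground.
#' @param pixel_size Micrometers per pixel (> 0).
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(pixels, pixel_size) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a matrix of at least 1 x 1")
  if (!is.finite(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  m <- matrix(as.integer(pixels != 0), nrow(pixels), ncol(pixels))
  structure(list(pixels = m, pixel_size = pixel_size), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary mask: %d x %d px, %.4g um/px, %d foreground px>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, sum(x$pixels)))
  invisible(x)
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Label connected components
#'
#' Flood-fill labeling of foreground pixels. Labels are assigned in
#' deterministic row-major first-seen order: the component whose topmost,
#' then leftmost pixel comes first receives label 1.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8; thin diagonal cracks stay
#'   connected under 8).
#' @return List with `labels` (integer matrix, 0 = background) and `n`
#'   (component count).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(inherits(mask, "binary_mask"))
  off <- neighbor_offsets(as.integer(connectivity))
  px <- mask$pixels
  nr <- nrow(px); nc <- ncol(px)
  labels <- matrix(0L, nr, nc)
  fg <- px != 0L
  # row-major scan order of foreground pixels
  ord <- which(t(fg))                       # linear index in transposed = row-major
  ord_r <- (ord - 1L) %/% nc + 1L
  ord_c <- (ord - 1L) %% nc + 1L
  n <- 0L
  for (s in seq_along(ord)) {
    r0 <- ord_r[s]; c0 <- ord_c[s]
    if (labels[r0, c0] != 0L) next
    n <- n + 1L
    frontier <- (c0 - 1L) * nr + r0         # column-major linear indices
    labels[frontier] <- n
    while (length(frontier)) {
      fr <- (frontier - 1L) %% nr + 1L
      fc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(off))) {
        rr <- fr + off[k, 1L]; cc <- fc + off[k, 2L]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[fg[idx] & labels[idx] == 0L]
        if (length(idx)) {
          labels[idx] <- n
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  list(labels = labels, n = n)
}

# Corner-lattice coordinates: pixel (r, c) occupies x in [c-1, c],
# y in [nr-r, nr-r+1] (y up). All polygons below live in this frame.

#' Trace the outer boundary polygon of a labeled component
#'
#' Returns the closed outer contour of the component as a polygon on the
#' pixel-corner lattice, counterclockwise in the mathematical (y up) frame,
#' with collinear vertices merged. Interior holes are ignored. At pinch
#' vertices (two pixels of the component touching only diagonally) the trace
#' crosses the pinch under 8-connectivity and separates under 4.
#'
#' @param labeled Result of [label_components()].
#' @param label Component label (> 0).
#' @param connectivity 4 or 8; should match the labeling connectivity.
#' @return Two-column matrix (`x`, `y`) of polygon vertices in pixel units,
#'   open form (last vertex connects back to the first).
#' @export
trace_boundary <- function(labeled, label, connectivity = 8L) {
  labels <- labeled$labels
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels == label)
  if (!length(idx)) stop("label ", label, " not present in mask")
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  inside <- function(rr, cc) {
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- logical(length(rr)); out[ok] <- labels[(cc[ok] - 1L) * nr + rr[ok]] == label
    out
  }
  # directed boundary edges, component on the left (CCW outer loop, y up)
  ex0 <- ey0 <- ex1 <- ey1 <- numeric(0)
  add <- function(sel, x0, y0, x1, y1) {
    ex0 <<- c(ex0, x0[sel]); ey0 <<- c(ey0, y0[sel])
    ex1 <<- c(ex1, x1[sel]); ey1 <<- c(ey1, y1[sel])
  }
  yb <- nr - r       # bottom y of pixel
  yt <- nr - r + 1L  # top y
  add(!inside(r + 1L, c), c - 1L, yb, c, yb)   # bottom edge, rightward
  add(!inside(r, c + 1L), c, yb, c, yt)        # right edge, upward
  add(!inside(r - 1L, c), c, yt, c - 1L, yt)   # top edge, leftward
  add(!inside(r, c - 1L), c - 1L, yt, c - 1L, yb) # left edge, downward
  key <- function(x, y) paste(x, y)
  from <- key(ex0, ey0)
  out_edges <- split(seq_along(ex0), from)
  used <- logical(length(ex0))
  loops <- list()
  for (e0 in seq_along(ex0)) {
    if (used[e0]) next
    verts_x <- ex0[e0]; verts_y <- ey0[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      vx <- ex1[e]; vy <- ey1[e]
      verts_x <- c(verts_x, vx); verts_y <- c(verts_y, vy)
      cand <- out_edges[[key(vx, vy)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      if (length(cand) > 1L) {
        # pinch vertex: pick by turn direction relative to incoming edge
        din <- c(ex1[e] - ex0[e], ey1[e] - ey0[e])
        crossz <- vapply(cand, function(j) {
          dj <- c(ex1[j] - ex0[j], ey1[j] - ey0[j])
          din[1L] * dj[2L] - din[2L] * dj[1L]
        }, numeric(1))
        # 8-connectivity: cross the pinch (rightmost turn); 4: split (leftmost)
        e <- if (connectivity == 8L) cand[which.min(crossz)]
             else cand[which.max(crossz)]
      } else e <- cand
    }
    loops[[length(loops) + 1L]] <- cbind(x = utils::head(verts_x, -1L),
                                         y = utils::head(verts_y, -1L))
  }
  areas <- vapply(loops, function(p) polygon_signed_area(p), numeric(1))
  poly <- loops[[which.max(areas)]]        # outer loop: largest CCW area
  merge_collinear(poly)
}

polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

merge_collinear <- function(p) {
  n <- nrow(p)
  if (n < 3L) return(p)
  keep <- logical(n)
  for (i in seq_len(n)) {
    a <- p[if (i == 1L) n else i - 1L, ]
    b <- p[i, ]
    d <- p[if (i == n) 1L else i + 1L, ]
    keep[i] <- abs((b[1L] - a[1L]) * (d[2L] - a[2L]) -
                   (b[2L] - a[2L]) * (d[1L] - a[1L])) > 1e-12
  }
  p[keep, , drop = FALSE]
}

#' Convex hull of a point set
#'
#' Andrew's monotone-chain hull: the minimal convex polygon containing all
#' points, counterclockwise, with collinear boundary points removed.
#' Degenerate (all-collinear) input yields the two extreme points; a single
#' distinct point yields itself.
#'
#' @param points Two-column matrix of coordinates.
#' @return Two-column matrix of hull vertices, counterclockwise.
#' @export
convex_hull <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  if (nrow(points) < 1L) stop("convex hull of an empty point set")
  pts <- unique(points[order(points[, 1L], points[, 2L]), , drop = FALSE])
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  cross <- function(o, a, b)
    (a[1L] - o[1L]) * (b[2L] - o[2L]) - (a[2L] - o[2L]) * (b[1L] - o[1L])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2L &&
             cross(pts[h[length(h) - 1L], ], pts[h[length(h)], ],
                   pts[i, ]) <= 1e-12) h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  if (length(hull) < 3L)                       # collinear input: segment hull
    return(pts[c(1L, n), , drop = FALSE])
  pts[hull, , drop = FALSE]
}

#' Feret (maximum caliper) diameter and angle of a hull
#'
#' Longest distance between any two hull vertices, found by rotating
#' calipers over antipodal vertex pairs (exhaustive pairwise search for tiny
#' hulls). The angle of the realizing segment is reported in degrees in
#' `[0, 180)`, counterclockwise from the positive horizontal axis in the
#' mathematical (y up) frame.
#'
#' @param hull Counterclockwise convex polygon from [convex_hull()],
#'   coordinates in the caller's length unit.
#' @return List with `diameter`, `angle` (degrees), and `degenerate`
#'   (`TRUE` for single-vertex input, where diameter 0 / angle 0 are
#'   reported by convention).
#' @export
feret <- function(hull) {
  if (is.null(dim(hull))) hull <- matrix(hull, ncol = 2L)
  h <- nrow(hull)
  if (h < 1L) stop("empty hull")
  if (h == 1L)
    return(list(diameter = 0, angle = 0, degenerate = TRUE))
  best <- c(0, 1L, 2L)
  if (h <= 4L) {
    for (i in seq_len(h - 1L)) for (j in (i + 1L):h) {
      d2 <- sum((hull[i, ] - hull[j, ])^2)
      if (d2 > best[1L]) best <- c(d2, i, j)
    }
  } else {
    area2 <- function(a, b, cc)
      abs((hull[b, 1L] - hull[a, 1L]) * (hull[cc, 2L] - hull[a, 2L]) -
          (hull[b, 2L] - hull[a, 2L]) * (hull[cc, 1L] - hull[a, 1L]))
    nxt <- function(i) if (i == h) 1L else i + 1L
    j <- 2L
    for (i in seq_len(h)) {
      i2 <- nxt(i)
      while (area2(i, i2, nxt(j)) > area2(i, i2, j)) j <- nxt(j)
      for (cand in c(j, nxt(j))) {
        for (a in c(i, i2)) {
          d2 <- sum((hull[a, ] - hull[cand, ])^2)
          if (d2 > best[1L]) best <- c(d2, a, cand)
        }
      }
    }
  }
  p <- hull[best[2L], ]; q <- hull[best[3L], ]
  ang <- atan2(q[2L] - p[2L], q[1L] - p[1L]) * 180 / pi
  ang <- ang %% 180
  list(diameter = sqrt(best[1L]), angle = ang, degenerate = FALSE)
}

#' Moment-based fitted ellipse of a component
#'
#' Ellipse with the component's second-order central moments (pixel extent
#' included via the 1/12 square-pixel term) and orientation from the
#' principal axes, rescaled so the ellipse area equals the component's pixel
#' area (area-preserving convention). Major axis >= minor axis always.
#'
#' @param labeled Result of [label_components()].
#' @param label Component label.
#' @param pixel_size Micrometers per pixel.
#' @return List with `major`, `minor` (full axis lengths, micrometers) and
#'   `orientation` (degrees in `[0, 180)`, y-up frame).
#' @export
fit_ellipse <- function(labeled, label, pixel_size = 1) {
  labels <- labeled$labels
  nr <- nrow(labels)
  idx <- which(labels == label)
  if (!length(idx)) stop("label ", label, " not present in mask")
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  x <- c - 0.5
  y <- (nr - r) + 0.5
  mxx <- mean((x - mean(x))^2) + 1 / 12
  myy <- mean((y - mean(y))^2) + 1 / 12
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  tr <- mxx + myy
  det2 <- sqrt(max(0, (mxx - myy)^2 / 4 + mxy^2))
  l1 <- tr / 2 + det2
  l2 <- max(tr / 2 - det2, 1e-12)
  a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)     # covariance-convention semi-axes
  scale <- sqrt(length(idx) / (pi * a0 * b0)) # area-preserving rescale
  ang <- if (abs(mxy) < 1e-12 && abs(mxx - myy) < 1e-12) 0
         else (atan2(2 * mxy, mxx - myy) / 2) * 180 / pi
  list(major = 2 * a0 * scale * pixel_size,
       minor = 2 * b0 * scale * pixel_size,
       orientation = ang %% 180)
}

# Moore-neighbor boundary chain on pixel centers, reduced to the minimal
# 8-chain (staircase pairs collapsed to diagonals); returns counts of
# orthogonal steps, diagonal steps and corners (direction changes).
# Single-pixel components have no steps.
boundary_chain_steps <- function(labels, label) {
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels == label)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  if (length(idx) == 1L) return(c(orth = 0L, diag = 0L, corner = 0L))
  start_i <- order(r, c)[1L]                  # topmost-leftmost pixel
  sr <- r[start_i]; sc <- c[start_i]
  is_lab <- function(rr, cc)
    rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
      labels[rr, cc] == label
  # clockwise Moore neighborhood starting from W
  dr8 <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc8 <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  path_r <- sr; path_c <- sc
  cr <- sr; cc2 <- sc
  scan_from <- 1L                             # start scanning at W
  repeat {
    found <- FALSE
    for (s in seq_len(8L)) {
      k <- ((scan_from - 1L + s - 1L) %% 8L) + 1L
      rr <- cr + dr8[k]; ccn <- cc2 + dc8[k]
      if (is_lab(rr, ccn)) {
        # radial-sweep rule: resume scan two positions counterclockwise
        # of the direction just travelled
        scan_from <- ((k - 1L + 6L) %% 8L) + 1L
        cr <- rr; cc2 <- ccn
        path_r <- c(path_r, cr); path_c <- c(path_c, ccn)
        found <- TRUE
        break
      }
    }
    if (!found) break                         # isolated pixel run
    if (cr == sr && cc2 == sc) break          # closed the loop
    if (length(path_r) > 8L * length(idx)) break  # safety stop
  }
  m <- length(path_r) - 1L                    # closed: last == first
  if (m < 1L) return(c(orth = 0L, diag = 0L, corner = 0L))
  # reduce to the minimal chain: drop a contour pixel whenever its two
  # neighbors along the contour are themselves 8-adjacent (staircase
  # corner pixels become diagonal steps)
  keep_r <- path_r[1L]; keep_c <- path_c[1L]
  i <- 2L
  while (i <= m) {
    nxt_r <- path_r[i + 1L]; nxt_c <- path_c[i + 1L]
    last_r <- keep_r[length(keep_r)]; last_c <- keep_c[length(keep_c)]
    if (abs(nxt_r - last_r) <= 1L && abs(nxt_c - last_c) <= 1L &&
        !(nxt_r == last_r && nxt_c == last_c)) {
      # staircase: drop pixel i, step diagonally to its successor
      keep_r <- c(keep_r, nxt_r); keep_c <- c(keep_c, nxt_c)
      i <- i + 2L
    } else {
      keep_r <- c(keep_r, path_r[i]); keep_c <- c(keep_c, path_c[i])
      i <- i + 1L
    }
  }
  dr <- diff(c(keep_r, keep_r[1L]))
  dc <- diff(c(keep_c, keep_c[1L]))
  step <- dr != 0L | dc != 0L
  dr <- dr[step]; dc <- dc[step]
  dg <- sum(dr != 0L & dc != 0L)
  orth <- sum(xor(dr != 0L, dc != 0L))
  dirs <- atan2(dr, dc)
  corner <- sum(dirs != c(dirs[-1L], dirs[1L]))
  c(orth = orth, diag = dg, corner = corner)
}

#' Measure one crack
#'
#' All six morphological descriptors of a labeled component:
#' area (pixel count times pixel area), perimeter (minimal 8-connected
#' boundary chain with Vossepoel-Smeulders weights: 0.980 per orthogonal
#' step, 1.406 per diagonal, -0.091 per corner, plus a half-pixel outset
#' term of pi times the pixel size),
#' Feret diameter and angle (maximum caliper over the convex hull of the
#' boundary polygon), aspect ratio (moment-fitted ellipse), circularity
#' (`4 pi area / perimeter^2`, clipped to 1), and solidity (area over
#' convex-hull area).
#'
#' @param labeled Result of [label_components()].
#' @param label Component label.
#' @param pixel_size Micrometers per pixel.
#' @param connectivity Connectivity used for labeling (default 8).
#' @return One-row data.frame (`crack_record`): `label`, `n_pixels`, `area`
#'   (um^2), `perimeter` (um), `feret_diameter` (um), `feret_angle`
#'   (degrees), `aspect_ratio`, `circularity`, `solidity`, `major`, `minor`,
#'   `orientation`, `touches_border`, `degenerate`.
#' @export
measure_crack <- function(labeled, label, pixel_size = 1,
                          connectivity = 8L) {
  labels <- labeled$labels
  nr <- nrow(labels); nc <- ncol(labels)
  idx <- which(labels == label)
  if (!length(idx)) stop("label ", label, " not present in mask")
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  npix <- length(idx)
  area <- npix * pixel_size^2
  steps <- boundary_chain_steps(labels, label)
  perimeter <- (0.980 * steps[["orth"]] + 1.406 * steps[["diag"]] -
                  0.091 * steps[["corner"]] + pi) * pixel_size
  poly <- trace_boundary(labeled, label, connectivity)
  hull <- convex_hull(poly)
  hull_area <- if (nrow(hull) >= 3L) polygon_signed_area(hull) else 0
  fer <- feret(hull * pixel_size)
  ell <- fit_ellipse(labeled, label, pixel_size)
  data.frame(
    label = label,
    n_pixels = npix,
    area = area,
    perimeter = perimeter,
    feret_diameter = fer$diameter,
    feret_angle = fer$angle,
    aspect_ratio = ell$major / ell$minor,
    circularity = min(1, 4 * pi * area / perimeter^2),
    solidity = if (hull_area > 0) min(1, npix / hull_area) else 1,
    major = ell$major,
    minor = ell$minor,
    orientation = ell$orientation,
    touches_border = any(r == 1L | r == nr | c == 1L | c == nc),
    degenerate = fer$degenerate
  )
}

#' Measure every crack in a mask
#'
#' Labels the mask and applies [measure_crack()] to each component.
#'
#' @param mask A [binary_mask()].
#' @param connectivity 4 or 8 (default 8).
#' @return Data.frame of `crack_record` rows (zero rows for an empty mask).
#' @export
measure_all_cracks <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (lab$n == 0L)
    return(data.frame(label = integer(0), n_pixels = integer(0),
                      area = numeric(0), perimeter = numeric(0),
                      feret_diameter = numeric(0), feret_angle = numeric(0),
                      aspect_ratio = numeric(0), circularity = numeric(0),
                      solidity = numeric(0), major = numeric(0),
                      minor = numeric(0), orientation = numeric(0),
                      touches_border = logical(0), degenerate = logical(0)))
  do.call(rbind, lapply(seq_len(lab$n), measure_crack, labeled = lab,
                        pixel_size = mask$pixel_size,
                        connectivity = connectivity))
}

#' Summarize crack descriptors
#'
#' Mean, SD, median and quartiles per descriptor, plus optional histogram
#' bin counts.
#'
#' @param records Data.frame of crack records from [measure_all_cracks()].
#' @param descriptors Character vector of columns to summarize.
#' @param breaks Optional named list of histogram bin edges per descriptor.
#' @return List with `summary` (data.frame: descriptor, n, mean, sd, median,
#'   q1, q3) and `histograms` (named list of `counts`/`breaks`, only for
#'   descriptors with supplied breaks).
#' @export
summarize_cracks <- function(records,
                             descriptors = c("feret_diameter",
                                             "feret_angle", "area",
                                             "aspect_ratio", "circularity",
                                             "solidity"),
                             breaks = list()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("no crack records to summarize")
  missing <- setdiff(descriptors, names(records))
  if (length(missing))
    stop("unknown descriptor(s): ", paste(missing, collapse = ", "))
  rows <- lapply(descriptors, function(d) {
    v <- records[[d]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(descriptor = d, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               median = q[2L], q1 = q[1L], q3 = q[3L])
  })
  hists <- list()
  for (d in intersect(names(breaks), descriptors)) {
    h <- graphics::hist(records[[d]], breaks = breaks[[d]], plot = FALSE)
    hists[[d]] <- list(counts = h$counts, breaks = h$breaks)
  }
  list(summary = do.call(rbind, rows), histograms = hists)
}
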