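# Rasterized analytic shapes used across the morphometry tests.

raster_disk <- function(r_px, pixel_size = 1, pad = 3) {
  n <- 2 * (r_px + pad) + 1
  cen <- r_px + pad + 0.5
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) ((i - cen)^2 + (j - cen)^2) <= r_px^2)
  binary_mask(m, pixel_size)
}

raster_rect <- function(h_px, w_px, pixel_size = 1, pad = 3) {
  m <- matrix(0L, h_px + 2 * pad, w_px + 2 * pad)
  m[pad + seq_len(h_px), pad + seq_len(w_px)] <- 1L
  binary_mask(m, pixel_size)
}

raster_ellipse <- function(a_px, b_px, angle_deg = 0, pixel_size = 1,
                           pad = 4) {
  n <- 2 * (a_px + pad) + 1
  cen <- a_px + pad + 0.5
  th <- angle_deg * pi / 180
  m <- outer(seq_len(n), seq_len(n), function(i, j) {
    x <- j - cen; y <- cen - i
    u <- (x * cos(th) + y * sin(th)) / a_px
    v <- (-x * sin(th) + y * cos(th)) / b_px
    u^2 + v^2 <= 1
  })
  binary_mask(m, pixel_size)
}

measure_first <- function(mask) {
  measure_crack(label_components(mask), 1L, mask$pixel_size)
}

# Independent two-sided exact signed-rank p-value by full 2^n enumeration
# of sign assignments over the observed midranks.
wilcoxon_enumeration_p <- function(ranks, w_plus) {
  n <- length(ranks)
  sums <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code)[seq_len(n)])
    sums[code + 1] <- sum(ranks[bits == 1L])
  }
  total <- sum(ranks)
  if (abs(w_plus - total / 2) < 1e-9) return(1)
  lo <- mean(sums <= w_plus + 1e-9)
  hi <- mean(sums >= w_plus - 1e-9)
  min(1, 2 * min(lo, hi))
}
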