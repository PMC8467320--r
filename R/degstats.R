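#' D'Agostino omnibus normality test
#'
#' The K-squared omnibus statistic: the sum of squared z-transformed sample
#' skewness (Johnson SU transformation) and z-transformed sample kurtosis
#' (Anscombe-Glynn transformation), referred to a chi-squared distribution
#' with 2 degrees of freedom. Sensitive to both asymmetry and tail weight.
#'
#' @param x Numeric sample, n >= 8, non-constant.
#' @return List with `K2`, `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino omnibus test needs n >= 8 (got ", n,
         "); use a small-sample normality test instead")
  if (stats::var(x) == 0) stop("sample has zero variance")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  ya <- y / alpha
  z1 <- delta * log(ya + sqrt(ya^2 + 1))

  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- z1^2 + z2^2
  list(K2 = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Conditional descriptive summary of a sample
#'
#' Computes both summary pairs (mean +/- SD and median with quartiles) and
#' selects the display form by the D'Agostino normality verdict: samples
#' that pass (p >= `alpha_normality`) are displayed as mean +/- SD, the
#' others as median (Q1, Q3). Quartiles use linear interpolation (type 7).
#'
#' @param x Numeric sample, n >= 8.
#' @param alpha_normality Normality screening level. Default 0.05.
#' @return A `group_summary` list: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `normality_p`, `normal`, `display`.
#' @export
summarize_sample <- function(x, alpha_normality = 0.05) {
  test <- dagostino_k2(x)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  normal <- test$p_value >= alpha_normality
  structure(list(n = length(x), mean = mean(x), sd = stats::sd(x),
                 median = q[2L], q1 = q[1L], q3 = q[3L],
                 normality_p = test$p_value, normal = normal,
                 display = if (normal) "mean±SD" else "median (Q1, Q3)"),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  if (x$normal) {
    cat(sprintf("%s: %.*f ± %.*f (n = %d)\n", x$display, digits, x$mean,
                digits, x$sd, x$n))
  } else {
    cat(sprintf("%s: %.*f (%.*f, %.*f) (n = %d)\n", x$display, digits,
                x$median, digits, x$q1, digits, x$q3, x$n))
  }
  invisible(x)
}

#' Format a group summary as a display cell
#'
#' @param s A `group_summary`.
#' @param digits Decimal places. Default 2.
#' @return Character scalar, `"m ± s"` or `"med (q1, q3)"` per the
#'   normality verdict.
#' @export
format_summary_cell <- function(s, digits = 2) {
  if (s$normal)
    sprintf("%.*f ± %.*f", digits, s$mean, digits, s$sd)
  else
    sprintf("%.*f (%.*f, %.*f)", digits, s$median, digits, s$q1,
            digits, s$q3)
}

# Exact null distribution of W+ for signed midranks: DP over doubled ranks
# (midranks are multiples of 1/2, so doubling makes them integers).
signed_rank_exact_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)                    # f[s + 1] = #subsets with sum s
  f[1L] <- 1
  for (rk in r2) {
    idx <- (total - rk):0
    f[idx + rk + 1L] <- f[idx + rk + 1L] + f[idx + 1L]
  }
  probs <- f / sum(f)
  w2 <- round(2 * w_plus)
  mean_w2 <- total / 2
  lo <- sum(probs[seq_len(w2 + 1L)])          # P(W+ <= w)
  hi <- sum(probs[(w2 + 1L):(total + 1L)])    # P(W+ >= w)
  if (abs(w2 - mean_w2) < 1e-9) return(1)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired two-sided test on `x - y`. Zero differences are dropped
#' (Wilcoxon's original rule; Pratt's method via `zero_method = "pratt"`
#' keeps them in the ranking and then discards their contribution).
#' Ties among the remaining absolute differences receive midranks. The
#' reported statistic `W` is the smaller of the positive- and negative-rank
#' sums. Exact p by enumeration of the signed-rank distribution for
#' `n <= exact_limit`; otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param mode `"auto"` (exact when n <= `exact_limit`), `"exact"`, or
#'   `"normal_approx"`.
#' @param exact_limit Largest n for exact enumeration. Default 20.
#' @param zero_method `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @return List with `W`, `W_plus`, `W_minus`, `p_value`, `n_used`,
#'   `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 mode = c("auto", "exact", "normal_approx"),
                                 exact_limit = 20L,
                                 zero_method = c("wilcoxon", "pratt")) {
  mode <- match.arg(mode)
  zero_method <- match.arg(zero_method)
  if (length(x) != length(y))
    stop("x and y must be paired vectors of equal length")
  d <- x - y
  if (all(d == 0)) stop("all paired differences are zero")
  if (zero_method == "wilcoxon") {
    d <- d[d != 0]
    ranks <- rank(abs(d))
  } else {
    ranks_all <- rank(abs(d))
    ranks <- ranks_all[d != 0]
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 6L)
    stop("need >= 6 non-zero paired differences (got ", n, ")")
  w_plus <- sum(ranks[d > 0])
  w_minus <- sum(ranks[d < 0])
  W <- min(w_plus, w_minus)
  use_exact <- switch(mode,
                      auto = n <= exact_limit,
                      exact = TRUE,
                      normal_approx = FALSE)
  if (use_exact) {
    if (n > 25L) stop("exact enumeration not supported for n > 25")
    p <- signed_rank_exact_p(ranks, w_plus)
    method <- "exact"
  } else {
    mu <- sum(ranks) / 2
    sigma2 <- sum(ranks^2) / 4  # midranks make the tie correction implicit
    z_num <- w_plus - mu
    z <- (z_num - sign(z_num) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  list(W = W, W_plus = w_plus, W_minus = w_minus, p_value = p,
       n_used = n, method = method)
}

#' Bonferroni per-comparison significance level
#'
#' @param alpha_family Familywise error rate, in (0, 1). Default 0.05.
#' @param m Number of comparisons (>= 1).
#' @return `alpha_family / m`.
#' @export
bonferroni <- function(alpha_family = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  if (alpha_family <= 0 || alpha_family >= 1)
    stop("alpha_family must lie in (0, 1)")
  alpha_family / m
}

#' Compare a metric across consecutive degradation periods
#'
#' Paired Wilcoxon signed-rank tests between each pair of consecutive
#' periods (periods sorted by week; `m = length(periods) - 1` comparisons),
#' with the per-test level set by the Bonferroni rule. Pairing is by grid
#' index (position i of one period against position i of the next); the
#' unpaired rank-sum alternative is available via `paired = FALSE`.
#'
#' @param metrics Named list: names are weeks (coercible to numeric), values
#'   numeric vectors of per-spot metrics. Equal lengths required when
#'   `paired = TRUE`.
#' @param alpha_family Familywise error rate. Default 0.05.
#' @param paired Pair by grid index (default `TRUE`).
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return Data.frame, one row per consecutive pair: `period_a`, `period_b`,
#'   `W`, `p_value`, `alpha_per_test`, `significant`, `direction` (sign of
#'   the median difference `b - a`).
#' @export
compare_series <- function(metrics, alpha_family = 0.05, paired = TRUE, ...) {
  weeks <- suppressWarnings(as.numeric(names(metrics)))
  if (any(is.na(weeks)))
    stop("metrics must be a named list with numeric week names")
  ord <- order(weeks)
  metrics <- metrics[ord]; weeks <- weeks[ord]
  if (length(weeks) < 2L)
    stop("need at least two periods to compare")
  m <- length(weeks) - 1L
  alpha <- bonferroni(alpha_family, m)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    a <- metrics[[i]]; b <- metrics[[i + 1L]]
    if (paired) {
      if (length(a) != length(b))
        stop("paired comparison of periods ", weeks[i], " and ",
             weeks[i + 1L], " needs equal n (", length(a), " vs ",
             length(b), ")")
      tst <- tryCatch(wilcoxon_signed_rank(a, b, ...), error = function(e)
        stop("comparison ", weeks[i], " vs ", weeks[i + 1L], ": ",
             conditionMessage(e), call. = FALSE))
      W <- tst$W; p <- tst$p_value
    } else {
      tst <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
      W <- unname(tst$statistic); p <- tst$p.value
    }
    rows[[i]] <- data.frame(period_a = weeks[i], period_b = weeks[i + 1L],
                            W = W, p_value = p, alpha_per_test = alpha,
                            significant = p < alpha,
                            direction = sign(stats::median(b) -
                                               stats::median(a)))
  }
  do.call(rbind, rows)
}
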