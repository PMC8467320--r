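test_that("D'Agostino omnibus statistic matches frozen reference values", {
  # reference values computed with an independent implementation of the
  # same transformed-moment formulas (scipy.stats.normaltest)
  x <- sin(1:30) * 3 + (1:30) * 0.1
  r <- dagostino_k2(x)
  expect_equal(r$K2, 3.9179331013, tolerance = 1e-9)
  expect_equal(r$p_value, 0.1410040662, tolerance = 1e-9)

  y <- c((1:12)^2, 200)
  r2 <- dagostino_k2(y)
  expect_equal(r2$K2, 2.6656336559, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.2637333226, tolerance = 1e-9)
})

test_that("D'Agostino test rejects skewed data and guards degenerate input", {
  set.seed(12)
  logn <- exp(rnorm(64, sd = 1))
  expect_lt(dagostino_k2(logn)$p_value, 0.01)

  expect_error(dagostino_k2(rep(2, 20)), "variance")
  expect_error(dagostino_k2(1:5), "n >= 8")
})

test_that("sample summaries pick the display form from the normality verdict", {
  s <- summarize_sample(1:9)
  expect_equal(s$median, 5)
  expect_equal(s$q1, 3)
  expect_equal(s$q3, 7)

  set.seed(30)
  near_normal <- rnorm(100)
  expect_equal(summarize_sample(near_normal)$display, "mean±SD")

  heavy <- exp(rnorm(100, sd = 1.2))
  sh <- summarize_sample(heavy)
  expect_equal(sh$display, "median (Q1, Q3)")
  expect_false(sh$normal)
  expect_match(format_summary_cell(sh), "\\(")
})

test_that("wilcoxon exact p equals full sign enumeration", {
  x <- c(12.1, 9.8, 13.4, 10.2, 8.7, 11.9, 10.8, 12.6, 9.1, 11.2)
  y <- c(10.3, 9.9, 11.1, 9.6, 9.2, 10.5, 10.1, 11.0, 9.4, 10.2)
  res <- wilcoxon_signed_rank(x, y, mode = "exact")
  d <- x - y
  ranks <- rank(abs(d[d != 0]))
  expect_equal(res$p_value,
               wilcoxon_enumeration_p(ranks, sum(ranks[d[d != 0] > 0])))

  # random fixtures incl. ties, n <= 12
  set.seed(17)
  for (k in 1:20) {
    n <- sample(6:12, 1)
    a <- round(rnorm(n, 10, 2), 1)
    b <- round(a + rnorm(n, 0.5, 1), 1)
    keep <- a != b
    if (sum(keep) < 6) next
    res <- wilcoxon_signed_rank(a, b, mode = "exact")
    d2 <- (a - b)[keep]
    rk <- rank(abs(d2))
    expect_equal(res$p_value, wilcoxon_enumeration_p(rk, sum(rk[d2 > 0])),
                 tolerance = 1e-12)
  }
})

test_that("wilcoxon matches base R and its approximation tracks exact", {
  set.seed(5)
  a <- rnorm(15); b <- rnorm(15) + 0.5
  mine <- wilcoxon_signed_rank(a, b, mode = "exact")
  base <- wilcox.test(a, b, paired = TRUE, exact = TRUE)
  expect_equal(mine$p_value, base$p.value)
  expect_equal(mine$W_plus, unname(base$statistic))

  set.seed(23)
  for (k in 1:10) {
    a <- rnorm(20); b <- a + rnorm(20, 0.3, 0.8)
    pe <- wilcoxon_signed_rank(a, b, mode = "exact")$p_value
    pa <- wilcoxon_signed_rank(a, b, mode = "normal_approx")$p_value
    expect_lt(abs(pe - pa), 0.01)
  }

  expect_error(wilcoxon_signed_rank(1:8, 1:8), "zero")
  expect_error(wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6)),
               "6 non-zero")
})

test_that("wilcoxon has power against a 1 SD paired shift at n = 64", {
  set.seed(41)
  hits <- 0
  for (k in 1:40) {
    a <- rnorm(64)
    b <- a + rnorm(64) * 0.3 + 1
    p <- wilcoxon_signed_rank(a, b)$p_value
    hits <- hits + (p < 0.001)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("bonferroni arithmetic", {
  expect_identical(bonferroni(0.05, 4), 0.0125)
  expect_identical(bonferroni(0.05, 1), 0.05)
  expect_identical(bonferroni(0.01, 5), 0.002)
  expect_identical(bonferroni(0.05, 4) * 4, 0.05)
  expect_error(bonferroni(0.05, 0), "m")
  expect_error(bonferroni(1.2, 4), "alpha_family")
})

test_that("series comparison is consecutive, paired and order equivariant", {
  set.seed(8)
  base <- rnorm(64, sd = 0.2)
  metrics <- list(`0` = base + 9.8, `4` = base + 9.2 + rnorm(64, sd = 0.1),
                  `8` = base + 8.0 + rnorm(64, sd = 0.1),
                  `16` = base + 6.6 + rnorm(64, sd = 0.1),
                  `24` = base + 6.3 + rnorm(64, sd = 0.1))
  res <- compare_series(metrics)
  expect_equal(nrow(res), 4)
  expect_equal(unique(res$alpha_per_test), 0.0125)
  expect_equal(res$period_a, c(0, 4, 8, 16))
  expect_true(all(res$direction == -1))

  shuffled <- compare_series(metrics[c(3, 1, 5, 2, 4)])
  expect_equal(res, shuffled)

  same <- list(`0` = base, `4` = base)
  expect_error(compare_series(same), "zero")
  expect_error(compare_series(list(`0` = 1:10, `4` = 1:8)), "equal n")
})
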