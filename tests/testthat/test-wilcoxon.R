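test_that("uniform positive differences across 6 pairs give exact p = 2/64", {
  res <- wilcoxon_signed_rank(rep(0, 6), rep(1, 6))
  expect_equal(res$p_value, 2 / 2^6, tolerance = 1e-15)
  expect_equal(res$statistic[["W+"]], 21)
  expect_equal(res$statistic[["W_min"]], 0)
  expect_equal(res$method, "exact signed-rank distribution")
})

test_that("identical pre and post give the degenerate p = 1 result", {
  x <- c(1.2, 3.4, 5.6, 7.8)
  res <- wilcoxon_signed_rank(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_zero_dropped, 4)
})

test_that("exact p equals the full 2^n sign-enumeration oracle", {
  for (seed in 1:6) {
    set.seed(seed + 60)
    n <- sample(5:15, 1)
    d <- round(rnorm(n), if (seed %% 2) 3 else 0)  # even seeds force ties/zeros
    res <- wilcoxon_signed_rank(rep(0, n), d)
    if (res$degenerate) next
    expect_equal(res$p_value, oracle_signrank_p(d), tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("the approximate branch matches the reference implementation", {
  for (seed in 1:4) {
    set.seed(seed + 70)
    pre <- rnorm(40)
    post <- pre + rnorm(40, 0.2)
    got <- wilcoxon_signed_rank(pre, post)
    ref <- suppressWarnings(
      stats::wilcox.test(post, pre, paired = TRUE, exact = FALSE,
                         correct = TRUE))
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(got$statistic[["W+"]], unname(ref$statistic))
  }
})

test_that("one-sided p-values match the reference implementation in both branches", {
  for (seed in 1:3) {
    set.seed(seed + 75)
    n <- c(12, 20, 40)[seed]
    pre <- rnorm(n); post <- pre + rnorm(n, -0.3)
    for (alt in c("greater", "less")) {
      got <- wilcoxon_signed_rank(pre, post, alternative = alt)
      ref <- suppressWarnings(
        stats::wilcox.test(post, pre, paired = TRUE, alternative = alt,
                           exact = n <= 25, correct = TRUE))
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10,
                   info = paste(alt, n))
    }
  }
  # a clearly decreasing metric prints p near 1 when testing for an increase
  set.seed(79)
  pre <- rnorm(40); post <- pre - 0.5 + rnorm(40, 0, 0.3)
  expect_gt(wilcoxon_signed_rank(pre, post, alternative = "greater")$p_value,
            0.95)
})

test_that("approximate p stays within 0.01 of exact at the crossover size", {
  for (seed in 1:5) {
    set.seed(seed + 80)
    d <- rnorm(25, 0.3)
    exact <- wilcoxon_signed_rank(rep(0, 25), d, exact_limit = 25)$p_value
    approx <- wilcoxon_signed_rank(rep(0, 25), d, exact_limit = 10)$p_value
    expect_lt(abs(exact - approx), 0.01)
  }
})

test_that("median and IQR of differences bracket correctly", {
  set.seed(91)
  pre <- rnorm(30); post <- pre + rnorm(30)
  res <- wilcoxon_signed_rank(pre, post)
  d <- post - pre
  expect_equal(res$median_diff, median(d))
  expect_equal(res$iqr_diff, unname(quantile(d, c(0.25, 0.75))))
  expect_true(res$iqr_diff[1] <= res$median_diff &&
              res$median_diff <= res$iqr_diff[2])
})
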