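test_that("bin_profile covers the data range with conserved counts", {
  # all data in one bin: its mean is the overall mean
  one <- tibble::tibble(dte = c(0.1, 0.2, 0.3), gc = c(10, 20, 60))
  b1 <- bin_profile(one, dte, gc)
  expect_equal(nrow(b1), 1)
  expect_equal(b1$n, 3)
  expect_equal(b1$feature_mean, 30)
  expect_equal(c(b1$bin_lower, b1$bin_upper), c(0, 0.5))
  # conservation on a random fixture, empty bins retained
  set.seed(3)
  d <- tibble::tibble(dte = rnorm(500, sd = 2), gc = runif(500))
  b <- bin_profile(d, dte, gc)
  expect_equal(sum(b$n), 500)
  expect_equal(b$bin_lower[-1], b$bin_upper[-nrow(b)])
  # feature equal to delta: bin means increase with the midpoint
  d2 <- tibble::tibble(dte = seq(-3, 3, length.out = 200))
  d2$f <- d2$dte
  b2 <- bin_profile(d2, dte, f)
  occ <- b2[b2$n > 0, ]
  expect_true(all(diff(occ$feature_mean) > 0))
  expect_error(bin_profile(d, dte, gc, window = 0),
               class = "polysomics_config_error")
})

test_that("pearson_test matches the product-moment oracle and cor.test", {
  expect_equal(pearson_test(1:10, 2 * (1:10))$estimate, 1)
  r_neg <- pearson_test(1:10, -(1:10))
  expect_equal(r_neg$estimate, -1)
  expect_lt(r_neg$p.value, 1e-15)
  # hand computation: x=(1,2,3), y=(1,2,4)
  res <- pearson_test(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$estimate, 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(round(res$estimate, 4), 0.982)
  # random fixtures against a brute-force covariance/variance oracle and
  # against R's cor.test
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(50)
    y <- 0.3 * x + rnorm(50)
    res <- pearson_test(x, y)
    r_oracle <- mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
    expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
    ct <- stats::cor.test(x, y)
    expect_equal(res$estimate, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p.value, ct$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_test(c(1, 1, 1), c(1, 2, 3)), "constant",
               class = "polysomics_input_error")
  expect_error(pearson_test(1:2, 1:2), class = "polysomics_input_error")
})

test_that("pearson_test holds its nominal type-I error", {
  set.seed(42)
  p <- replicate(2000, pearson_test(rnorm(200), rnorm(200))$p.value)
  expect_gte(mean(p < 0.05), 0.035)
  expect_lte(mean(p < 0.05), 0.065)
})

test_that("mann_whitney: exact small-sample branch and tie-corrected approximation", {
  res <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")
  # identical samples: all ties, approximate branch, p = 1
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1)
  # agrees with wilcox.test on tie-free data
  set.seed(5)
  for (i in 1:5) {
    a <- runif(6)
    b <- runif(7) + 0.2
    res <- mann_whitney(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
    expect_equal(res$statistic, unname(wt$statistic))
    expect_equal(res$p.value, wt$p.value, tolerance = 1e-12)
  }
  # exact and approximate branches agree within 0.02 at 8 vs 8
  set.seed(6)
  for (i in 1:10) {
    a <- runif(8)
    b <- runif(8)
    exact_p <- mann_whitney(a, b)$p.value
    # approximate p computed by the large-sample branch on the same data
    wt_approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    )$p.value
    expect_lt(abs(exact_p - wt_approx), 0.02)
  }
  expect_error(mann_whitney(numeric(0), 1:3), class = "polysomics_input_error")
})

test_that("mann_whitney exact branch matches full enumeration for sizes <= 8", {
  set.seed(7)
  for (n_a in c(1, 2, 3, 5, 8)) {
    for (n_b in c(2, 4, 8)) {
      a <- runif(n_a)
      b <- runif(n_b)
      expect_equal(mann_whitney(a, b)$p.value, mw_enum_p(a, b),
                   tolerance = 1e-12,
                   info = sprintf("n_a=%d n_b=%d", n_a, n_b))
    }
  }
})

test_that("subset shift summaries isolate an engineered subset", {
  d <- tibble::tibble(
    dte = c(rep(-1, 13), rep(0, 87)),
    mito = c(rep(TRUE, 13), rep(FALSE, 87))
  )
  s <- subset_shift_summary(d, dte, mito)
  sub <- s$summary[s$summary$group == "subset", ]
  expect_equal(sub$fraction_negative, 1)
  expect_equal(sub$median, -1)
  expect_equal(sub$n, 13L)
  expect_lt(s$test$p.value, 1e-3)
  # identical distributions: zero median difference
  d2 <- tibble::tibble(x = rep(c(1, 2, 3), 2),
                       m = rep(c(TRUE, FALSE), each = 3))
  s2 <- subset_shift_summary(d2, x, m)
  expect_equal(diff(s2$summary$median), 0)
  # medians match a direct sort-based oracle
  set.seed(8)
  d3 <- tibble::tibble(x = rnorm(101), m = runif(101) < 0.3)
  s3 <- subset_shift_summary(d3, x, m)
  med_oracle <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else mean(v[n / 2 + 0:1])
  }
  expect_equal(s3$summary$median[s3$summary$group == "subset"],
               med_oracle(d3$x[d3$m]))
  expect_equal(s3$summary$median[s3$summary$group == "rest"],
               med_oracle(d3$x[!d3$m]))
  d3$all_true <- TRUE
  expect_error(subset_shift_summary(d3, x, all_true),
               class = "polysomics_input_error")
  d3$all_false <- FALSE
  expect_error(subset_shift_summary(d3, x, all_false),
               class = "polysomics_input_error")
})

test_that("enrichment_2x2 reproduces hypergeometric tails and Fisher's rule", {
  res <- enrichment_2x2(k = 4, K = 5, n = 4, N = 10)
  expect_equal(res$p_upper, 5 / 210, tolerance = 1e-12)
  # two-sided p agrees with fisher.test across random tables
  set.seed(9)
  for (i in 1:10) {
    N <- sample(10:40, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(max(0, n - (N - K)):min(K, n), 1)
    res <- enrichment_2x2(k, K, n, N)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    ft <- stats::fisher.test(tab)
    expect_equal(res$p_fisher, ft$p.value, tolerance = 1e-9)
    expect_equal(res$p_upper,
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
  # upper-tail p is monotone non-increasing in k at fixed margins
  ks <- 0:5
  ps <- vapply(ks, function(k) enrichment_2x2(k, 5, 5, 12)$p_upper, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(enrichment_2x2(6, 5, 6, 10), class = "polysomics_input_error")
})
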