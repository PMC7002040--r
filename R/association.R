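#' Binned feature profile along the change-in-TE axis
#'
#' Bins observations by `delta` into contiguous windows of width `window`
#' whose edges are multiples of `window` covering the data range (a value `x`
#' falls in the bin `[k*window, (k+1)*window)` with `k = floor(x/window)`),
#' and summarises a feature per bin. Empty interior bins are retained with
#' `n = 0`.
#'
#' @param data Tibble holding the two variables.
#' @param delta,feature Unquoted column names: the binning variable (log2
#'   change in TE) and the feature to summarise (e.g. 5'UTR GC).
#' @param window Bin width (> 0, default 0.5).
#' @return Tibble with `bin_lower`, `bin_upper`, `bin_mid`, `n`,
#'   `feature_mean`, `feature_se`.
#' @examples
#' d <- tibble::tibble(dte = c(-0.6, -0.4, 0.2, 0.3), gc = c(70, 60, 50, 40))
#' bin_profile(d, dte, gc)
#' @export
bin_profile <- function(data, delta, feature, window = 0.5) {
  if (!is.numeric(window) || length(window) != 1L || !is.finite(window) ||
      window <= 0) {
    abort_config("`window` must be a single number > 0.")
  }
  x <- pull(data, {{ delta }})
  y <- pull(data, {{ feature }})
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) == 0) abort_input("No finite observations to bin.")
  k <- floor(x / window + 1e-9)
  k_range <- seq(min(k), max(k))
  per_bin <- map(k_range, function(kk) {
    yy <- y[k == kk]
    tibble(
      bin_lower = kk * window,
      bin_upper = (kk + 1) * window,
      bin_mid = (kk + 0.5) * window,
      n = length(yy),
      feature_mean = if (length(yy) > 0) mean(yy) else NA_real_,
      feature_se = if (length(yy) > 1) sd(yy) / sqrt(length(yy)) else NA_real_
    )
  })
  list_rbind(per_bin)
}

#' Pearson correlation with t-based significance
#'
#' Product-moment correlation `r`, its t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` and the two-sided p-value from the t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, neither constant.
#'   Pairs with missing values are dropped.
#' @return Object of class `pearson_cor`: a list with `estimate`, `n`,
#'   `statistic`, `p.value`. Has [tidy()] and [glance()] methods.
#' @examples
#' pearson_test(1:10, (1:10) + rnorm(10))
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) abort_input("`x` and `y` must have equal length.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort_input("Need at least 3 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort_input("Correlation undefined: a vector is constant.")
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  t_stat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  structure(
    list(estimate = r, n = n, statistic = t_stat, p.value = p,
         method = "Pearson product-moment correlation (t test)"),
    class = "pearson_cor"
  )
}

#' @export
print.pearson_cor <- function(x, ...) {
  p_txt <- if (x$p.value < 2.2e-16) "< 2.2e-16" else format(x$p.value, digits = 4)
  cat(sprintf("Pearson r = %.4f (n = %d, t = %.3f, two-sided p %s)\n",
              x$estimate, x$n, x$statistic,
              if (startsWith(p_txt, "<")) p_txt else paste("=", p_txt)))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. With no ties and `min(n_a, n_b) <= 8` the exact
#' null distribution of U is used; otherwise a normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return Object of class `mann_whitney`: list with `statistic` (U for
#'   sample `a`), `p.value`, `n_a`, `n_b`, `method` ("exact" or
#'   "normal approximation"). Has a [tidy()] method.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) {
    abort_input("Both groups must be nonempty.")
  }
  n_a <- length(a)
  n_b <- length(b)
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(c(a, b))
  has_ties <- any(ties > 1)

  if (!has_ties && min(n_a, n_b) <= 8) {
    p <- if (u > n_a * n_b / 2) {
      pwilcox(u - 1, n_a, n_b, lower.tail = FALSE)
    } else {
      pwilcox(u, n_a, n_b)
    }
    p <- min(2 * p, 1)
    method <- "exact"
  } else {
    n <- n_a + n_b
    mu <- n_a * n_b / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * pnorm(-abs(z)), 1)
    }
    method <- "normal approximation"
  }
  structure(
    list(statistic = u, p.value = p, n_a = n_a, n_b = n_b, method = method),
    class = "mann_whitney"
  )
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d, %s), two-sided p = %.4g\n",
              x$statistic, x$n_a, x$n_b, x$method, x$p.value))
  invisible(x)
}

#' Distribution summary of a subset versus the rest
#'
#' Summarises the change-in-TE distribution of a transcript subset (for
#' example the mitochondrially encoded transcripts) against its complement:
#' n, median, quartiles and the fraction of negative values per group, plus a
#' Mann-Whitney test of subset versus rest.
#'
#' @param data Tibble holding the variables.
#' @param delta Unquoted column: log2 change in TE.
#' @param subset Unquoted logical column marking the subset.
#' @return Object of class `subset_shift`: list with `summary` (tibble, one
#'   row per group) and `test` (a [mann_whitney()] result). Has [tidy()] and
#'   [glance()] methods.
#' @export
subset_shift_summary <- function(data, delta, subset) {
  x <- pull(data, {{ delta }})
  m <- pull(data, {{ subset }})
  if (length(m) != length(x)) abort_input("Mask length must match `delta`.")
  if (!is.logical(m)) abort_input("`subset` must be a logical column.")
  ok <- is.finite(x) & !is.na(m)
  x <- x[ok]
  m <- m[ok]
  if (!any(m)) abort_input("Subset is empty.")
  if (all(m)) abort_input("Subset complement is empty.")
  summarise_group <- function(values, label) {
    q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(group = label, n = length(values), median = q[2],
           q1 = q[1], q3 = q[3], fraction_negative = mean(values < 0))
  }
  structure(
    list(
      summary = bind_rows(summarise_group(x[m], "subset"),
                          summarise_group(x[!m], "rest")),
      test = mann_whitney(x[m], x[!m])
    ),
    class = "subset_shift"
  )
}

#' @export
print.subset_shift <- function(x, ...) {
  print(x$summary)
  print(x$test)
  invisible(x)
}

#' 2x2 enrichment test (hypergeometric / Fisher)
#'
#' For `k` marked items among `n` drawn from a population of `N` containing
#' `K` marked items: the one-sided upper-tail hypergeometric p-value
#' `P(X >= k)` and the two-sided Fisher p-value obtained by summing the
#' probabilities of all tables at the same margins that are no more likely
#' than the observed one. The odds ratio is the sample (cross-product) ratio.
#'
#' @param k Observed marked items in the draw.
#' @param K Marked items in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return Object of class `enrichment_test`: list with `odds_ratio`,
#'   `p_upper` (one-sided), `p_fisher` (two-sided) and the margins. Has a
#'   [tidy()] method.
#' @examples
#' enrichment_2x2(k = 4, K = 5, n = 4, N = 10)
#' @export
enrichment_2x2 <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != round(vals))) {
    abort_input("All margins must be nonnegative integers.")
  }
  if (K > N || n > N || k > min(K, n) || k < max(0, n - (N - K))) {
    abort_input("Inconsistent 2x2 margins.")
  }
  p_upper <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  support <- max(0, n - (N - K)):min(K, n)
  probs <- dhyper(support, K, N - K, n)
  p_obs <- dhyper(k, K, N - K, n)
  p_fisher <- min(sum(probs[probs <= p_obs * (1 + 1e-7)]), 1)
  or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
  structure(
    list(odds_ratio = or, p_upper = p_upper, p_fisher = p_fisher,
         k = k, K = K, n = n, N = N),
    class = "enrichment_test"
  )
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat(sprintf(
    "2x2 enrichment: k=%d of n=%d drawn (K=%d of N=%d marked)\n  OR = %.4g, one-sided p = %.4g, two-sided Fisher p = %.4g\n",
    x$k, x$n, x$K, x$N, x$odds_ratio, x$p_upper, x$p_fisher
  ))
  invisible(x)
}
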