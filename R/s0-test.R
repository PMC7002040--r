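#' s0-moderated t-test with permutation-based FDR
#'
#' SAM/Perseus-style differential test for two groups. For each protein the
#' moderated statistic is `d = (mean2 - mean1) / (se + s0)`, where `se` is
#' the Welch (default) or pooled-variance standard error and the additive
#' constant `s0` encodes the relative importance of the absolute difference
#' between the means: with `s0 = 0`, `d` is exactly the textbook t statistic,
#' while larger `s0` damps the significance of small fold changes.
#'
#' The null distribution comes from group-label permutations. Distinct
#' labelings are enumerated up to the group-swap symmetry (which leaves `|d|`
#' unchanged) and the observed labeling is excluded; if more than `n_perm`
#' remain, `n_perm` are sampled without replacement. For a symmetric
#' threshold `t`, `FDR(t) = mean over permutations of #\{|d*| >= t\} /
#' #\{|d| >= t\}`, capped at 1 (`pi0` fixed at 1, the conservative Perseus
#' convention). Each protein's q-value is the minimum `FDR(t)` over
#' thresholds `t <= |d_i|`, which makes q monotone non-increasing in `|d|`.
#'
#' @param data Log2 intensity tibble (`protein_id` + sample columns) with no
#'   missing values — impute first (see [impute_downshifted()]).
#' @param design Tibble `sample`, `group` (exactly two groups, each with >= 2
#'   replicates). The fold change is group 2 minus group 1 in the order the
#'   groups first appear in `design`.
#' @param s0 Additive denominator constant (>= 0; 0.1 and 0.2 are common
#'   choices).
#' @param n_perm Maximum number of label permutations (default 250).
#' @param fdr Significance threshold on q (default 0.05).
#' @param variance `"welch"` (default) or `"pooled"` standard error.
#' @param seed Optional seed used only when permutations must be sampled.
#' @return Tibble of class `s0_test_result` with columns `protein_id`,
#'   `mean_1`, `mean_2`, `log2_fc`, `se`, `d`, `q`, `significant`;
#'   attributes record `s0`, `n_perm_used`, `variance` and `fdr`. Has
#'   [glance()] and [autoplot()] methods.
#' @examples
#' sim <- simulate_proteomics(synth_config(seed = 1, n_proteins = 60))
#' mat <- log2_transform(sim$protein_groups[1:60, ], sim$design)
#' imp <- impute_downshifted(mat, seed = 1)
#' res <- s0_permutation_test(imp, sim$design, s0 = 0.1, seed = 1)
#' glance(res)
#' @export
s0_permutation_test <- function(data, design, s0 = 0.1, n_perm = 250L,
                                fdr = 0.05, variance = c("welch", "pooled"),
                                seed = NULL) {
  variance <- match.arg(variance)
  if (!is.numeric(s0) || length(s0) != 1L || !is.finite(s0) || s0 < 0) {
    abort_config("`s0` must be a single number >= 0.")
  }
  assert_scalar_number(n_perm, "n_perm", positive = TRUE)
  assert_scalar_number(fdr, "fdr", positive = TRUE)
  validate_design(design, data)
  groups <- unique(design$group)
  if (length(groups) != 2L) abort_input("`design` must define exactly 2 groups.")
  idx1 <- which(names(data) %in% design$sample[design$group == groups[1]])
  idx2 <- which(names(data) %in% design$sample[design$group == groups[2]])
  if (length(idx1) < 2L || length(idx2) < 2L) {
    abort_input("Each group needs at least 2 replicates.")
  }
  mat <- as.matrix(data[setdiff(names(data), "protein_id")])
  col_group1 <- match(design$sample[design$group == groups[1]], colnames(mat))
  col_group2 <- match(design$sample[design$group == groups[2]], colnames(mat))
  if (anyNA(mat)) {
    abort_input("Intensity matrix contains missing values; impute first.")
  }

  d_obs <- moderated_d(mat, col_group1, col_group2, s0, variance)
  labelings <- permutation_labelings(ncol(mat), length(col_group1),
                                     sort(col_group1), n_perm, seed)
  d_null <- map(labelings, function(g1) {
    g2 <- setdiff(seq_len(ncol(mat)), g1)
    abs(moderated_d(mat, g1, g2, s0, variance)$d)
  })
  d_null_all <- sort(unlist(d_null))
  n_perm_used <- length(labelings)

  abs_d <- abs(d_obs$d)
  ord <- order(abs_d)  # ascending thresholds
  thresholds <- abs_d[ord]
  n_prot <- length(abs_d)
  # #{|d| >= t} and mean-per-permutation #{|d*| >= t} at each threshold
  r_count <- n_prot - findInterval(thresholds - 1e-12, sort(abs_d))
  v_count <- (length(d_null_all) -
                findInterval(thresholds - 1e-12, d_null_all)) / n_perm_used
  fdr_at <- pmin(v_count / pmax(r_count, 1), 1)
  q_sorted <- cummin_forward(fdr_at)
  q <- numeric(n_prot)
  q[ord] <- q_sorted

  out <- tibble(
    protein_id = data$protein_id,
    mean_1 = d_obs$m1,
    mean_2 = d_obs$m2,
    log2_fc = d_obs$m2 - d_obs$m1,
    se = d_obs$se,
    d = d_obs$d,
    q = q,
    significant = q < fdr
  )
  attr(out, "s0") <- s0
  attr(out, "n_perm_used") <- n_perm_used
  attr(out, "variance") <- variance
  attr(out, "fdr") <- fdr
  attr(out, "groups") <- groups
  class(out) <- c("s0_test_result", class(out))
  out
}

# running minimum over ascending thresholds: q at threshold k is the best
# (smallest) FDR among all thresholds t <= t_k
cummin_forward <- function(x) cummin(x)

#' Automatic s0 selection by coefficient-of-variation minimisation
#'
#' The canonical SAM recipe for the exchangeability constant: over a grid of
#' candidate `s0` values (quantiles of the per-protein standard errors), pick
#' the one that makes the spread of the moderated statistic `d = diff /
#' (se + s0)` most uniform across the standard-error range — concretely, the
#' candidate minimising the coefficient of variation of the per-bin median
#' absolute deviation of `d`, with proteins binned by `se` quantile. Small
#' `s0` lets low-variance proteins dominate the tails; the CV-minimising
#' choice stabilises `d` so that significance reflects both the fold change
#' and its precision.
#'
#' @inheritParams s0_permutation_test
#' @param n_bins Number of equal-count standard-error bins (default 10).
#' @param probs Candidate quantiles of the standard-error distribution.
#' @return The selected `s0` (scalar).
#' @export
s0_tusher <- function(data, design, variance = c("welch", "pooled"),
                      n_bins = 10L, probs = seq(0, 1, by = 0.05)) {
  variance <- match.arg(variance)
  validate_design(design, data)
  groups <- unique(design$group)
  if (length(groups) != 2L) abort_input("`design` must define exactly 2 groups.")
  mat <- as.matrix(data[setdiff(names(data), "protein_id")])
  if (anyNA(mat)) abort_input("Intensity matrix contains missing values; impute first.")
  g1 <- match(design$sample[design$group == groups[1]], colnames(mat))
  g2 <- match(design$sample[design$group == groups[2]], colnames(mat))
  st <- moderated_d(mat, g1, g2, s0 = 0, variance = variance)
  diff <- st$m2 - st$m1
  se <- st$se
  cand <- quantile(se, probs, names = FALSE)
  cand <- unique(cand[cand > 0])
  if (length(cand) == 0) abort_input("All standard errors are zero.")
  bin <- cut(rank(se, ties.method = "first"), n_bins, labels = FALSE)
  cv <- map_dbl(cand, function(s0) {
    d <- diff / (se + s0)
    v <- tapply(d, bin, stats::mad)
    sd(v) / mean(v)
  })
  cand[which.min(cv)]
}

moderated_d <- function(mat, g1, g2, s0, variance) {
  n1 <- length(g1)
  n2 <- length(g2)
  m1 <- rowMeans(mat[, g1, drop = FALSE])
  m2 <- rowMeans(mat[, g2, drop = FALSE])
  v1 <- rowSums((mat[, g1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((mat[, g2, drop = FALSE] - m2)^2) / (n2 - 1)
  se <- if (variance == "welch") {
    sqrt(v1 / n1 + v2 / n2)
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(m1 = m1, m2 = m2, se = se, d = (m2 - m1) / (se + s0))
}

# Distinct group labelings up to the swap symmetry: enumerate subsets of the
# column indices of group-1 size that contain column 1 (canonical half),
# drop the observed labeling, sample if more than n_perm remain.
permutation_labelings <- function(n_cols, n1, observed_g1, n_perm, seed) {
  all_subsets <- combn(n_cols, n1, simplify = FALSE)
  if (n1 * 2 == n_cols) {
    all_subsets <- all_subsets[map_lgl(all_subsets, function(s) 1 %in% s)]
  }
  all_subsets <- all_subsets[!map_lgl(all_subsets, function(s) {
    identical(sort(s), observed_g1) ||
      identical(sort(setdiff(seq_len(n_cols), s)), observed_g1)
  })]
  if (length(all_subsets) > n_perm) {
    picked <- with_optional_seed(seed, sample(length(all_subsets), n_perm))
    all_subsets <- all_subsets[picked]
  }
  all_subsets
}

#' @export
print.s0_test_result <- function(x, ...) {
  cat(sprintf(
    "s0-moderated permutation test (s0 = %g, %s SE, %d permutations)\n",
    attr(x, "s0"), attr(x, "variance"), attr(x, "n_perm_used")
  ))
  cat(sprintf("%d of %d proteins significant at q < %g\n",
              sum(x$significant), nrow(x), attr(x, "fdr")))
  NextMethod()
}
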