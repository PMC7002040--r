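# broom-style tidiers for the package's test objects

#' @method tidy pearson_cor
#' @export
tidy.pearson_cor <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic,
         p.value = x$p.value, n = x$n, method = x$method)
}

#' @method glance pearson_cor
#' @export
glance.pearson_cor <- function(x, ...) tidy(x)

#' @method tidy mann_whitney
#' @export
tidy.mann_whitney <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n_a = x$n_a, n_b = x$n_b, method = x$method)
}

#' @method tidy subset_shift
#' @export
tidy.subset_shift <- function(x, ...) x$summary

#' @method glance subset_shift
#' @export
glance.subset_shift <- function(x, ...) {
  tibble(statistic = x$test$statistic, p.value = x$test$p.value,
         n_subset = x$summary$n[x$summary$group == "subset"],
         n_rest = x$summary$n[x$summary$group == "rest"])
}

#' @method tidy enrichment_test
#' @export
tidy.enrichment_test <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_upper = x$p_upper,
         p_fisher = x$p_fisher, k = x$k, K = x$K, n = x$n, N = x$N)
}

#' @method tidy mendelian_test
#' @export
tidy.mendelian_test <- function(x, ...) {
  out <- tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
  if (!is.null(x$p.exact)) out$p.exact <- x$p.exact
  out
}

#' @method glance s0_test_result
#' @export
glance.s0_test_result <- function(x, ...) {
  tibble(
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2_fc > 0),
    n_down = sum(x$significant & x$log2_fc < 0),
    s0 = attr(x, "s0"),
    fdr = attr(x, "fdr"),
    n_perm_used = attr(x, "n_perm_used"),
    variance = attr(x, "variance")
  )
}

#' @method glance te_result
#' @export
glance.te_result <- function(x, ...) {
  out <- tibble(n_transcripts = nrow(x),
                n_dropped = nrow(attr(x, "dropped") %||% tibble()))
  counts <- attr(x, "class_counts")
  if (!is.null(counts)) {
    wide <- pivot_wider(counts, names_from = "shift_class", values_from = "n",
                        names_prefix = "n_")
    out <- bind_cols(out, wide)
  }
  out
}
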