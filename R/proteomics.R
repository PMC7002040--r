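#' Filter a protein-groups table
#'
#' Applies the standard quality filters in order: (1) drop decoy
#' (`reverse`), `potential_contaminant` and `only_identified_by_site` rows;
#' (2) drop rows annotated with any excluded GO term (default
#' `"blood microparticle"`); (3) drop rows with more than `max_zeros` zero
#' intensities counted across all samples. Per-rule removal counts are
#' recorded in the `removal_counts` attribute in application order.
#'
#' @param table Protein-groups tibble with logical flag columns `reverse`,
#'   `potential_contaminant`, `only_identified_by_site`, a `go_terms` column
#'   (';'-separated labels) and one intensity column per sample (0 =
#'   missing).
#' @param design Tibble with columns `sample` (intensity column names) and
#'   `group`; every `sample` must exist in `table`.
#' @param max_zeros Maximum tolerated zero intensities per row (default 3,
#'   "more than 3 zero-values" excluded).
#' @param excluded_go Character vector of GO terms whose rows are removed.
#' @return Filtered tibble with attribute `removal_counts` (tibble `rule`,
#'   `removed`).
#' @export
filter_protein_groups <- function(table, design, max_zeros = 3L,
                                  excluded_go = "blood microparticle") {
  validate_design(design, table)
  assert_scalar_number(max_zeros, "max_zeros", nonnegative = TRUE)
  flags <- c("reverse", "potential_contaminant", "only_identified_by_site")
  missing <- setdiff(c(flags, "go_terms"), names(table))
  if (length(missing) > 0) {
    abort_input(sprintf("Protein table is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  removed <- integer(0)

  bad_flag <- table$reverse | table$potential_contaminant |
    table$only_identified_by_site
  removed["decoy_contaminant_site"] <- sum(bad_flag)
  table <- table[!bad_flag, , drop = FALSE]

  if (length(excluded_go) > 0) {
    has_excluded <- map_lgl(str_split(table$go_terms, ";"), function(tt) {
      any(str_trim(tt) %in% excluded_go)
    })
    has_excluded[is.na(has_excluded)] <- FALSE
  } else {
    has_excluded <- rep(FALSE, nrow(table))
  }
  removed["excluded_go"] <- sum(has_excluded)
  table <- table[!has_excluded, , drop = FALSE]

  mat <- as.matrix(table[design$sample])
  too_many_zeros <- rowSums(mat == 0) > max_zeros
  removed["zero_values"] <- sum(too_many_zeros)
  table <- table[!too_many_zeros, , drop = FALSE]

  attr(table, "removal_counts") <- tibble(rule = names(removed),
                                          removed = as.integer(removed))
  table
}

validate_design <- function(design, table = NULL) {
  if (!is.data.frame(design) || !all(c("sample", "group") %in% names(design))) {
    abort_input("`design` must be a tibble with `sample` and `group` columns.")
  }
  if (anyDuplicated(design$sample)) {
    abort_input("`design` has duplicated sample names.")
  }
  if (!is.null(table)) {
    absent <- setdiff(design$sample, names(table))
    if (length(absent) > 0) {
      abort_input(sprintf("Unknown sample(s) in design: %s.",
                          paste(absent, collapse = ", ")))
    }
  }
  invisible(design)
}

#' Log2-transform an intensity table
#'
#' Positive intensities become log2 values; zeros become `NA` (the explicit
#' missing marker). Metadata columns are carried through unchanged.
#'
#' @param table Protein-groups tibble (intensities >= 0).
#' @param design Design tibble naming the intensity columns.
#' @return Tibble with `protein_id` and one log2 intensity column per sample
#'   (`NA` = missing).
#' @export
log2_transform <- function(table, design) {
  validate_design(design, table)
  mat <- as.matrix(table[design$sample])
  if (any(mat < 0, na.rm = TRUE)) abort_input("Negative intensity encountered.")
  out <- tibble(protein_id = table$protein_id)
  for (s in design$sample) {
    v <- table[[s]]
    out[[s]] <- ifelse(v > 0, log2(v), NA_real_)
  }
  out
}

#' Impute missing values from a downshifted normal distribution
#'
#' Perseus-style imputation for missing-not-at-random label-free data: each
#' missing value is replaced by a draw from
#' `Normal(mean_obs - shift * sd_obs, (width * sd_obs)^2)`, where `mean_obs`
#' and `sd_obs` are the observed-value statistics of its scope — the sample
#' column by default, or the whole matrix with `scope = "global"`.
#'
#' @param data Log2 intensity tibble from [log2_transform()] (`protein_id` +
#'   sample columns, `NA` = missing).
#' @param width Width of the imputation distribution in observed-SD units
#'   (default 0.3).
#' @param shift Downshift of its mean in observed-SD units (default 1.8).
#' @param scope `"per_sample"` (default) or `"global"`.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return The completed tibble with attributes `imputed_mask` (logical
#'   matrix) and `fraction_imputed`; see [imputation_fraction()].
#' @export
impute_downshifted <- function(data, width = 0.3, shift = 1.8,
                               scope = c("per_sample", "global"), seed = NULL) {
  scope <- match.arg(scope)
  assert_scalar_number(width, "width", positive = TRUE)
  assert_scalar_number(shift, "shift", nonnegative = TRUE)
  value_cols <- setdiff(names(data), "protein_id")
  mat <- as.matrix(data[value_cols])
  mask <- is.na(mat)

  if (scope == "per_sample") {
    n_obs <- colSums(!mask)
    if (any(n_obs < 2)) {
      abort_input(paste0(
        "Column(s) with fewer than 2 observed values: ",
        paste(value_cols[n_obs < 2], collapse = ", "),
        ". Filter low-coverage proteins before imputing."
      ))
    }
  } else if (sum(!mask) < 2) {
    abort_input("Fewer than 2 observed values overall; filter before imputing.")
  }

  mat <- with_optional_seed(seed, {
    if (scope == "per_sample") {
      for (j in seq_along(value_cols)) {
        miss <- mask[, j]
        if (any(miss)) {
          m <- mean(mat[!miss, j])
          s <- sd(mat[!miss, j])
          mat[miss, j] <- rnorm(sum(miss), m - shift * s, width * s)
        }
      }
    } else {
      obs <- mat[!mask]
      if (any(mask)) {
        m <- mean(obs)
        s <- sd(obs)
        mat[mask] <- rnorm(sum(mask), m - shift * s, width * s)
      }
    }
    mat
  })

  out <- bind_cols(tibble(protein_id = data$protein_id), as_tibble(mat))
  attr(out, "imputed_mask") <- mask
  attr(out, "fraction_imputed") <- mean(mask)
  out
}

#' Fraction of cells filled in by imputation
#'
#' @param data Output of [impute_downshifted()].
#' @return Scalar fraction in \[0, 1\].
#' @export
imputation_fraction <- function(data) {
  f <- attr(data, "fraction_imputed")
  if (is.null(f)) abort_input("`data` carries no imputation record.")
  f
}
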