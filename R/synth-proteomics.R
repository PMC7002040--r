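#' Simulate a label-free proteomics intensity table
#'
#' Generates a proteinGroups-style table for two groups with known ground
#' truth. True protein log2 abundances are Normal(`intensity_mean`,
#' `intensity_sd`); a random `effect_fraction` of (non-histone) proteins is
#' shifted by `effect_size` log2 units in the second group, with the sign
#' randomised per protein. Replicate measurements add Normal(0, `resid_sd`)
#' noise. Each measurement is then observed with probability
#' `1 - plogis((mnar_tau - x) / mnar_kappa)` — a missing-not-at-random
#' mechanism that drops low-abundance values preferentially — and missing
#' values are encoded as intensity 0, matching MaxQuant LFQ output.
#'
#' The table includes `cfg$n_histones` high-abundance histone anchor
#' proteins (never affected, never missing in practice) for the proteomic
#' ruler, organelle localisation labels, and a small number of decoy /
#' contaminant / site-only flagged rows plus a "blood microparticle" GO
#' annotation so the filtering rules have work to do.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `proteomics_sim` with elements `protein_groups`
#'   (tibble: `protein_id`, `gene_name`, `molecular_weight_kda`, flag
#'   columns, `go_terms`, `localisation`, `is_histone`, one intensity column
#'   per sample), `design` (tibble: `sample`, `group`) and `true_effects`
#'   (tibble: `protein_id`, `true_log2_fc`, `affected`).
#' @examples
#' sim <- simulate_proteomics(synth_config(seed = 1, n_proteins = 100))
#' sim$design
#' @export
simulate_proteomics <- function(cfg) {
  cfg <- validate_synth_config(unclass(cfg))
  with_seed(as.integer(cfg$seed) + 2L, simulate_proteomics_impl(cfg))
}

simulate_proteomics_impl <- function(cfg) {
  n <- cfg$n_proteins
  groups <- cfg$groups
  design <- tibble(
    sample = unlist(map2(names(groups), groups,
                         function(g, k) paste(g, seq_len(k), sep = "_"))),
    group = rep(names(groups), groups)
  )

  histone_names <- c("H2AFZ", "H2BC1", "H3C1", "H4C1", "H1-0", "H2AC4",
                     "H2BC11", "H3-3A")
  is_histone <- seq_len(n) <= cfg$n_histones
  gene <- sprintf("GENE%04d", seq_len(n))
  gene[is_histone] <- head(rep(histone_names, length.out = cfg$n_histones),
                           cfg$n_histones)

  compartments <- c("mitochondrion", "nucleus", "cytosol",
                    "endoplasmic reticulum", "plasma membrane", "golgi")
  loc <- sample(compartments, n, replace = TRUE,
                prob = c(0.30, 0.20, 0.30, 0.10, 0.07, 0.03))
  dual <- runif(n) < 0.1
  loc[dual] <- paste(loc[dual],
                     sample(compartments, sum(dual), replace = TRUE), sep = ";")
  loc[is_histone] <- "nucleus"

  mu <- rnorm(n, cfg$intensity_mean, cfg$intensity_sd)
  mu[is_histone] <- cfg$intensity_mean + 2.5 * cfg$intensity_sd

  affected <- rep(FALSE, n)
  n_aff <- round(cfg$effect_fraction * sum(!is_histone))
  if (n_aff > 0) affected[sample(which(!is_histone), n_aff)] <- TRUE
  effect <- numeric(n)
  effect[affected] <- cfg$effect_size * sample(c(-1, 1), n_aff, replace = TRUE)

  values <- matrix(0, nrow = n, ncol = nrow(design),
                   dimnames = list(NULL, design$sample))
  group2 <- names(groups)[2]
  for (j in seq_len(nrow(design))) {
    m <- mu + if (design$group[j] == group2) effect else 0
    x <- m + rnorm(n, 0, cfg$resid_sd)
    p_miss <- if (cfg$mnar_kappa == 0) {
      ifelse(x < cfg$mnar_tau, 1, ifelse(x > cfg$mnar_tau, 0, 0.5))
    } else {
      plogis((cfg$mnar_tau - x) / cfg$mnar_kappa)
    }
    miss <- runif(n) < p_miss
    values[, j] <- ifelse(miss, 0, 2^x)
  }

  go <- rep("", n)
  pg <- tibble(
    protein_id = sprintf("P%05d", seq_len(n)),
    gene_name = gene,
    molecular_weight_kda = round(rlnorm(n, log(50), 0.5), 2),
    reverse = FALSE,
    potential_contaminant = FALSE,
    only_identified_by_site = FALSE,
    go_terms = go,
    localisation = loc,
    is_histone = is_histone
  )
  pg <- bind_cols(pg, as_tibble(values))

  # QC-flagged extras exercising the filter rules (not in true_effects)
  n_bad <- max(2L, round(0.01 * n))
  bad <- pg[sample(n, 3 * n_bad, replace = TRUE), ]
  bad$protein_id <- sprintf("BAD%05d", seq_len(nrow(bad)))
  bad$is_histone <- FALSE
  bad$reverse <- rep(c(TRUE, FALSE, FALSE), each = n_bad)
  bad$potential_contaminant <- rep(c(FALSE, TRUE, FALSE), each = n_bad)
  bad$only_identified_by_site <- rep(c(FALSE, FALSE, TRUE), each = n_bad)
  micro <- pg[sample(which(!is_histone), n_bad), ]
  micro$protein_id <- sprintf("MP%05d", seq_len(n_bad))
  micro$is_histone <- FALSE
  micro$go_terms <- "blood microparticle"

  structure(
    list(
      protein_groups = bind_rows(pg, bad, micro),
      design = design,
      true_effects = tibble(
        protein_id = pg$protein_id,
        true_log2_fc = effect,
        affected = affected
      )
    ),
    class = "proteomics_sim"
  )
}

#' @export
print.proteomics_sim <- function(x, ...) {
  cat(sprintf("<proteomics_sim> %d protein groups x %d samples (%d affected)\n",
              nrow(x$protein_groups), nrow(x$design),
              sum(x$true_effects$affected)))
  invisible(x)
}
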