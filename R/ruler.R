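AVOGADRO <- 6.02214076e23
MEAN_BP_MASS_DA <- 615.8771  # average mass of a DNA base pair, g/mol

#' DNA mass per cell from genome size
#'
#' `genome_bp * ploidy * 615.8771 / N_A * 1e12` picograms, using the average
#' molar mass of a DNA base pair.
#'
#' @param genome_bp Haploid genome size in base pairs.
#' @param ploidy Copies of the genome per cell (default 2).
#' @return DNA mass per cell in pg.
#' @examples
#' dna_mass_from_genome(2.7e9)  # mouse, diploid: ~5.5 pg
#' @export
dna_mass_from_genome <- function(genome_bp, ploidy = 2) {
  assert_scalar_number(genome_bp, "genome_bp", positive = TRUE)
  assert_scalar_number(ploidy, "ploidy", positive = TRUE)
  genome_bp * ploidy * MEAN_BP_MASS_DA / AVOGADRO * 1e12
}

#' Proteomic-ruler protein mass and copy numbers per cell
#'
#' Histone proteins are bound to DNA in a fixed stoichiometry, so the summed
#' histone MS signal can serve as an internal standard equal to the cellular
#' DNA mass. Each protein's mass per cell is its intensity divided by the
#' summed histone intensity times the DNA mass; copy numbers follow from the
#' molecular weight via Avogadro's number:
#' `copies = mass_pg * 1e-12 / (MW_kDa * 1000) * N_A`.
#'
#' @param table Protein-groups tibble with `protein_id`, logical
#'   `is_histone`, `molecular_weight_kda` and intensity columns.
#' @param intensity Character vector of intensity column names to process
#'   (each is ruled independently).
#' @param dna_mass_pg DNA mass per cell in pg; alternatively give
#'   `genome_bp` (and `ploidy`) to derive it via [dna_mass_from_genome()].
#' @param genome_bp,ploidy Genome-size alternative to `dna_mass_pg`.
#' @return Tibble of class `ruler_result` with columns `protein_id`,
#'   `sample`, `intensity`, `mass_pg`, `copies_per_cell`; attribute
#'   `total_mass_pg` (named per sample). Rows with missing/zero molecular
#'   weight are skipped with a warning.
#' @examples
#' tab <- tibble::tibble(protein_id = c("h", "x"), is_histone = c(TRUE, FALSE),
#'                       molecular_weight_kda = c(11, 50), i = c(1e6, 2e6))
#' proteomic_ruler(tab, "i", dna_mass_pg = 6.5)
#' @export
proteomic_ruler <- function(table, intensity, dna_mass_pg = NULL,
                            genome_bp = NULL, ploidy = 2) {
  if (is.null(dna_mass_pg)) {
    if (is.null(genome_bp)) {
      abort_config("Provide `dna_mass_pg` or `genome_bp`.")
    }
    dna_mass_pg <- dna_mass_from_genome(genome_bp, ploidy)
  }
  assert_scalar_number(dna_mass_pg, "dna_mass_pg", positive = TRUE)
  needed <- c("protein_id", "is_histone", "molecular_weight_kda")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    abort_input(sprintf("Protein table is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  absent <- setdiff(intensity, names(table))
  if (length(absent) > 0) {
    abort_input(sprintf("Unknown intensity column(s): %s.",
                        paste(absent, collapse = ", ")))
  }
  bad_mw <- is.na(table$molecular_weight_kda) | table$molecular_weight_kda <= 0
  if (any(bad_mw)) {
    warn(sprintf("proteomic_ruler: skipping %d row(s) with missing/zero MW.",
                 sum(bad_mw)))
    table <- table[!bad_mw, , drop = FALSE]
  }
  per_sample <- map(intensity, function(s) {
    v <- table[[s]]
    histone_sum <- sum(v[table$is_histone])
    if (!is.finite(histone_sum) || histone_sum <= 0) {
      abort_input(sprintf("No histone signal in column `%s`.", s))
    }
    mass_pg <- v / histone_sum * dna_mass_pg
    tibble(
      protein_id = table$protein_id,
      sample = s,
      intensity = v,
      mass_pg = mass_pg,
      copies_per_cell = mass_pg * 1e-12 / (table$molecular_weight_kda * 1000) *
        AVOGADRO
    )
  })
  out <- list_rbind(per_sample)
  totals <- summarise(group_by(out, .data$sample),
                      total = sum(.data$mass_pg), .groups = "drop")
  attr(out, "total_mass_pg") <- setNames(totals$total, totals$sample)
  attr(out, "dna_mass_pg") <- dna_mass_pg
  class(out) <- c("ruler_result", class(out))
  out
}

#' Total protein mass per cell from a ruler result
#'
#' @param ruler A `ruler_result`.
#' @return Named numeric vector, pg per cell per ruled intensity column.
#' @export
total_protein_mass <- function(ruler) {
  t <- attr(ruler, "total_mass_pg")
  if (is.null(t)) abort_input("`ruler` carries no total-mass record.")
  t
}

#' Partition protein mass across subcellular compartments
#'
#' Maps each ruled protein to its compartment(s) and sums mass per
#' compartment and sample. Multi-localised proteins split their mass equally
#' across their compartments; proteins absent from the localisation map
#' contribute to `"unassigned"`. Percentages sum to 100 per sample.
#'
#' @param ruler A `ruler_result` from [proteomic_ruler()].
#' @param localisation Tibble with `protein_id` and `compartment`
#'   (';'-separated multi-labels allowed).
#' @return Tibble with `sample`, `compartment`, `mass_pg`, `percent`.
#' @export
organelle_mass_fractions <- function(ruler, localisation) {
  if (!all(c("protein_id", "compartment") %in% names(localisation))) {
    abort_input("`localisation` needs `protein_id` and `compartment` columns.")
  }
  loc <- distinct(localisation, .data$protein_id, .keep_all = TRUE)
  comp <- loc$compartment[match(ruler$protein_id, loc$protein_id)]
  comp[is.na(comp) | !nzchar(comp)] <- "unassigned"
  split_comp <- str_split(comp, ";")
  rows <- list_rbind(map(seq_along(split_comp), function(i) {
    cc <- str_trim(split_comp[[i]])
    cc <- cc[nzchar(cc)]
    if (length(cc) == 0) cc <- "unassigned"
    tibble(sample = ruler$sample[i], compartment = cc,
           mass_pg = ruler$mass_pg[i] / length(cc))
  }))
  out <- summarise(group_by(rows, .data$sample, .data$compartment),
                   mass_pg = sum(.data$mass_pg), .groups = "drop_last")
  out <- ungroup(mutate(out, percent = 100 * .data$mass_pg / sum(.data$mass_pg)))
  arrange(out, .data$sample, desc(.data$percent))
}
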