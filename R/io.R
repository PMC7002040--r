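#' Read a transcript count table
#'
#' TSV with a `transcript_id` first column and one integer column per
#' sample. Duplicate transcript ids, empty tables and non-integer counts are
#' rejected with informative errors.
#'
#' @param path TSV path.
#' @return Tibble: `transcript_id` + numeric sample columns.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("Count file not found: %s", path))
  tab <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    abort_input(sprintf("Count table is empty: %s", path))
  }
  names(tab)[1] <- "transcript_id"
  if (anyDuplicated(tab$transcript_id)) {
    dup <- tab$transcript_id[duplicated(tab$transcript_id)][1]
    abort_input(sprintf("Duplicated transcript id: %s", dup))
  }
  for (col in setdiff(names(tab), "transcript_id")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      abort_input(sprintf("Non-numeric counts in column `%s`.", col))
    }
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad) > 0) {
      abort_input(sprintf("Non-integer count at row %d, column `%s`.",
                          bad[1], col))
    }
  }
  tab
}

#' Read a polysome sample sheet
#'
#' TSV with columns `sample_id`, `condition`, `replicate`, `pool`; validated
#' with [compute_te()]'s design rules ((condition, replicate, pool) unique,
#' every replicate has a heavy and a light sample).
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("Sample sheet not found: %s", path))
  sheet <- read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_sheet(sheet)
  sheet
}

#' Column dialect of a proteinGroups table
#'
#' Describes how to read a MaxQuant-style proteinGroups TSV: the metadata
#' column names, the "+" flag convention and the intensity column prefix.
#'
#' @param id,gene,mw,reverse,contaminant,site,go,localisation Column names.
#' @param intensity_prefix Prefix identifying intensity columns; the
#'   remainder of the column name is the sample id.
#' @return A named list of class `pg_dialect`.
#' @export
pg_dialect <- function(id = "Protein IDs",
                       gene = "Gene names",
                       mw = "Mol. weight [kDa]",
                       reverse = "Reverse",
                       contaminant = "Potential contaminant",
                       site = "Only identified by site",
                       go = "GO terms",
                       localisation = "Subcellular localisation",
                       intensity_prefix = "LFQ intensity ") {
  structure(list(id = id, gene = gene, mw = mw, reverse = reverse,
                 contaminant = contaminant, site = site, go = go,
                 localisation = localisation,
                 intensity_prefix = intensity_prefix),
            class = "pg_dialect")
}

#' Read a proteinGroups-style TSV
#'
#' Parses a MaxQuant proteinGroups dialect table into the package's
#' canonical protein-groups tibble: "+" flags become logicals, missing
#' intensities become 0, and intensity columns (identified by
#' `dialect$intensity_prefix`) are renamed to their bare sample ids. Histone
#' rows are recognised by gene name (`H1`-`H4`/`H2A`/`H2B` families).
#'
#' @param path TSV path.
#' @param dialect A [pg_dialect()].
#' @return Protein-groups tibble with columns `protein_id`, `gene_name`,
#'   `molecular_weight_kda`, `reverse`, `potential_contaminant`,
#'   `only_identified_by_site`, `go_terms`, `localisation`, `is_histone` and
#'   one intensity column per sample.
#' @export
read_protein_groups <- function(path, dialect = pg_dialect()) {
  if (!file.exists(path)) abort_input(sprintf("File not found: %s", path))
  # everything as character: "+" flag columns and all-empty columns defeat
  # type guessing; numerics are converted explicitly below
  raw <- read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = character(),
                  col_types = readr::cols(.default = readr::col_character()))
  required <- c(dialect$id, dialect$mw, dialect$reverse, dialect$contaminant,
                dialect$site)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort_input(sprintf("proteinGroups file lacks column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  int_cols <- names(raw)[str_starts(names(raw), stringr::fixed(dialect$intensity_prefix))]
  if (length(int_cols) == 0) {
    abort_input(sprintf("No intensity columns with prefix `%s`.",
                        dialect$intensity_prefix))
  }
  flag <- function(col) {
    v <- raw[[col]]
    !is.na(v) & str_trim(as.character(v)) == "+"
  }
  opt <- function(col) {
    if (col %in% names(raw)) as.character(raw[[col]]) else rep("", nrow(raw))
  }
  gene <- opt(dialect$gene)
  out <- tibble(
    protein_id = as.character(raw[[dialect$id]]),
    gene_name = gene,
    molecular_weight_kda = as.numeric(raw[[dialect$mw]]),
    reverse = flag(dialect$reverse),
    potential_contaminant = flag(dialect$contaminant),
    only_identified_by_site = flag(dialect$site),
    go_terms = opt(dialect$go),
    localisation = opt(dialect$localisation),
    is_histone = str_detect(str_to_upper(gene),
                            "^(H1|H2A|H2B|H3|H4)([^0-9A-Z]|[C\\-0-9]|$)")
  )
  for (col in int_cols) {
    sample_id <- str_remove(col, stringr::fixed(dialect$intensity_prefix))
    v <- suppressWarnings(as.numeric(raw[[col]]))
    v[is.na(v)] <- 0
    out[[sample_id]] <- v
  }
  out
}

#' Write a protein-groups tibble in proteinGroups dialect
#'
#' Inverse of [read_protein_groups()]: logical flags become "+"/"",
#' intensity columns get the dialect prefix.
#'
#' @param table Canonical protein-groups tibble.
#' @param path Output TSV path.
#' @param dialect A [pg_dialect()].
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(table, path, dialect = pg_dialect()) {
  meta <- c("protein_id", "gene_name", "molecular_weight_kda", "reverse",
            "potential_contaminant", "only_identified_by_site", "go_terms",
            "localisation", "is_histone")
  int_cols <- setdiff(names(table), meta)
  out <- tibble(
    !!dialect$id := table$protein_id,
    !!dialect$gene := table$gene_name,
    !!dialect$mw := table$molecular_weight_kda,
    !!dialect$reverse := ifelse(table$reverse, "+", ""),
    !!dialect$contaminant := ifelse(table$potential_contaminant, "+", ""),
    !!dialect$site := ifelse(table$only_identified_by_site, "+", ""),
    !!dialect$go := table$go_terms,
    !!dialect$localisation := table$localisation
  )
  for (col in int_cols) {
    out[[paste0(dialect$intensity_prefix, col)]] <- table[[col]]
  }
  write_tsv(out, path)
  invisible(path)
}

#' Read / write a run configuration
#'
#' Run configurations are plain named lists serialised as YAML; they
#' round-trip losslessly. See [run_pipeline()] for the recognised fields.
#'
#' @param path YAML path.
#' @param config Named list.
#' @return `read_run_config()`: the configuration list. `write_run_config()`:
#'   `path`, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("Config file not found: %s", path))
  yaml::read_yaml(path)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
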