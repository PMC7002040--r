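#' Run the full analysis pipeline from a configuration
#'
#' Executes one or both analysis chains and writes every stage's table plus a
#' provenance manifest to `config$out_dir`:
#'
#' * **te** chain: simulate (or read) polysome counts, compute TE, change in
#'   TE and shift classes, extract or reuse 5'UTR features, and produce the
#'   GC/length association report (Pearson tests, binned profiles,
#'   mitochondrial-subset summary, TOP-motif enrichment among shifted
#'   transcripts).
#' * **proteomics** chain: simulate (or read) a protein-groups table, filter,
#'   log2-transform, impute, run the s0 permutation test, and compute
#'   proteomic-ruler masses and organelle mass fractions.
#'
#' The run is deterministic given the configuration: every stochastic stage
#' receives a seed derived from `config$seed`, and the manifest contains no
#' timestamps, so reruns are byte-identical.
#'
#' @param config Named list or path to a YAML file. Recognised fields:
#'   `seed` (integer, required), `out_dir` (required), `chains` (subset of
#'   `"te"`, `"proteomics"`; default both), `te` (list: either `simulate:
#'   TRUE` with [synth_config()] overrides, or `counts` + `sample_sheet` [+
#'   `gtf` + `fasta`] paths; optional `min_total`, `pseudocount`,
#'   `threshold`, `window`), `proteomics` (list: either `simulate: TRUE`
#'   with overrides, or `protein_groups` + `design` paths; optional `s0`,
#'   `n_perm`, `fdr`, `variance`, `width`, `shift`, `max_zeros`,
#'   `dna_mass_pg` or `genome_bp`/`ploidy`).
#' @return Invisibly, a named list of the result tables plus
#'   `manifest_path`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.list(config)) abort_config("`config` must be a list or a YAML path.")
  if (is.null(config$seed)) abort_config("`config$seed` is required.")
  if (is.null(config$out_dir)) abort_config("`config$out_dir` is required.")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  chains <- config$chains %||% c("te", "proteomics")

  manifest <- list(
    package = "polysomics",
    version = as.character(packageVersion("polysomics")),
    seed = seed,
    chains = chains,
    stages = list()
  )
  results <- list()
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  outfile <- function(name) file.path(out_dir, name)

  if ("te" %in% chains) {
    te_cfg <- config$te %||% list()
    if (isTRUE(te_cfg$simulate) || is.null(te_cfg$counts)) {
      synth_args <- te_cfg[intersect(names(te_cfg), names(formals(synth_config)))]
      synth_args$seed <- seed
      cfg <- do.call(synth_config, synth_args)
      ts <- generate_transcriptome(cfg)
      sim <- simulate_polysome_experiment(ts, cfg)
      counts <- sim$counts
      sheet <- sim$sample_sheet
      utr <- tibble(transcript_id = ts$transcript_id, gc = ts$gc,
                    length = ts$utr5_length, has_top = ts$is_top,
                    is_mito = ts$is_mito)
      write_tsv(counts, outfile("counts.tsv"))
      write_tsv(sheet, outfile("sample_sheet.tsv"))
      write_tsv(sim$true_effects, outfile("true_effects.tsv"))
      note("simulate_te", n_transcripts = nrow(counts),
           n_samples = nrow(sheet), seed = seed)
    } else {
      counts <- read_counts(te_cfg$counts)
      sheet <- read_sample_sheet(te_cfg$sample_sheet)
      if (is.null(te_cfg$gtf) || is.null(te_cfg$fasta)) {
        abort_config("te chain on real counts needs `gtf` and `fasta` paths.")
      }
      utr_rec <- extract_five_prime_utrs(te_cfg$gtf, te_cfg$fasta)
      utr <- tibble(transcript_id = utr_rec$transcript_id, gc = utr_rec$gc,
                    length = utr_rec$length, has_top = utr_rec$has_top,
                    is_mito = FALSE)
      note("read_te", n_transcripts = nrow(counts), n_samples = nrow(sheet))
    }

    te <- compute_te(counts, sheet,
                     min_total = te_cfg$min_total %||% 10L,
                     pseudocount = te_cfg$pseudocount %||% 0.5)
    te <- change_in_te(te)
    te <- classify_te_shift(te, threshold = te_cfg$threshold %||% 1)
    te_out <- left_join(as_tibble(te), utr, by = "transcript_id")
    write_tsv(te_out, outfile("te_table.tsv"))
    note("te", n_scored = nrow(te), n_dropped = nrow(attr(te, "dropped")),
         counts = as.list(setNames(shift_class_counts(te)$n,
                                   as.character(shift_class_counts(te)$shift_class))))

    assoc <- filter(te_out, !.data$excluded, is.finite(.data$gc))
    gc_cor <- pearson_test(assoc$gc, assoc$log2_change)
    len_cor <- pearson_test(log10(assoc$length + 1), assoc$log2_change)
    report <- bind_rows(
      mutate(tidy(gc_cor), feature = "gc"),
      mutate(tidy(len_cor), feature = "log10_length")
    )
    write_tsv(report, outfile("association_report.tsv"))
    bins <- bin_profile(assoc, .data$log2_change, .data$gc,
                        window = te_cfg$window %||% 0.5)
    write_tsv(bins, outfile("bin_profile_gc.tsv"))
    if (any(assoc$is_mito)) {
      mito <- subset_shift_summary(assoc, .data$log2_change, .data$is_mito)
      write_tsv(tidy(mito), outfile("mito_subset.tsv"))
      results$mito_subset <- mito
    }
    shifted <- !is.na(assoc$shift_class) & assoc$shift_class != "none"
    if (any(shifted) && any(assoc$has_top)) {
      top_enrich <- enrichment_2x2(sum(assoc$has_top & shifted),
                                   sum(assoc$has_top), sum(shifted), nrow(assoc))
      write_tsv(tidy(top_enrich), outfile("top_enrichment.tsv"))
      results$top_enrichment <- top_enrich
    }
    note("association", n_used = nrow(assoc),
         excluded_undefined_utr = sum(te_out$excluded | !is.finite(te_out$gc)),
         gc_r = gc_cor$estimate)
    results$te <- te_out
    results$association <- report
    results$bins <- bins
  }

  if ("proteomics" %in% chains) {
    pr_cfg <- config$proteomics %||% list()
    if (isTRUE(pr_cfg$simulate) || is.null(pr_cfg$protein_groups)) {
      synth_args <- pr_cfg[intersect(names(pr_cfg), names(formals(synth_config)))]
      synth_args$seed <- seed
      cfg <- do.call(synth_config, synth_args)
      sim <- simulate_proteomics(cfg)
      pg <- sim$protein_groups
      design <- sim$design
      write_protein_groups(pg, outfile("protein_groups.tsv"))
      write_tsv(sim$true_effects, outfile("protein_true_effects.tsv"))
      note("simulate_proteomics", n_proteins = nrow(pg), seed = seed)
    } else {
      pg <- read_protein_groups(pr_cfg$protein_groups)
      design <- read_tsv(pr_cfg$design, show_col_types = FALSE, progress = FALSE)
      validate_design(design, pg)
      note("read_proteomics", n_proteins = nrow(pg))
    }

    filtered <- filter_protein_groups(pg, design,
                                      max_zeros = pr_cfg$max_zeros %||% 3L)
    rc <- attr(filtered, "removal_counts")
    note("filter", removed = as.list(setNames(rc$removed, rc$rule)),
         n_kept = nrow(filtered))
    logged <- log2_transform(filtered, design)
    imputed <- impute_downshifted(logged,
                                  width = pr_cfg$width %||% 0.3,
                                  shift = pr_cfg$shift %||% 1.8,
                                  seed = seed + 10L)
    note("impute", fraction_imputed = imputation_fraction(imputed))
    diff <- s0_permutation_test(imputed, design,
                                s0 = pr_cfg$s0 %||% 0.1,
                                n_perm = pr_cfg$n_perm %||% 250L,
                                fdr = pr_cfg$fdr %||% 0.05,
                                variance = pr_cfg$variance %||% "welch",
                                seed = seed + 11L)
    write_tsv(as_tibble(diff), outfile("differential_proteins.tsv"))
    note("s0_test", n_significant = sum(diff$significant),
         s0 = attr(diff, "s0"), n_perm_used = attr(diff, "n_perm_used"))

    dna_mass <- pr_cfg$dna_mass_pg %||%
      dna_mass_from_genome(pr_cfg$genome_bp %||% 2.7e9,
                           pr_cfg$ploidy %||% 2)
    ruler <- proteomic_ruler(filtered, design$sample, dna_mass_pg = dna_mass)
    write_tsv(as_tibble(ruler), outfile("ruler.tsv"))
    loc <- tibble(protein_id = filtered$protein_id,
                  compartment = filtered$localisation)
    fractions <- organelle_mass_fractions(ruler, loc)
    write_tsv(fractions, outfile("organelle_fractions.tsv"))
    note("ruler", dna_mass_pg = dna_mass,
         total_mass_pg = as.list(total_protein_mass(ruler)))
    results$differential <- diff
    results$ruler <- ruler
    results$organelle_fractions <- fractions
  }

  manifest_path <- outfile("manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  results$manifest_path <- manifest_path
  invisible(results)
}
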