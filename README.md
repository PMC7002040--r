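# polysomics

Tools for asking how ribosome programming reshapes gene expression — in
particular mitochondrial gene expression — from two complementary data
types: **polysome-profiling RNA-seq** (which mRNAs are heavily loaded with
ribosomes) and **label-free quantitative proteomics** (what the cell's
protein mass actually looks like). The package is aimed at analysts working
with pooled heavy/light polysome fractions and MaxQuant/Perseus-style
proteinGroups tables, and ships seeded synthetic-data generators with known
ground truth so the whole pipeline is testable without any external
download.

## What it computes

**Translational efficiency (TE).** Polysome gradients are pooled into a
*light* pool (1–3 ribosomes) and a *heavy* pool (>3 ribosomes). For
transcript *t* in one replicate,

```
TE_t = (heavy relative abundance of t) / (light relative abundance of t)
```

where relative abundance is the within-sample proportion
`(count + pseudocount) / Σ(count + pseudocount)`, so TE is invariant to
per-sample sequencing depth. Per-condition TE scores average the
per-replicate ratios; the change in TE between knockdown and control is
analysed as `log2(TE_kd / TE_ctrl)`, with transcripts called shifted when
the log2 change exceeds ±1 (strictly — "TE doubled or halved").

**5'UTR features and association.** `extract_five_prime_utrs()` assembles
strand-aware spliced 5'UTRs from a GTF + genome FASTA; `gc_content()` and
`detect_top_motif()` (cap-adjacent C followed by a 4–15 nt pyrimidine run)
provide the features. The association layer offers binned profiles along the
ΔTE axis (`bin_profile()`, windows of 0.5 log2 units), a Pearson
correlation test (`pearson_test()`, t-based, two-sided), a Mann–Whitney test
with an exact small-sample branch (`mann_whitney()`), subset-vs-rest shift
summaries (`subset_shift_summary()`, e.g. mitochondrially encoded
transcripts against everything else) and a 2×2 hypergeometric/Fisher
enrichment test (`enrichment_2x2()`) for motif content among shifted
transcripts.

**Perseus-style proteomics statistics.** Filtering of decoy / contaminant /
site-only rows, excluded GO terms, and rows with more than 3 zero
intensities; log2 transform with zeros as missing; downshifted-normal
imputation of missing-not-at-random values (`Normal(m − 1.8·s, (0.3·s)²)`
per sample); the SAM/Perseus moderated statistic

```
d_i = (mean2_i − mean1_i) / (se_i + s0)
```

with permutation-based FDR (group-label permutations, q = best achievable
FDR at any threshold the protein passes, π₀ = 1), plus `s0_tusher()`, the
canonical coefficient-of-variation–minimising choice of `s0`. The
**proteomic ruler** converts intensities to protein mass and copy numbers
per cell using the summed histone signal as an internal standard equal to
the cellular DNA mass, and `organelle_mass_fractions()` partitions protein
mass across subcellular compartments.

**Physiology metrics.** Exactly testable closed forms: respiratory exchange
ratio `VCO2/VO2`, energy expenditure `3.815·VO2 + 1.232·VCO2`, fractional
shortening `(LVDD − LVSD)/LVDD × 100`, relative wall thickness
`(IVSD + LVPWD)/LVDD`, Bazett-corrected QT `QT/√RR`, respiratory control
ratio `OXPHOS/LEAK`, and a Mendelian goodness-of-fit test
(`mendelian_gof()`, χ² against 1:2:1 with an optional exact multinomial p).

## Worked example

```r
library(polysomics)
library(dplyr)

cfg <- synth_config(seed = 1, n_transcripts = 2000)  # 2 conditions x 3 replicates
ts  <- generate_transcriptome(cfg, sequences = FALSE)
sim <- simulate_polysome_experiment(ts, cfg)

te <- compute_te(sim$counts, sim$sample_sheet) |>
  change_in_te() |>
  classify_te_shift(threshold = 1)
shift_class_counts(te)
#>   shift_class     n
#> 1 down          200
#> 2 none         1536
#> 3 up            264

assoc <- te |>
  inner_join(select(ts, transcript_id, gc, is_mito), by = "transcript_id") |>
  filter(!excluded)
pearson_test(assoc$gc, assoc$log2_change)
#> Pearson r = -0.1331 (n = 2000, t = -6.003, two-sided p = 2.29e-09)

subset_shift_summary(assoc, log2_change, is_mito)
#>   group      n  median     q1     q3 fraction_negative
#> 1 subset    13 -1.55   -1.95  -1.00              1
#> 2 rest    1987  0.0702 -0.447  0.619             0.463
#> Mann-Whitney U = 2044 (n = 13 vs 1987, normal approximation), two-sided p = 1.623e-07
```

The generator planted a GC-dependent knockdown shift tuned to a population
GC–ΔTE correlation of about −0.13 plus a −ln 2 logit shift on the 13
mitochondrially encoded transcripts; the recovered correlation (−0.133) and
the uniformly negative, roughly halved mitochondrial TE are the planted
truths read back out.

The proteomics chain:

```r
sim <- simulate_proteomics(cfg)
filtered <- filter_protein_groups(sim$protein_groups, sim$design)
attr(filtered, "removal_counts")
#>   rule                   removed
#> 1 decoy_contaminant_site      99
#> 2 excluded_go                 33
#> 3 zero_values                205

imputed <- impute_downshifted(log2_transform(filtered, sim$design), seed = 1)
imputation_fraction(imputed)          # 0.0499
res <- s0_permutation_test(imputed, sim$design, s0 = 0.1, seed = 1)
glance(res)
#>   n_proteins n_significant n_up n_down  s0   fdr n_perm_used variance
#> 1       3050           116   66     50 0.1  0.05           9 welch

ruler <- proteomic_ruler(filtered, sim$design$sample, genome_bp = 2.7e9)
total_protein_mass(ruler)             # ~350-440 pg per cell per sample
```

`autoplot()` methods give the standard figures (TE scatter, volcano), and
`run_pipeline()` executes either chain end to end from a YAML config,
writing every stage's TSV plus a provenance manifest. A thin command-line
wrapper with `simulate`, `te`, `utr`, `associate`, `proteomics`, `physio`
and `run` subcommands is installed at `inst/cli/polysomics.R`.

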