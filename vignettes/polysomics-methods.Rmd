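---
title: "polysomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polysomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the models, the parameters that matter and their defaults, what the
synthetic-data generators do and do not emulate, and the choices made where
the design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Translational efficiency from pooled polysome fractions

Polysome profiling separates mRNAs on a sucrose gradient by the number of
bound ribosomes. The analysis works on two pooled sequencing libraries per
replicate: a *light* pool (fractions with 1–3 ribosomes) and a *heavy* pool
(more than 3 ribosomes); fractions with no ribosomes form a sub-polysomal
pool that is collected but not analysed. `pool_fractions()` performs this
pooling when fraction-level counts are available; the boundary is a
parameter (`boundary = 3`) because the light pool can defensibly be defined
as "three or fewer" or "fewer than three" ribosomes — the default takes the
former, and the choice only moves one fraction between pools.

For transcript $t$ in one replicate, TE is the ratio of the transcript's
*relative abundance* in the heavy pool to its relative abundance in the
light pool, where relative abundance is the within-sample proportion
$(c_t + a)/\sum_u (c_u + a)$ with pseudocount $a$. Two consequences:

* TE is invariant to per-sample library size, so no external normalisation
  (TMM or similar) is needed or wanted — the definition itself normalises.
* TE is *relative to the pool*: if every transcript's heavy/light odds were
  shifted by the same factor, all measured TEs would be unchanged. Only
  differential shifts are identifiable. This matters for interpreting
  recovery experiments (below).

Per-condition scores average the per-replicate ratios arithmetically;
ratios are formed within replicate (heavy and light samples paired by
replicate index) before averaging. A geometric-mean option exists
(`average = "geometric"`) since averaging ratios is scale-asymmetric, but
the arithmetic mean is the default to match the field's usual "average of
the ratio" convention.

Defaults: `pseudocount = 0.5` (half a read, the usual continuity choice,
which also keeps zero-count pools finite) and `min_total = 10` (transcripts
with fewer than 10 raw reads across all heavy/light samples carry almost no
information about a ratio of proportions; they are dropped and reported via
the `dropped` attribute, never silently). Both are explicit arguments, and a
zero pseudocount plus `min_total = 0` reproduces the bare definition.

The change in TE is `log2(TE_knockdown / TE_control)`. Everything
downstream — the ±1 shift threshold, the 0.5-wide profile bins, the
correlation with GC — operates on this log2 scale: a threshold of "±1,
i.e. TE doubled or halved" is only coherent for a log-ratio, and resolving
the scale once globally avoids mixed conventions. The threshold test is
strict (`>1` or `< −1`); a transcript sitting exactly at the boundary is
"none". Transcripts with zero or undefined TE in either condition are
flagged (`excluded` column) and excluded from association analyses, with
the count reported — not silently dropped.

## 5'UTR features

`extract_five_prime_utrs()` defines a transcript's 5'UTR as the exonic
sequence strictly 5' of the first CDS base, spliced in transcript order and
reverse-complemented for minus-strand transcripts. GTF input is 1-based
inclusive (Ensembl dialect, read through `rtracklayer`); genome sequence
comes from a FASTA via `Biostrings`. Transcripts without any CDS feature
are skipped and counted; a CDS that starts at the first transcribed base
yields an empty, flagged record (length 0, GC undefined) rather than an
error. A CDS outside its transcript's exons is a malformed-annotation
error, as is a chromosome missing from the FASTA — both name the offender.

GC content is $(G+C)/(A+C+G+T)$, case-insensitive, with `N` and other
ambiguity codes excluded from the denominator; an empty or all-ambiguous
sequence has undefined GC and is flagged. GC is a fraction internally and a
percentage in written outputs.

The 5' terminal oligopyrimidine (TOP) motif has no single formal
definition; the package adopts the canonical description — a cap-adjacent
cytosine followed by an uninterrupted run of 4–15 pyrimidines — with both
run bounds configurable. The association layer treats TOP content as a
binary feature and tests enrichment among shifted transcripts with the
hypergeometric/Fisher machinery.

## Association statistics

`pearson_test()` computes the product-moment correlation with
$t = r\sqrt{(n-2)/(1-r^2)}$ and a two-sided p from the $t_{n-2}$
distribution — the same convention as `cor.test`, which the unit tests use
as an independent cross-check. P-values below double precision are printed
as "< 2.2e-16" but stored as computed. `mann_whitney()` uses the exact null
distribution of U when both groups are tie-free and the smaller has at most
8 observations, and otherwise a normal approximation with tie and
continuity corrections; the test suite verifies the exact branch against
full enumeration of all label assignments. `enrichment_2x2()` reports the
upper hypergeometric tail and the two-sided Fisher p (sum of table
probabilities no larger than the observed one); the odds ratio is the
sample cross-product ratio, not the conditional MLE, and is infinite for
tables with an empty off-diagonal cell.

`bin_profile()` bins on edges that are multiples of the window (default
0.5 log2 units) covering the data range, keeps empty interior bins with
$n = 0$, and reports per-bin mean and standard error of the feature.

## The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated: two conditions × three replicates, 2000 transcripts of which 13
are mitochondrially encoded, expected depth 5 × 10⁶ reads per pooled
sample, and 3-vs-3 label-free proteomics.

**Transcriptome.** UTR lengths are log-uniform on [10, 2000] nt and target
GC uniform on (0.2, 0.9); the stored GC is the realised base composition,
so it satisfies the same invariant as the extractor output. A configurable
fraction of transcripts (default 5%) carries a constructed TOP motif. With
`sequences = TRUE` each transcript becomes a full gene model (1–3 exons,
random strand, CDS, introns, padding) on its own contig, and the emitted
GTF/FASTA round-trips exactly through `extract_five_prime_utrs()`; with
`sequences = FALSE` only the features are drawn, which is what count-level
simulations at $n = 10{,}000$ use.

**Polysome counts.** Transcript $t$ has baseline abundance
$a_t \sim \mathrm{LogNormal}(0, 1.2)$, multiplied by 8 for mitochondrial
transcripts (mito-encoded mRNAs are among the most abundant in energetic
tissue), and a control heavy-pool share $p_t = \mathrm{logistic}(\alpha_t)$
with $\alpha_t \sim N(0, 0.7)$. The knockdown applies a logit shift
$\delta_t = \beta_{GC}(GC_t - \overline{GC}) + \beta_{mito}\,[t \in mito]
+ N(0, \sigma)$. Counts are negative binomial with variance
$m + \phi m^2$, $\phi = 0.05$ by default (sequencing depth and dispersion
are free parameters of the design, not estimates of any particular
dataset). Because TE equals the heavy/light odds up to a pool-level factor,
the true per-transcript effect recorded in the ground-truth table is
$\log_2 \Delta TE = \delta_t / \ln 2$.

Default effect sizes: $\beta_{mito} = -\ln 2$ (a 50% TE reduction of the
mitochondrial subset) and $\sigma = 0.5$ with $\beta_{GC}$ derived in
closed form by `beta_gc_for_correlation()` so that the population GC–ΔTE
correlation is −0.13: with GC uniform, $\rho = \beta\,\mathrm{sd}(GC) /
\sqrt{\beta^2 \mathrm{var}(GC) + \sigma^2}$, inverted for $\beta$.

Two identifiability caveats, both consequences of TE being
pool-relative:

* A logit shift applied uniformly to *all* transcripts is unobservable —
  the within-sample proportions renormalise it away. Recovery experiments
  therefore shift a subset (the 13 mitochondrial transcripts) against an
  unshifted background.
* When the shifted subset carries a non-trivial share of pool mass, the
  pool normaliser itself moves and the measured shift is biased toward
  zero by up to a few hundredths of a log2 unit (with the 8× mitochondrial
  abundance multiplier the subset can reach ~5–10% of heavy-pool mass).
  The *analytic* recovery check therefore runs with the multiplier at 1,
  where the subset share is ~0.7% and the identity is clean; the
  *study-like* subset check keeps the multiplier and the wider tolerance.
  "Noise-free" checks use $\sigma = 0$ and $\phi = 10^{-6}$ (the Poisson
  limit).

**Proteomics.** True log2 abundances are $N(25, 2)$ (typical LFQ log2
scale), histones pinned 2.5 SD above centre; replicate noise is
$N(0, 0.25)$. A value at log2 intensity $x$ is missing with probability
$\mathrm{logistic}((\tau - x)/\kappa)$ with $\tau = 22$, $\kappa = 0.6$ —
missing-not-at-random, low-abundance-biased, giving a value-level
missingness in the several-percent range typical of LFQ experiments —
and missing values are encoded as intensity 0, matching MaxQuant output.
A 5% fraction of proteins receives a ±1 log2 true effect in the second
group. The table carries decoy/contaminant/site-only flagged rows and a
"blood microparticle" GO annotation so the filter rules are exercised, plus
compartment labels (10% dual-localised) for the mass-partitioning step.

What the generators deliberately do **not** emulate: read-level artefacts
(FASTQ, positional/fragment bias), isoform ambiguity, correlated GC and
length (the two axes are treated as separate features), peptide-level
quantification, shared-peptide protein grouping, and batch structure.
Passing tests on synthetic data therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artefact of real libraries.

## Proteomics statistics

**Filtering** applies, in order: decoy/contaminant/site-only flags; excluded
GO terms (default `blood microparticle`); more than `max_zeros = 3` zero
intensities across all samples. Per-rule removal counts are reported in
application order so alternative orders are auditable (a row failing two
rules is counted under the first).

**Imputation** replaces each missing value with a draw from
$N(\bar{x}_{obs} - 1.8\,s_{obs},\ (0.3\,s_{obs})^2)$ using the observed
mean and SD of its scope. The default scope is the sample column (the
Perseus default); a `global` scope is provided because "standard deviations
of the data" can be read either way. Columns with fewer than two observed
values are an error directing the user to filter first. The imputed-cell
mask and overall fraction are attached to the result; the test suite checks
the imputed distribution against its target normal (Kolmogorov–Smirnov) and
that the reported fraction equals the constructed missingness exactly.

**The s0-moderated permutation test.** The statistic is
$d_i = (\bar{x}_{2i} - \bar{x}_{1i})/(\mathrm{se}_i + s_0)$ with the Welch
standard error by default (a pooled-variance option exists because both
conventions appear in practice). The null is built from group-label
permutations: distinct labelings are enumerated up to the group-swap
symmetry (which leaves $|d|$ unchanged) and the observed labeling is
excluded — at 3 vs 3 that is 9 informative permutations, all of which are
used; when more than `n_perm` (default 250, the Perseus default) exist they
are sampled uniformly without replacement under a seed. For a symmetric
threshold $t$,
$\widehat{FDR}(t) = \frac{\mathrm{mean}_{perm}\,\#\{|d^*| \ge t\}}
{\#\{|d| \ge t\}}$, capped at 1 with $\pi_0$ fixed at 1 (conservative).
A protein's q-value is the smallest $\widehat{FDR}(t)$ over thresholds
$t \le |d_i|$ — the best FDR at which it would still be called — which
makes q monotone non-increasing in $|d|$.

**Choosing s0.** $s_0$ expresses how much a call should depend on the
absolute difference rather than only its precision; 0.1 and 0.2 are common
fixed choices and both are plain arguments. With very few replicates a
small fixed $s_0$ leaves the statistic dominated by 2-df variance
estimates, and no procedure based on such estimates can separate even
4-SD effects cleanly: the test suite's power simulation shows this regime
directly. The canonical remedy is the SAM recipe implemented in
`s0_tusher()`: choose $s_0$ on a grid of standard-error quantiles to
minimise the coefficient of variation of the spread of $d$ across the
standard-error range. The power/FDR validation uses `s0_tusher()`; the
null-calibration validation uses the fixed $s_0 = 0.1$, where permutation
FDR is conservative by construction. For real 3-vs-3 datasets the same
trade-off applies, and the automatic choice is recommended when absolute
fold changes matter.

**Proteomic ruler.** Histones are bound to DNA in fixed stoichiometry, so
the summed histone MS signal is used as an internal standard equal to the
cellular DNA mass: $\mathrm{mass}_i = I_i / \sum_{histones} I \times
m_{DNA}$, and copies per cell follow from the molecular weight via
Avogadro's number. The DNA mass per cell is a required input — either
directly in pg or via genome size (`genome_bp × ploidy × 615.8771 / N_A ×
10^{12}` pg; ~5.5 pg for a diploid mouse cell). Rows with missing or zero
molecular weight are skipped with a warning; a column without histone
signal is an error. Mass partitioning splits multi-localised proteins
equally across their compartments, routes unmapped mass to `unassigned`,
and returns percentages that sum to 100 per sample (conservation is tested
to 1e-9 relative).

## Physiology metrics

All metrics are pure closed forms, vectorised, with positivity checks on
denominators: RER = VCO₂/VO₂; energy expenditure = 3.815·VO₂ + 1.232·VCO₂
(the function is unit-agnostic — the output scale follows the gas-exchange
units, e.g. kcal/h for L/h inputs); FS = (LVDD − LVSD)/LVDD × 100 (%);
RWT = (IVSD + LVPWD)/LVDD, reading the septal thickness in diastole as the
first argument (the conventional definition; some sources print "IVDD" for
the same quantity); Bazett QTc = QT/√RR with seconds in and out
(`qtc_bazett_ms()` wraps milliseconds); RCR = OXPHOS/LEAK. Beats with
LVSD > LVDD are physiologically suspect and are flagged by
`physiology_table()` rather than rejected.

`mendelian_gof()` tests genotype counts against expected segregation
weights: $\chi^2 = \sum (O - E)^2/E$ with $df = k - 1$ and the upper-tail
chi-square p (equivalently the regularised upper incomplete gamma, which
the tests verify). The optional exact mode sums multinomial probabilities
of all outcome tables no more probable than the observed one, for totals up
to 100. Exact and asymptotic p agree well on average but the multinomial is
discrete: adjacent outcome tables can move the exact p by several
hundredths at totals of 50–100, so agreement is asserted on average (and
bounded in the worst case) rather than uniformly.

## Pipeline, formats and reproducibility

TSV is the universal tabular interchange (matching the MaxQuant/Perseus
ecosystem), FASTA/GTF carry sequence and annotation, YAML carries run
configuration. The proteinGroups reader takes a configurable dialect
(column names, "+" flag convention, intensity prefix) and encodes missing
intensities as 0 on the way in. `run_pipeline()` executes the TE and
proteomics chains from a config, writes every stage's table plus a
manifest recording package version, seeds, parameters and per-stage record
counts, and contains no timestamps — identical config and seed give
byte-identical outputs. Every stochastic function takes an explicit seed
and restores the caller's RNG state.

Problem sizes used by the validation suite were chosen to make Monte-Carlo
error small relative to the tolerances while keeping the default run
fast: 2000-transcript simulations at depth 5 × 10⁶ for recovery checks,
10 seeds at 10,000 transcripts for the correlation band, 2000 independent
replicates for the Pearson type-I rate, 20 null 2000 × 6 matrices for FDR
calibration, and 10,000 imputed cells for the distribution checks.

## Known limitations

* TE is identifiable only up to a pool-level factor; analyses should be
  read as *relative* shifts, and global translational up/down-regulation
  is invisible to this design.
* The permutation null at 3 vs 3 rests on 9 distinct labelings; q-values
  are correspondingly coarse, and the FDR estimate is conservative when
  many proteins carry true effects (the permuted matrices retain them).
* The exact Mann–Whitney branch requires tie-free data; heavily tied data
  fall back to the corrected normal approximation regardless of size.
* The UTR extractor assumes one gene model per `transcript_id` and does
  not attempt per-gene collapsing; annotation with CDS features
  inconsistent with exons is rejected rather than repaired.
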