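#' Configuration for the synthetic-data generators
#'
#' Bundles every tunable of the synthetic transcriptome, polysome-profiling
#' count simulator and label-free proteomics simulator into one validated
#' object. The defaults describe the study design the package targets: two
#' conditions (control vs knockdown) with three replicates each, 13
#' mitochondrially encoded transcripts, a GC-dependent knockdown shift in
#' translational efficiency plus a stronger shift on the mitochondrial
#' subset, and 3 vs 3 label-free proteomics with intensity-dependent
#' (missing-not-at-random) dropout.
#'
#' @param seed Integer seed; the generators are fully deterministic given the
#'   configuration. Transcriptome, polysome and proteomics stages draw from
#'   sub-seeds `seed`, `seed + 1` and `seed + 2` so each stage has its own
#'   stream.
#' @param n_transcripts Number of transcripts to simulate.
#' @param n_mito Number of transcripts flagged as mitochondrially encoded
#'   (default 13, the number of protein-coding genes on the mammalian
#'   mitochondrial genome).
#' @param n_replicates Replicates per condition (>= 2; the study used 3).
#' @param library_size Expected reads per pooled sample.
#' @param nb_dispersion Negative-binomial dispersion `phi` (> 0); counts are
#'   drawn with variance `m + phi * m^2`.
#' @param beta_gc Logit-scale slope of the knockdown shift on centred 5'UTR
#'   GC. The default is chosen so that, with `noise_sd = 0.5` and GC uniform
#'   on (0.2, 0.9), the population correlation between GC and log2 change in
#'   TE is approximately -0.13 (see [beta_gc_for_correlation()]).
#' @param beta_mito Extra logit-scale shift applied to mitochondrial
#'   transcripts; the default `-log(2)` halves their TE (a 50% reduction).
#' @param noise_sd Standard deviation of transcript-level logit-shift noise.
#' @param mito_abundance Abundance multiplier for mitochondrial transcripts
#'   (mito-encoded mRNAs are among the most abundant in energetic tissues).
#' @param top_fraction Fraction of transcripts built with a 5' terminal
#'   oligopyrimidine (TOP) motif.
#' @param include_subpolysomal Also emit sub-polysomal pool samples
#'   (collected in the design but unused downstream).
#' @param n_proteins Number of simulated protein groups.
#' @param groups Named integer vector of replicate counts per proteomics
#'   group (two groups, each >= 2).
#' @param n_histones Number of histone anchor proteins (high-abundance, used
#'   by the proteomic ruler).
#' @param intensity_mean,intensity_sd Mean and SD of true protein log2
#'   intensities.
#' @param resid_sd Within-group replicate SD of log2 intensities.
#' @param effect_fraction Fraction of proteins with a true group effect.
#' @param effect_size Absolute true log2 fold change of affected proteins
#'   (sign randomised per protein).
#' @param mnar_tau,mnar_kappa Midpoint and scale of the logistic
#'   missing-not-at-random dropout: a value at log2 intensity `x` is missing
#'   with probability `plogis((mnar_tau - x) / mnar_kappa)`, so low-abundance
#'   measurements drop out preferentially. `mnar_kappa = 0` is the hard
#'   threshold limit.
#'
#' @return An object of class `synth_config` (a validated named list).
#' @seealso [generate_transcriptome()], [simulate_polysome_experiment()],
#'   [simulate_proteomics()]
#' @examples
#' cfg <- synth_config(seed = 1, n_transcripts = 200)
#' cfg$n_mito
#' @export
synth_config <- function(seed = 1L,
                         n_transcripts = 2000L,
                         n_mito = 13L,
                         n_replicates = 3L,
                         library_size = 5e6,
                         nb_dispersion = 0.05,
                         beta_gc = beta_gc_for_correlation(-0.13, noise_sd = 0.5),
                         beta_mito = -log(2),
                         noise_sd = 0.5,
                         mito_abundance = 8,
                         top_fraction = 0.05,
                         include_subpolysomal = FALSE,
                         n_proteins = 3255L,
                         groups = c(control = 3L, knockdown = 3L),
                         n_histones = 4L,
                         intensity_mean = 25,
                         intensity_sd = 2,
                         resid_sd = 0.25,
                         effect_fraction = 0.05,
                         effect_size = 1,
                         mnar_tau = 22,
                         mnar_kappa = 0.6) {
  cfg <- list(
    seed = seed, n_transcripts = n_transcripts, n_mito = n_mito,
    n_replicates = n_replicates, library_size = library_size,
    nb_dispersion = nb_dispersion, beta_gc = beta_gc, beta_mito = beta_mito,
    noise_sd = noise_sd, mito_abundance = mito_abundance,
    top_fraction = top_fraction, include_subpolysomal = include_subpolysomal,
    n_proteins = n_proteins, groups = groups, n_histones = n_histones,
    intensity_mean = intensity_mean, intensity_sd = intensity_sd,
    resid_sd = resid_sd, effect_fraction = effect_fraction,
    effect_size = effect_size, mnar_tau = mnar_tau, mnar_kappa = mnar_kappa
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  check_count <- function(x, name, min = 0L) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
      abort_config(sprintf("`%s` must be an integer >= %d.", name, min))
    }
  }
  check_count(cfg$seed, "seed")
  check_count(cfg$n_transcripts, "n_transcripts", 1L)
  check_count(cfg$n_mito, "n_mito")
  check_count(cfg$n_replicates, "n_replicates", 2L)
  if (cfg$n_mito > cfg$n_transcripts) {
    abort_config("`n_mito` must not exceed `n_transcripts`.")
  }
  assert_scalar_number(cfg$library_size, "library_size", positive = TRUE)
  assert_scalar_number(cfg$nb_dispersion, "nb_dispersion", positive = TRUE)
  assert_scalar_number(cfg$beta_gc, "beta_gc")
  assert_scalar_number(cfg$beta_mito, "beta_mito")
  assert_scalar_number(cfg$noise_sd, "noise_sd", nonnegative = TRUE)
  assert_scalar_number(cfg$mito_abundance, "mito_abundance", positive = TRUE)
  assert_scalar_number(cfg$top_fraction, "top_fraction", nonnegative = TRUE)
  if (cfg$top_fraction > 1) abort_config("`top_fraction` must be <= 1.")
  check_count(cfg$n_proteins, "n_proteins", 1L)
  if (length(cfg$groups) != 2L || is.null(names(cfg$groups)) ||
      any(!nzchar(names(cfg$groups)))) {
    abort_config("`groups` must be a named vector of two replicate counts.")
  }
  for (g in names(cfg$groups)) check_count(cfg$groups[[g]], sprintf("groups[%s]", g), 2L)
  check_count(cfg$n_histones, "n_histones", 1L)
  if (cfg$n_histones > cfg$n_proteins) {
    abort_config("`n_histones` must not exceed `n_proteins`.")
  }
  assert_scalar_number(cfg$intensity_mean, "intensity_mean")
  assert_scalar_number(cfg$intensity_sd, "intensity_sd", positive = TRUE)
  assert_scalar_number(cfg$resid_sd, "resid_sd", nonnegative = TRUE)
  assert_scalar_number(cfg$effect_fraction, "effect_fraction", nonnegative = TRUE)
  if (cfg$effect_fraction > 1) abort_config("`effect_fraction` must be <= 1.")
  assert_scalar_number(cfg$effect_size, "effect_size")
  assert_scalar_number(cfg$mnar_tau, "mnar_tau")
  assert_scalar_number(cfg$mnar_kappa, "mnar_kappa", nonnegative = TRUE)
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  transcriptome: %d transcripts (%d mitochondrial), seed %d\n",
              x$n_transcripts, x$n_mito, as.integer(x$seed)))
  cat(sprintf("  polysome: %d replicates/condition, library %.3g, phi %.3g\n",
              x$n_replicates, x$library_size, x$nb_dispersion))
  cat(sprintf("  shifts: beta_gc %.4g, beta_mito %.4g, noise_sd %.3g\n",
              x$beta_gc, x$beta_mito, x$noise_sd))
  cat(sprintf("  proteomics: %d proteins, groups %s, effect %.0f%% at %.3g log2\n",
              x$n_proteins,
              paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = "/"),
              100 * x$effect_fraction, x$effect_size))
  invisible(x)
}

#' Logit slope giving a target GC/TE-shift population correlation
#'
#' With 5'UTR GC uniform on `gc_range` and transcript-level shift noise of
#' standard deviation `noise_sd` on the logit scale, the knockdown shift is
#' `delta = beta_gc * (GC - mean(GC)) + noise`, so the population correlation
#' between GC and delta is
#' `rho = beta_gc * sd(GC) / sqrt(beta_gc^2 * var(GC) + noise_sd^2)`.
#' This helper inverts that relation, returning the `beta_gc` that attains a
#' requested `rho`.
#'
#' @param rho Target correlation in (-1, 1), nonzero sign preserved.
#' @param noise_sd Logit-scale shift noise SD.
#' @param gc_range Range of the uniform GC distribution.
#' @return Scalar `beta_gc`.
#' @examples
#' beta_gc_for_correlation(-0.13, noise_sd = 0.5)
#' @export
beta_gc_for_correlation <- function(rho, noise_sd, gc_range = c(0.2, 0.9)) {
  assert_scalar_number(rho, "rho")
  if (abs(rho) >= 1) abort_config("`rho` must lie strictly inside (-1, 1).")
  assert_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  gc_var <- diff(gc_range)^2 / 12
  sign(rho) * sqrt(rho^2 * noise_sd^2 / (gc_var * (1 - rho^2)))
}
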