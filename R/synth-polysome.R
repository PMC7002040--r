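#' Simulate a polysome-profiling count experiment
#'
#' Draws heavy- and light-pool negative-binomial counts for two conditions
#' (control and knockdown) with `cfg$n_replicates` replicates each, following
#' the generative model the TE pipeline assumes. Each transcript has a
#' baseline relative abundance `a_t` (log-normal; mitochondrial transcripts
#' multiplied by `cfg$mito_abundance`) and a control heavy-pool share
#' `p_t = plogis(alpha_t)`. The knockdown applies a logit shift
#' `delta_t = beta_gc * (GC_t - mean(GC)) + beta_mito * is_mito + N(0,
#' noise_sd)`. Since TE equals the heavy/light odds `p/(1-p)` up to a common
#' pool normaliser, the true per-transcript log2 change in TE recorded in the
#' ground-truth table is `delta_t / ln 2`.
#'
#' Expected counts for a sample are `library_size` distributed over
#' transcripts proportional to `a_t * p_t` (heavy) or `a_t * (1 - p_t)`
#' (light); counts are drawn NB with dispersion `phi = cfg$nb_dispersion`
#' (variance `m + phi m^2`).
#'
#' @param ts A `transcript_set` from [generate_transcriptome()].
#' @param cfg A [synth_config()].
#' @return A list of class `polysome_sim` with elements `counts` (tibble:
#'   `transcript_id` + one integer column per sample), `sample_sheet`
#'   (tibble: `sample_id`, `condition`, `replicate`, `pool`) and
#'   `true_effects` (tibble: `transcript_id`, `true_log2_dte`, `affected`).
#' @examples
#' cfg <- synth_config(seed = 1, n_transcripts = 50, library_size = 1e5)
#' sim <- simulate_polysome_experiment(generate_transcriptome(cfg), cfg)
#' names(sim$counts)
#' @export
simulate_polysome_experiment <- function(ts, cfg) {
  cfg <- validate_synth_config(unclass(cfg))
  if (!is.data.frame(ts) || nrow(ts) == 0L) {
    abort_input("`ts` must be a nonempty transcript set.")
  }
  with_seed(as.integer(cfg$seed) + 1L, simulate_polysome_impl(ts, cfg))
}

simulate_polysome_impl <- function(ts, cfg) {
  n <- nrow(ts)
  a <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  a[ts$is_mito] <- a[ts$is_mito] * cfg$mito_abundance
  alpha <- rnorm(n, 0, 0.7)

  systematic <- cfg$beta_gc * (ts$gc - mean(ts$gc)) + cfg$beta_mito * ts$is_mito
  delta <- systematic + rnorm(n, 0, cfg$noise_sd)
  p <- list(control = plogis(alpha), knockdown = plogis(alpha + delta))

  conditions <- c("control", "knockdown")
  pools <- c("heavy", "light", if (cfg$include_subpolysomal) "subpolysomal")
  sheet <- tidyr::crossing(
    condition = conditions,
    replicate = seq_len(cfg$n_replicates),
    pool = pools
  )
  sheet <- mutate(sheet,
                  sample_id = paste(.data$condition, .data$replicate, .data$pool, sep = "_"))
  sheet <- select(sheet, "sample_id", "condition", "replicate", "pool")

  size <- 1 / cfg$nb_dispersion
  draw_sample <- function(condition, pool) {
    w <- switch(pool,
      heavy = a * p[[condition]],
      light = a * (1 - p[[condition]]),
      subpolysomal = a * 0.2
    )
    mu <- cfg$library_size * w / sum(w)
    rnbinom(n, mu = mu, size = size)
  }
  counts <- tibble(transcript_id = ts$transcript_id)
  for (i in seq_len(nrow(sheet))) {
    counts[[sheet$sample_id[i]]] <- draw_sample(sheet$condition[i], sheet$pool[i])
  }

  true_effects <- tibble(
    transcript_id = ts$transcript_id,
    true_log2_dte = delta / log(2),
    affected = systematic != 0
  )
  structure(
    list(counts = counts, sample_sheet = sheet, true_effects = true_effects),
    class = "polysome_sim"
  )
}

#' @export
print.polysome_sim <- function(x, ...) {
  cat(sprintf("<polysome_sim> %d transcripts x %d samples (%d affected)\n",
              nrow(x$counts), nrow(x$sample_sheet), sum(x$true_effects$affected)))
  invisible(x)
}
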