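#' Pool per-fraction polysome counts into heavy / light / subpolysomal
#'
#' Sums gradient-fraction count columns into the three analysis pools by the
#' number of ribosomes loaded: fractions with 1 to `boundary` ribosomes form
#' the light pool, fractions with more than `boundary` ribosomes the heavy
#' pool, and ribosome-free fractions the subpolysomal pool. Column sums are
#' conserved.
#'
#' @param counts Tibble with a `transcript_id` column and one numeric column
#'   per gradient fraction.
#' @param ribosome_map Named numeric vector mapping each fraction column name
#'   to its ribosome count (>= 0).
#' @param boundary Light/heavy boundary; fractions with `ribosomes <=
#'   boundary` (and >= 1) are light (default 3, "three or less ribosomes").
#' @return Tibble with columns `transcript_id`, `light`, `heavy`,
#'   `subpolysomal`.
#' @examples
#' counts <- tibble::tibble(transcript_id = "t1", f1 = 1, f2 = 1, f3 = 1,
#'                          f4 = 1, f5 = 1)
#' pool_fractions(counts, c(f1 = 1, f2 = 2, f3 = 3, f4 = 4, f5 = 5))
#' @export
pool_fractions <- function(counts, ribosome_map, boundary = 3L) {
  if (!is.data.frame(counts) || !"transcript_id" %in% names(counts)) {
    abort_input("`counts` must contain a `transcript_id` column.")
  }
  assert_scalar_number(boundary, "boundary", nonnegative = TRUE)
  frac_cols <- setdiff(names(counts), "transcript_id")
  unknown <- setdiff(frac_cols, names(ribosome_map))
  if (length(unknown) > 0) {
    abort_input(sprintf("Fraction column(s) without a ribosome annotation: %s.",
                        paste(unknown, collapse = ", ")))
  }
  ribo <- ribosome_map[frac_cols]
  if (any(!is.finite(ribo)) || any(ribo < 0)) {
    abort_input("Every fraction must have a finite ribosome count >= 0.")
  }
  pool_of <- ifelse(ribo == 0, "subpolysomal",
                    ifelse(ribo <= boundary, "light", "heavy"))
  sum_pool <- function(pool) {
    cols <- frac_cols[pool_of == pool]
    if (length(cols) == 0) return(rep(0, nrow(counts)))
    rowSums(as.matrix(counts[cols]))
  }
  tibble(
    transcript_id = counts$transcript_id,
    light = sum_pool("light"),
    heavy = sum_pool("heavy"),
    subpolysomal = sum_pool("subpolysomal")
  )
}

validate_sample_sheet <- function(sheet, counts = NULL) {
  required <- c("sample_id", "condition", "replicate", "pool")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    abort_input(sprintf("Sample sheet is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(sheet[c("condition", "replicate", "pool")])) {
    abort_input("Sample sheet has duplicated (condition, replicate, pool) entries.")
  }
  hl <- filter(sheet, .data$pool %in% c("heavy", "light"))
  pairing <- count(hl, .data$condition, .data$replicate)
  bad <- filter(pairing, .data$n != 2L)
  if (nrow(bad) > 0) {
    abort_input(sprintf(
      "Replicate(s) missing a heavy or light sample: %s.",
      paste(sprintf("%s replicate %s", bad$condition, bad$replicate),
            collapse = "; ")
    ))
  }
  if (!is.null(counts)) {
    absent <- setdiff(hl$sample_id, names(counts))
    if (length(absent) > 0) {
      abort_input(sprintf("Count table lacks sample column(s): %s.",
                          paste(absent, collapse = ", ")))
    }
  }
  invisible(sheet)
}

#' Compute per-transcript translational-efficiency scores
#'
#' A transcript's TE in one replicate is its relative abundance in the heavy
#' polysome pool divided by its relative abundance in the light pool, where
#' relative abundance is `(count + pseudocount) / sum(count + pseudocount)`
#' within each sample (so TE is invariant to per-sample library size). The
#' per-condition TE score is the average of the per-replicate ratios, pairing
#' heavy and light samples by replicate index within condition. Transcripts
#' whose total raw count across all heavy/light samples is below `min_total`
#' are dropped and reported via the `dropped` attribute.
#'
#' @param counts Tibble: `transcript_id` + one nonnegative integer column per
#'   sample.
#' @param sheet Sample sheet tibble with columns `sample_id`, `condition`,
#'   `replicate`, `pool` ("heavy"/"light"/"subpolysomal"); every
#'   (condition, replicate) needs both a heavy and a light sample.
#' @param min_total Minimum total raw count for a transcript to be scored
#'   (default 10).
#' @param pseudocount Added to every count before forming within-sample
#'   proportions (default 0.5).
#' @param average `"arithmetic"` (default; the ratios are averaged) or
#'   `"geometric"`.
#' @return Tibble of class `te_result` with columns `transcript_id` and one
#'   `te_<condition>` column per condition; attributes `te_replicates` (long
#'   per-replicate TE tibble) and `dropped` (tibble of filtered transcripts).
#' @examples
#' counts <- tibble::tibble(transcript_id = c("a", "b", "c"),
#'                          c_1_heavy = c(10, 30, 60), c_1_light = c(30, 30, 40))
#' sheet <- tibble::tibble(sample_id = c("c_1_heavy", "c_1_light"),
#'                         condition = "control", replicate = 1L,
#'                         pool = c("heavy", "light"))
#' compute_te(counts, sheet, min_total = 0, pseudocount = 0)
#' @export
compute_te <- function(counts, sheet, min_total = 10L, pseudocount = 0.5,
                       average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  validate_sample_sheet(sheet, counts)
  assert_scalar_number(min_total, "min_total", nonnegative = TRUE)
  assert_scalar_number(pseudocount, "pseudocount", nonnegative = TRUE)
  hl <- filter(sheet, .data$pool %in% c("heavy", "light"))
  mat <- as.matrix(counts[hl$sample_id])
  if (any(!is.finite(mat)) || any(mat < 0)) {
    abort_input("Counts must be finite and nonnegative.")
  }

  keep <- rowSums(mat) >= min_total
  dropped <- tibble(transcript_id = counts$transcript_id[!keep],
                    total_count = rowSums(mat)[!keep])
  mat <- mat[keep, , drop = FALSE]
  ids <- counts$transcript_id[keep]

  rel <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), "/")
  pairs <- pivot_wider(hl, id_cols = c("condition", "replicate"),
                       names_from = "pool", values_from = "sample_id")
  te_rep <- list_rbind(map(seq_len(nrow(pairs)), function(i) {
    tibble(
      transcript_id = ids,
      condition = pairs$condition[i],
      replicate = pairs$replicate[i],
      te = rel[, pairs$heavy[i]] / rel[, pairs$light[i]]
    )
  }))

  agg <- if (average == "arithmetic") {
    summarise(group_by(te_rep, .data$transcript_id, .data$condition),
              te = mean(.data$te), .groups = "drop")
  } else {
    summarise(group_by(te_rep, .data$transcript_id, .data$condition),
              te = exp(mean(log(.data$te))), .groups = "drop")
  }
  out <- pivot_wider(agg, names_from = "condition", values_from = "te",
                     names_prefix = "te_")
  out <- out[match(ids, out$transcript_id), ]
  attr(out, "te_replicates") <- te_rep
  attr(out, "dropped") <- dropped
  if (nrow(dropped) > 0) {
    inform(sprintf("compute_te: dropped %d transcript(s) with total count < %s.",
                   nrow(dropped), format(min_total)))
  }
  class(out) <- c("te_result", class(out))
  out
}

#' Log2 change in TE between conditions
#'
#' Adds `log2_change = log2(TE_knockdown / TE_control)` to a TE table.
#' Transcripts whose TE in either condition is zero or non-finite are flagged
#' in the `excluded` column (with `log2_change = NA`) rather than silently
#' dropped. Swapping the two condition arguments negates the result.
#'
#' @param te A `te_result` tibble (or any tibble with `te_<condition>`
#'   columns and `transcript_id`).
#' @param knockdown,control Condition names (defaults `"knockdown"`,
#'   `"control"`).
#' @return The input tibble with `log2_change` and logical `excluded`
#'   columns appended.
#' @export
change_in_te <- function(te, knockdown = "knockdown", control = "control") {
  kd_col <- paste0("te_", knockdown)
  ct_col <- paste0("te_", control)
  missing <- setdiff(c(kd_col, ct_col), names(te))
  if (length(missing) > 0) {
    abort_input(sprintf("TE table is missing column(s): %s.",
                        paste(missing, collapse = ", ")))
  }
  kd <- te[[kd_col]]
  ct <- te[[ct_col]]
  bad <- !is.finite(kd) | !is.finite(ct) | kd <= 0 | ct <= 0
  lc <- ifelse(bad, NA_real_, log2(kd / ct))
  out <- mutate(te, log2_change = lc, excluded = bad)
  if (any(bad)) {
    inform(sprintf("change_in_te: flagged %d transcript(s) with zero/undefined TE.",
                   sum(bad)))
  }
  out
}

#' Classify TE shifts at a symmetric log2 threshold
#'
#' A transcript is shifted "down" when `log2_change < -threshold` and "up"
#' when `log2_change > threshold` (strict inequalities, so values exactly at
#' the threshold are "none"). With the default threshold of 1 this is the
#' "TE doubled or halved" rule. `NA` values from flagged transcripts
#' propagate as `NA`; non-finite values are an error.
#'
#' @param te Tibble with a `log2_change` column (or a bare numeric vector).
#' @param threshold Positive threshold on the log2 scale (default 1).
#' @return For a tibble input, the tibble with a `shift_class` factor column
#'   (levels down/none/up) and a `class_counts` attribute; for a vector
#'   input, the factor vector with the same attribute.
#' @examples
#' classify_te_shift(c(-2, -1, 0, 1, 2))
#' @export
classify_te_shift <- function(te, threshold = 1) {
  assert_scalar_number(threshold, "threshold", positive = TRUE)
  x <- if (is.data.frame(te)) {
    if (!"log2_change" %in% names(te)) {
      abort_input("`te` must contain a `log2_change` column.")
    }
    te$log2_change
  } else {
    te
  }
  if (any(!is.na(x) & !is.finite(x))) {
    abort_input("`log2_change` contains non-finite values.")
  }
  cls <- factor(
    ifelse(is.na(x), NA_character_,
           ifelse(x < -threshold, "down", ifelse(x > threshold, "up", "none"))),
    levels = c("down", "none", "up")
  )
  counts <- tibble(shift_class = factor(c("down", "none", "up"),
                                        levels = c("down", "none", "up")),
                   n = as.integer(table(cls)))
  if (is.data.frame(te)) {
    out <- mutate(te, shift_class = cls)
    attr(out, "class_counts") <- counts
    out
  } else {
    attr(cls, "class_counts") <- counts
    cls
  }
}

#' Shift-class counts of a classified TE table
#'
#' @param te Output of [classify_te_shift()].
#' @return Tibble with `shift_class` and `n`.
#' @export
shift_class_counts <- function(te) {
  counts <- attr(te, "class_counts")
  if (!is.null(counts)) return(counts)
  if (!"shift_class" %in% names(te)) {
    abort_input("`te` has no shift classification.")
  }
  out <- count(as_tibble(te), .data$shift_class, .drop = FALSE)
  filter(out, !is.na(.data$shift_class))
}
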