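# shared fixture builders (everything generated in code; no stored data)

# matrix -> tidy intensity tibble with protein ids
as_intensity_tbl <- function(mat, ids = sprintf("p%04d", seq_len(nrow(mat)))) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("s", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(mat))
}

two_group_design <- function(k1, k2 = k1, names = c("a", "b")) {
  tibble::tibble(
    sample = c(paste0(names[1], "_", seq_len(k1)), paste0(names[2], "_", seq_len(k2))),
    group = rep(names, c(k1, k2))
  )
}

# null Normal(0,1) intensity tibble for a k1 vs k2 design
null_matrix_tbl <- function(n, k1, k2 = k1) {
  des <- two_group_design(k1, k2)
  mat <- matrix(rnorm(n * (k1 + k2)), n, dimnames = list(NULL, des$sample))
  list(data = as_intensity_tbl(mat), design = des)
}

# minimal paired heavy/light sample sheet
hl_sheet <- function(conditions = c("control", "knockdown"), replicates = 3) {
  sheet <- expand.grid(condition = conditions, replicate = seq_len(replicates),
                       pool = c("heavy", "light"), stringsAsFactors = FALSE)
  sheet$sample_id <- paste(sheet$condition, sheet$replicate, sheet$pool, sep = "_")
  tibble::as_tibble(sheet[c("sample_id", "condition", "replicate", "pool")])
}

# direct-formula Welch t statistic (independent oracle)
welch_t_oracle <- function(mat, g1, g2) {
  apply(mat, 1, function(x) {
    a <- x[g1]; b <- x[g2]
    (mean(b) - mean(a)) / sqrt(var(a) / length(a) + var(b) / length(b))
  })
}

# full-enumeration Mann-Whitney two-sided p (independent oracle)
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  idx <- utils::combn(length(pooled), n_a)
  r_all <- rank(pooled)
  u_obs <- sum(r_all[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  u_null <- apply(idx, 2, function(sel) {
    sum(rank(pooled)[sel]) - n_a * (n_a + 1) / 2
  })
  p_le <- mean(u_null <= u_obs)
  p_ge <- mean(u_null >= u_obs)
  min(2 * min(p_le, p_ge), 1)
}

# hand-written two-transcript GTF/FASTA pair: plus- and minus-strand toys
write_toy_annotation <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  # chrP: exon 1-30, CDS 11-30 (+): UTR = bases 1-10
  # chrM: exon 1-30, CDS 1-20 (-): UTR = revcomp(bases 21-30)
  chr_p <- "ACGTACGTAC GGGATGCCCC TTTTAAAAGG"
  chr_m <- "ACGTACGTAC GGGATGCCCC TTTTAAAAGG"
  chr_p <- gsub(" ", "", chr_p)
  chr_m <- gsub(" ", "", chr_m)
  fasta <- file.path(dir, "toy.fa")
  writeLines(c(">chrP", chr_p, ">chrM", chr_m), fasta)
  gtf <- file.path(dir, "toy.gtf")
  writeLines(c(
    sprintf('chrP\ttoy\texon\t1\t30\t.\t+\t.\tgene_id "gp"; transcript_id "txp";'),
    sprintf('chrP\ttoy\tCDS\t11\t30\t.\t+\t.\tgene_id "gp"; transcript_id "txp";'),
    sprintf('chrM\ttoy\texon\t1\t30\t.\t-\t.\tgene_id "gm"; transcript_id "txm";'),
    sprintf('chrM\ttoy\tCDS\t1\t20\t.\t-\t.\tgene_id "gm"; transcript_id "txm";')
  ), gtf)
  list(gtf = gtf, fasta = fasta, chr_p = chr_p, chr_m = chr_m)
}
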