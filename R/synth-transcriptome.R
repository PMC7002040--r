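#' Generate a synthetic transcriptome with 5'UTR features
#'
#' Builds `n_transcripts` gene models with known 5'UTR sequence, GC content,
#' length, TOP-motif status and mitochondrial flag, each on its own contig of
#' a miniature genome. Exactly `n_mito` transcripts are flagged as
#' mitochondrially encoded. Transcripts have 1-3 exons, random strand, and a
#' coding sequence downstream of the UTR, so the emitted GTF/FASTA pair
#' exercises strand-aware spliced 5'UTR extraction: running
#' [extract_five_prime_utrs()] on [write_transcriptome_fasta()] /
#' [write_transcriptome_gtf()] output reproduces the stored UTR sequences
#' exactly.
#'
#' UTR lengths are drawn log-uniformly on \[10, 2000\] bases and target GC
#' uniformly on (0.2, 0.9); the stored `gc` column is the realised
#' (G+C)/length of the generated sequence. TOP-flagged transcripts start
#' with a cap-adjacent C followed by a 4-15 base pyrimidine run terminated by
#' a purine.
#'
#' @param cfg A [synth_config()].
#' @param sequences Build full gene models (UTR/CDS sequences, exon
#'   structure, contigs) so that FASTA/GTF can be emitted. With `sequences =
#'   FALSE` only the per-transcript features (GC, length, flags) are drawn —
#'   orders of magnitude faster, sufficient for count-level simulation.
#' @return A tibble of class `transcript_set` with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand`, `utr5_seq`, `utr5_length`, `gc`,
#'   `is_mito`, `is_top`, plus (when `sequences = TRUE`) attributes `genome`
#'   (named character vector of contig sequences) and `features` (exon/CDS
#'   coordinate table used by the GTF writer).
#' @examples
#' ts <- generate_transcriptome(synth_config(seed = 1, n_transcripts = 20))
#' sum(ts$is_mito)
#' @export
generate_transcriptome <- function(cfg, sequences = TRUE) {
  cfg <- validate_synth_config(unclass(cfg))
  with_seed(as.integer(cfg$seed), generate_transcriptome_impl(cfg, sequences))
}

generate_transcriptome_impl <- function(cfg, sequences = TRUE) {
  n <- cfg$n_transcripts
  id <- sprintf("tx%05d", seq_len(n))
  is_mito <- seq_len(n) <= cfg$n_mito
  n_top <- round(cfg$top_fraction * n)
  is_top_target <- rep(FALSE, n)
  if (n_top > 0) {
    is_top_target[sample(which(!is_mito), min(n_top, sum(!is_mito)))] <- TRUE
  }

  utr_len <- round(exp(runif(n, log(10), log(2000))))
  gc_target <- runif(n, 0.2, 0.9)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  n_exons <- sample(1:3, n, replace = TRUE)

  if (!sequences) {
    ts <- tibble(
      transcript_id = id,
      gene_id = sprintf("g%05d", seq_len(n)),
      chrom = paste0("chr_", id),
      strand = strand,
      utr5_seq = NA_character_,
      utr5_length = as.integer(utr_len),
      gc = gc_target,
      is_mito = is_mito,
      is_top = is_top_target
    )
    class(ts) <- c("transcript_set", class(ts))
    return(ts)
  }

  models <- pmap(
    list(id, utr_len, gc_target, is_top_target, strand, n_exons),
    build_gene_model
  )

  utr5 <- map_chr(models, "utr5")
  ts <- tibble(
    transcript_id = id,
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = map_chr(models, "chrom"),
    strand = strand,
    utr5_seq = utr5,
    utr5_length = str_length(utr5),
    gc = gc_content(utr5),
    is_mito = is_mito,
    is_top = detect_top_motif(utr5)
  )
  features <- list_rbind(map(models, "features"))
  features$gene_id <- ts$gene_id[match(features$transcript_id, ts$transcript_id)]
  attr(ts, "genome") <- setNames(map_chr(models, "contig_seq"), ts$chrom)
  attr(ts, "features") <- features
  class(ts) <- c("transcript_set", class(ts))
  ts
}

random_dna <- function(len, gc = 0.5) {
  if (len == 0) return("")
  gc_draw <- runif(len) < gc
  base <- character(len)
  base[gc_draw] <- sample(c("G", "C"), sum(gc_draw), replace = TRUE)
  base[!gc_draw] <- sample(c("A", "T"), sum(!gc_draw), replace = TRUE)
  paste(base, collapse = "")
}

top_motif_seq <- function() {
  run <- sample(4:15, 1L)
  paste0("C", paste(sample(c("C", "T"), run, replace = TRUE), collapse = ""),
         sample(c("A", "G"), 1L))
}

# One gene model: UTR5 + CDS + UTR3 split into exons with introns, padded,
# placed on its own contig; minus-strand contigs carry the reverse
# complement so the annotated transcript reads 3'->5' along the contig.
build_gene_model <- function(id, utr_len, gc_target, top, strand, n_exons) {
  utr5 <- if (top) {
    head_seq <- top_motif_seq()
    paste0(head_seq, random_dna(max(utr_len - str_length(head_seq), 0L), gc_target))
  } else {
    random_dna(utr_len, gc_target)
  }
  n_codons <- sample(10:100, 1L)
  cds <- paste0(
    "ATG",
    paste(sample(c("GCT", "GAA", "CTG", "AAG", "TTC", "GGA", "CCT", "ATC"),
                 n_codons, replace = TRUE), collapse = ""),
    "TAA"
  )
  utr3 <- random_dna(sample(20:200, 1L), 0.45)
  tx <- paste0(utr5, cds, utr3)
  tx_len <- str_length(tx)
  cds_tx <- c(str_length(utr5) + 1L, str_length(utr5) + str_length(cds))

  cuts <- if (n_exons > 1) sort(sample(tx_len - 1L, n_exons - 1L)) else integer(0)
  exon_tx_start <- c(1L, cuts + 1L)
  exon_tx_end <- c(cuts, tx_len)

  pad5 <- random_dna(10L, 0.5)
  pad3 <- random_dna(10L, 0.5)
  introns <- map_chr(seq_len(max(n_exons - 1L, 0L)),
                     function(i) random_dna(sample(30:80, 1L), 0.4))

  # sense-strand layout: pad5 | exon1 | intron1 | exon2 | ... | pad3
  sense_start <- integer(n_exons)
  offset <- str_length(pad5)
  pieces <- pad5
  for (i in seq_len(n_exons)) {
    sense_start[i] <- offset + 1L
    exon_seq <- str_sub(tx, exon_tx_start[i], exon_tx_end[i])
    pieces <- c(pieces, exon_seq)
    offset <- offset + str_length(exon_seq)
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      offset <- offset + str_length(introns[i])
    }
  }
  pieces <- c(pieces, pad3)
  sense_seq <- paste(pieces, collapse = "")
  sense_end <- sense_start + (exon_tx_end - exon_tx_start)
  contig_len <- str_length(sense_seq)

  # CDS pieces in transcript coordinates intersected with each exon
  cds_piece <- map(seq_len(n_exons), function(i) {
    s <- max(exon_tx_start[i], cds_tx[1])
    e <- min(exon_tx_end[i], cds_tx[2])
    if (s > e) return(NULL)
    # map transcript coords -> sense coords within exon i
    c(sense_start[i] + (s - exon_tx_start[i]), sense_start[i] + (e - exon_tx_start[i]))
  })
  cds_piece <- cds_piece[!map_lgl(cds_piece, is.null)]

  flip <- function(iv) c(contig_len - iv[2] + 1L, contig_len - iv[1] + 1L)
  exon_iv <- map(seq_len(n_exons), function(i) c(sense_start[i], sense_end[i]))
  if (strand == "-") {
    contig_seq <- revcomp_chr(sense_seq)
    exon_iv <- map(exon_iv, flip)
    cds_piece <- map(cds_piece, flip)
  } else {
    contig_seq <- sense_seq
  }

  chrom <- paste0("chr_", id)
  features <- bind_rows(
    tibble(
      chrom = chrom, feature = "exon",
      start = map_int(exon_iv, function(iv) as.integer(iv[1])),
      end = map_int(exon_iv, function(iv) as.integer(iv[2])),
      strand = strand, transcript_id = id
    ),
    tibble(
      chrom = chrom, feature = "CDS",
      start = map_int(cds_piece, function(iv) as.integer(iv[1])),
      end = map_int(cds_piece, function(iv) as.integer(iv[2])),
      strand = strand, transcript_id = id
    )
  )
  features <- arrange(features, .data$feature, .data$start)
  list(utr5 = utr5, chrom = chrom, contig_seq = contig_seq, features = features)
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Write the synthetic genome / annotation of a transcript set
#'
#' `write_transcriptome_fasta()` writes the per-transcript contigs as a
#' genome FASTA; `write_transcriptome_gtf()` writes the exon and CDS features
#' as a 1-based, inclusive, Ensembl-dialect GTF (`gene_id` and
#' `transcript_id` attributes).
#'
#' @param ts A `transcript_set` from [generate_transcriptome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(ts, path) {
  genome <- attr(ts, "genome")
  if (is.null(genome)) abort_input("`ts` carries no genome attribute.")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname write_transcriptome_fasta
#' @export
write_transcriptome_gtf <- function(ts, path) {
  feat <- attr(ts, "features")
  if (is.null(feat)) abort_input("`ts` carries no features attribute.")
  lines <- sprintf(
    '%s\tpolysomics\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    feat$chrom, feat$feature, feat$start, feat$end, feat$strand,
    feat$gene_id, feat$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}
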