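#' GC content of DNA sequences
#'
#' Fraction (G+C)/(A+C+G+T), case-insensitive; `N` (and any other IUPAC
#' ambiguity code) is excluded from the denominator. Empty or all-ambiguous
#' sequences return `NA`.
#'
#' @param sequence Character vector of DNA sequences (ACGTN + IUPAC codes).
#' @return Numeric vector of GC fractions in \[0, 1\] (`NA` where undefined).
#' @examples
#' gc_content(c("GCGC", "ATAT", "ATGCN"))
#' @export
gc_content <- function(sequence) {
  if (length(sequence) == 0) return(numeric(0))
  seq_up <- str_to_upper(sequence)
  if (any(str_detect(seq_up, "[^ACGTNRYSWKMBDHV]"), na.rm = TRUE)) {
    abort_input("Sequences contain characters outside the IUPAC DNA alphabet.")
  }
  gc <- str_count(seq_up, "[GC]")
  at <- str_count(seq_up, "[AT]")
  denom <- gc + at
  ifelse(denom == 0, NA_real_, gc / denom)
}

#' Detect a 5' terminal oligopyrimidine (TOP) motif
#'
#' A sequence carries a TOP motif when its first base is a cytosine followed
#' by an uninterrupted run of `min_pyr` to `max_pyr` pyrimidines (C/T). The
#' run must terminate (by a purine or the sequence end) within `max_pyr`
#' bases. Empty sequences return `FALSE`.
#'
#' @param sequence Character vector of DNA sequences.
#' @param min_pyr,max_pyr Minimum and maximum pyrimidine run length after the
#'   leading C (defaults 4 and 15).
#' @return Logical vector.
#' @examples
#' detect_top_motif(c("CTTTCAAA", "GTTTTT", ""))
#' @export
detect_top_motif <- function(sequence, min_pyr = 4L, max_pyr = 15L) {
  assert_scalar_number(min_pyr, "min_pyr", positive = TRUE)
  assert_scalar_number(max_pyr, "max_pyr", positive = TRUE)
  if (max_pyr < min_pyr) abort_config("`max_pyr` must be >= `min_pyr`.")
  if (length(sequence) == 0) return(logical(0))
  seq_up <- str_to_upper(sequence)
  run_after_c <- function(s) {
    if (is.na(s) || !nzchar(s) || str_sub(s, 1, 1) != "C") return(-1L)
    rest <- str_sub(s, 2)
    m <- regmatches(rest, regexpr("^[CT]*", rest))
    str_length(m)
  }
  runs <- vapply(seq_up, run_after_c, integer(1), USE.NAMES = FALSE)
  runs >= min_pyr & runs <= max_pyr
}

#' Extract spliced 5'UTR sequences from a GTF and genome FASTA
#'
#' For each transcript with both `exon` and `CDS` features, the 5'UTR is the
#' exonic sequence strictly 5' of the first CDS base, spliced in transcript
#' order; minus-strand transcripts are reverse-complemented. Transcripts
#' without a CDS are skipped and counted (attribute `skipped_no_cds`).
#' Transcripts whose CDS starts at the first transcribed base yield an empty,
#' flagged record.
#'
#' GTF coordinates are 1-based inclusive (Ensembl dialect with
#' `transcript_id` attributes); the genome FASTA is read with Biostrings and
#' indexed by the first word of each header.
#'
#' @param gtf_path Path to the GTF file.
#' @param genome_fasta_path Path to the genome FASTA.
#' @param min_pyr,max_pyr TOP-motif parameters passed to
#'   [detect_top_motif()].
#' @return Tibble with columns `transcript_id`, `sequence`, `length`, `gc`
#'   (`NA` and `gc_defined = FALSE` for empty UTRs) and `has_top`; attribute
#'   `skipped_no_cds` counts transcripts without CDS annotation.
#' @export
extract_five_prime_utrs <- function(gtf_path, genome_fasta_path,
                                    min_pyr = 4L, max_pyr = 15L) {
  if (!file.exists(gtf_path)) abort_input(sprintf("GTF not found: %s", gtf_path))
  if (!file.exists(genome_fasta_path)) {
    abort_input(sprintf("FASTA not found: %s", genome_fasta_path))
  }
  gr <- rtracklayer::import(gtf_path)
  feat <- as_tibble(as.data.frame(gr))
  needed <- c("seqnames", "start", "end", "strand", "type", "transcript_id")
  missing <- setdiff(needed, names(feat))
  if (length(missing) > 0) {
    abort_input(sprintf("GTF lacks field(s): %s.", paste(missing, collapse = ", ")))
  }
  feat <- mutate(feat,
                 seqnames = as.character(.data$seqnames),
                 strand = as.character(.data$strand),
                 type = as.character(.data$type))
  feat <- filter(feat, .data$type %in% c("exon", "CDS"), !is.na(.data$transcript_id))

  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- vapply(str_split(names(genome), "\\s+"), `[[`, character(1), 1)

  tx_ids <- unique(feat$transcript_id)
  has_cds <- unique(feat$transcript_id[feat$type == "CDS"])
  skipped <- setdiff(tx_ids, has_cds)

  records <- map(intersect(tx_ids, has_cds), function(tx) {
    rows <- filter(feat, .data$transcript_id == tx)
    extract_utr_one(tx, rows, genome)
  })
  out <- list_rbind(records)
  out <- mutate(out,
                gc = gc_content(.data$sequence),
                gc_defined = !is.na(.data$gc),
                has_top = detect_top_motif(.data$sequence, min_pyr, max_pyr))
  attr(out, "skipped_no_cds") <- length(skipped)
  if (length(skipped) > 0) {
    inform(sprintf("extract_five_prime_utrs: skipped %d transcript(s) without CDS.",
                   length(skipped)))
  }
  out
}

extract_utr_one <- function(tx, rows, genome) {
  chrom <- unique(rows$seqnames)
  strand <- unique(rows$strand)
  if (length(chrom) != 1L || length(strand) != 1L || !strand %in% c("+", "-")) {
    abort_input(sprintf("Transcript %s has inconsistent chromosome/strand.", tx))
  }
  if (!chrom %in% names(genome)) {
    abort_input(sprintf("Chromosome %s (transcript %s) absent from FASTA.",
                        chrom, tx))
  }
  exons <- arrange(filter(rows, .data$type == "exon"), .data$start)
  cds <- filter(rows, .data$type == "CDS")
  contained <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
  }, logical(1))
  if (!all(contained)) {
    abort_input(sprintf("Malformed annotation: CDS outside exons for transcript %s.",
                        tx))
  }
  if (strand == "+") {
    cut <- min(cds$start)  # first CDS base in transcript orientation
    utr <- mutate(exons, u_start = .data$start,
                  u_end = pmin(.data$end, cut - 1L))
  } else {
    cut <- max(cds$end)
    utr <- mutate(exons, u_start = pmax(.data$start, cut + 1L),
                  u_end = .data$end)
  }
  utr <- filter(utr, .data$u_start <= .data$u_end)
  seqs <- map_chr(seq_len(nrow(utr)), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], utr$u_start[i], utr$u_end[i]))
  })
  spliced <- paste(seqs, collapse = "")  # ascending genomic order
  if (strand == "-") spliced <- if (nzchar(spliced)) revcomp_chr(spliced) else ""
  tibble(transcript_id = tx, sequence = spliced, length = str_length(spliced))
}

#' Write a UTR feature table as TSV
#'
#' GC is written as a percentage (`gc_percent`), matching how the feature is
#' usually reported; all other columns are written as-is.
#'
#' @param utrs Output of [extract_five_prime_utrs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_utr_features <- function(utrs, path) {
  out <- mutate(utrs, gc_percent = 100 * .data$gc)
  out <- select(out, -"gc")
  write_tsv(out, path)
  invisible(path)
}
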