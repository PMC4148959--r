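## I/O for the standard formats the pipeline touches. Internal coordinates
## are 0-based half-open everywhere; SAM/BED conversion happens only here.

#' Read paired FASTQ files into a pair table
#'
#' Mates must appear in the same order in both files. Qualities are kept as
#' Phred+33 strings (decode with [phred_to_int()]).
#'
#' @param path1,path2 FASTQ files for mate 1 and mate 2.
#' @param sample_id,population sample provenance attached to every pair.
#' @return `data.table` with columns `pair_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`, `sample_id`, `population`.
#' @export
read_fastq_pairs <- function(path1, path2, sample_id, population) {
  r1 <- read_fastq_one(path1)
  r2 <- read_fastq_one(path2)
  if (nrow(r1) != nrow(r2)) {
    stop(sprintf("mate files differ in record count (%d vs %d); first missing record is %d",
                 nrow(r1), nrow(r2), min(nrow(r1), nrow(r2)) + 1L))
  }
  data.table(pair_id = sub("/[12]$", "", r1$id),
             seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual,
             sample_id = sample_id, population = population)
}

read_fastq_one <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a pair table back to two FASTQ files
#'
#' Inverse of [read_fastq_pairs()] up to the `/1`,`/2` mate suffix.
#'
#' @param pairs pair table as returned by [read_fastq_pairs()].
#' @param path1,path2 output FASTQ paths.
#' @return invisibly, the number of pairs written.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  write_fastq_one(pairs$pair_id, pairs$seq1, pairs$qual1, path1, "/1")
  write_fastq_one(pairs$pair_id, pairs$seq2, pairs$qual2, path2, "/2")
  invisible(nrow(pairs))
}

write_fastq_one <- function(ids, seqs, quals, path, suffix) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0(ids, suffix)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
}

#' Read / write FASTA
#'
#' `write_fasta` wraps sequence lines at 60 columns; ids must be unique.
#'
#' @param records named character vector, or `data.frame`/`data.table` with
#'   columns `id` and `seq`.
#' @param path file path.
#' @return `read_fasta`: `data.table(id, seq)`.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    ids <- names(records); seqs <- unname(records)
  } else {
    ids <- records$id; seqs <- records$seq
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.table(id = names(x), seq = as.character(x))
}

#' Read name-grouped SAM/BAM alignments
#'
#' Primary records only; SAM's 1-based leftmost positions become 0-based.
#' Returns one row per pair with both mates' fields; unmapped mates have
#' `NA` chrom/pos/strand.
#'
#' @param path a `.sam` (text) or `.bam` file with both mates adjacent.
#' @return `data.table` with `pair_id` and, for `m` in `m1`,`m2`:
#'   `<m>_mapped`, `<m>_chrom`, `<m>_pos` (0-based), `<m>_strand`, `<m>_mapq`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  if (length(hdr$targets) == 0L) {
    stop("SAM/BAM header has no sequence dictionary (@SQ lines): ", path)
  }
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "mapq"), flag = flags)
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  dt <- data.table(pair_id = b$qname,
                   flag = b$flag,
                   chrom = as.character(b$rname),
                   pos = as.integer(b$pos) - 1L,
                   strand = as.character(b$strand),
                   mapq = as.integer(b$mapq))
  dt[, mapped := bitwAnd(flag, 4L) == 0L]
  dt[, mate_index := fifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L)]
  dt[mapped == FALSE, c("chrom", "pos", "strand", "mapq") :=
       .(NA_character_, NA_integer_, NA_character_, NA_integer_)]
  counts <- dt[, .N, by = pair_id]
  if (any(counts$N != 2L)) {
    bad <- counts$pair_id[counts$N != 2L][1]
    stop("pair without exactly two primary records: ", bad)
  }
  m1 <- dt[mate_index == 1L]
  m2 <- dt[mate_index == 2L]
  setnames(m1, c("mapped", "chrom", "pos", "strand", "mapq"),
           paste0("m1_", c("mapped", "chrom", "pos", "strand", "mapq")))
  setnames(m2, c("mapped", "chrom", "pos", "strand", "mapq"),
           paste0("m2_", c("mapped", "chrom", "pos", "strand", "mapq")))
  out <- merge(m1[, !c("flag", "mate_index")], m2[, !c("flag", "mate_index")],
               by = "pair_id", sort = FALSE)
  out[]
}

#' Write alignments as SAM text
#'
#' Inverse of [read_alignments()] for the fields the pipeline uses
#' (internal 0-based positions become SAM 1-based). Sequences/qualities are
#' taken from the pair table when supplied, else written as `*`.
#'
#' @param aln pair-level alignment table (see [read_alignments()]).
#' @param ref_lengths named integer vector of chromosome lengths (for `@SQ`).
#' @param path output `.sam` path.
#' @param pairs optional pair table providing `seq1/qual1/seq2/qual2`.
#' @export
write_sam <- function(aln, ref_lengths, path, pairs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:queryname", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                     as.integer(ref_lengths)), con)
  seqs1 <- quals1 <- seqs2 <- quals2 <- NULL
  if (!is.null(pairs)) {
    idx <- match(aln$pair_id, pairs$pair_id)
    seqs1 <- pairs$seq1[idx]; quals1 <- pairs$qual1[idx]
    seqs2 <- pairs$seq2[idx]; quals2 <- pairs$qual2[idx]
  }
  fmt_mate <- function(which_mate, m_mapped, m_chrom, m_pos, m_strand, m_mapq,
                       o_mapped, seqs, quals) {
    flag <- 1L +                       # paired
      ifelse(m_mapped, 0L, 4L) +
      ifelse(o_mapped, 0L, 8L) +
      ifelse(m_mapped & m_strand == "-", 16L, 0L) +
      if (which_mate == 1L) 64L else 128L
    # mate-reverse bit intentionally omitted: consumers here use only the
    # per-record strand
    sq <- if (is.null(seqs)) "*" else seqs
    ql <- if (is.null(quals)) "*" else quals
    cigar <- ifelse(m_mapped, paste0(nchar(if (is.null(seqs)) "" else seqs), "M"), "*")
    cigar[!m_mapped | cigar == "M"] <- "*"
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            aln$pair_id, flag,
            ifelse(m_mapped, m_chrom, "*"),
            ifelse(m_mapped, m_pos + 1L, 0L),
            ifelse(m_mapped, m_mapq, 0L),
            cigar, sq, ql)
  }
  l1 <- fmt_mate(1L, aln$m1_mapped, aln$m1_chrom, aln$m1_pos, aln$m1_strand,
                 aln$m1_mapq, aln$m2_mapped, seqs1, quals1)
  l2 <- fmt_mate(2L, aln$m2_mapped, aln$m2_chrom, aln$m2_pos, aln$m2_strand,
                 aln$m2_mapq, aln$m1_mapped, seqs2, quals2)
  writeLines(as.vector(rbind(l1, l2)), con)
  invisible(path)
}

#' Read a typed BED annotation
#'
#' Expects at least 6 columns (chrom, start, end, name, score, strand) plus a
#' 7th feature-type column in `{gene, exon, utr, intron}`. BED is 0-based
#' half-open on disk, matching the internal convention.
#'
#' @param path BED file.
#' @return `GRanges` with metadata columns `name` and `type`.
#' @export
read_bed_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 7L) stop("BED line ", i, ": expected >= 7 columns, got ", length(f))
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      stop("BED line ", i, ": non-integer start/end")
    }
    if (!f[7] %in% c("gene", "exon", "utr", "intron")) {
      stop("BED line ", i, ": unknown feature type '", f[7], "'")
    }
  }
  m <- do.call(rbind, fields)
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = as.integer(m[, 2]) + 1L,
                              end = as.integer(m[, 3])),
    strand = ifelse(m[, 6] %in% c("+", "-"), m[, 6], "*"),
    name = m[, 4], type = m[, 7])
}
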