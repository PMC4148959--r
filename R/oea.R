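## Classification of aligned pairs and extraction/pooling of one-end-anchored
## (OEA) records. "Uniquely mapped" is operationalised as MAPQ >= min_mapq.

#' Pair classes
#'
#' Every aligned pair receives exactly one of: `CONCORDANT` (both mates
#' effectively mapped, FR orientation, insert within range),
#' `DISCORDANT_BOTH_MAPPED`, `OEA` (exactly one mate uniquely mapped, the
#' other unmapped), `FULL_ORPHAN` (neither mate effectively mapped; a pair
#' whose only mapped mate falls below `min_mapq` is demoted here).
#'
#' @name pair_classes
NULL

#' Classify aligned pairs
#'
#' @param aln pair-level alignment table from [read_alignments()] or the
#'   simulator (columns `m1_mapped`..`m2_mapq`).
#' @param min_mapq minimum MAPQ for a mate to count as uniquely mapped.
#' @param insert_mean,insert_sd expected insert size; when `NULL` they are
#'   estimated from the both-mapped FR pairs (median and MAD). Pairs within
#'   `mean +/- 4 sd` in FR orientation are concordant.
#' @return character vector of classes, one per row of `aln`.
#' @export
classify_pairs <- function(aln, min_mapq = 20L, insert_mean = NULL,
                           insert_sd = NULL) {
  e1 <- aln$m1_mapped & !is.na(aln$m1_mapq) & aln$m1_mapq >= min_mapq
  e2 <- aln$m2_mapped & !is.na(aln$m2_mapq) & aln$m2_mapq >= min_mapq
  same_chrom <- !is.na(aln$m1_chrom) & !is.na(aln$m2_chrom) &
    aln$m1_chrom == aln$m2_chrom
  # FR: forward mate leftmost, mates on opposite strands
  fr <- same_chrom & !is.na(aln$m1_strand) & !is.na(aln$m2_strand) &
    aln$m1_strand != aln$m2_strand &
    fifelse(aln$m1_strand == "+",
            aln$m1_pos <= aln$m2_pos, aln$m2_pos <= aln$m1_pos)
  isize <- abs(fifelse(aln$m1_strand == "+",
                       aln$m2_pos - aln$m1_pos, aln$m1_pos - aln$m2_pos))
  both <- e1 & e2
  if (is.null(insert_mean)) {
    cand <- both & fr
    if (any(cand, na.rm = TRUE)) {
      insert_mean <- stats::median(isize[cand], na.rm = TRUE)
      if (is.null(insert_sd))
        insert_sd <- max(stats::mad(isize[cand], na.rm = TRUE), 1)
    } else {
      insert_mean <- Inf; insert_sd <- Inf
    }
  }
  if (is.null(insert_sd)) insert_sd <- insert_mean / 10
  in_range <- !is.na(isize) & abs(isize - insert_mean) <= 4 * insert_sd
  cls <- rep("FULL_ORPHAN", nrow(aln))
  cls[both & fr & in_range] <- "CONCORDANT"
  cls[both & !(fr & in_range)] <- "DISCORDANT_BOTH_MAPPED"
  oea <- (e1 & !aln$m2_mapped) | (e2 & !aln$m1_mapped)
  cls[oea] <- "OEA"
  # one unique + one mapped-but-low-MAPQ: both physically mapped
  cls[(e1 & aln$m2_mapped & !e2) | (e2 & aln$m1_mapped & !e1)] <-
    "DISCORDANT_BOTH_MAPPED"
  cls
}

#' Classify a single pair
#'
#' Scalar convenience over [classify_pairs()]; `a1`, `a2` are lists with
#' `mapped`, `chrom`, `pos`, `strand`, `mapq` and `mate_index`.
#'
#' @param a1,a2 alignment records for mates 1 and 2.
#' @inheritParams classify_pairs
#' @return one of the [pair_classes].
#' @export
classify_pair <- function(a1, a2, min_mapq = 20L, insert_mean = 300,
                          insert_sd = 30) {
  if (!is.null(a1$mate_index) && !is.null(a2$mate_index) &&
      a1$mate_index == a2$mate_index) {
    stop("both records claim mate_index ", a1$mate_index)
  }
  g <- function(a, f, cast) if (is.null(a[[f]]) || is.na(a[[f]] %||% NA)) cast(NA) else cast(a[[f]])
  aln <- data.table(
    m1_mapped = isTRUE(a1$mapped), m1_chrom = g(a1, "chrom", as.character),
    m1_pos = g(a1, "pos", as.integer), m1_strand = g(a1, "strand", as.character),
    m1_mapq = g(a1, "mapq", as.integer),
    m2_mapped = isTRUE(a2$mapped), m2_chrom = g(a2, "chrom", as.character),
    m2_pos = g(a2, "pos", as.integer), m2_strand = g(a2, "strand", as.character),
    m2_mapq = g(a2, "mapq", as.integer))
  classify_pairs(aln, min_mapq, insert_mean, insert_sd)
}

#' Extract OEA records from a classified sample
#'
#' One record per OEA pair: the orphan's sequence/quality plus the anchor's
#' chromosome, 0-based position, strand, and the pair's sample provenance.
#'
#' @param pairs pair table (sequences + provenance).
#' @param aln matching alignment table (same `pair_id`s).
#' @param classes output of [classify_pairs()] for `aln`.
#' @return `data.table` of OEA records (`orphan_seq`, `orphan_qual`,
#'   `anchor_chrom`, `anchor_pos`, `anchor_strand`, `anchor_end`,
#'   `sample_id`, `population`, `pair_id`).
#' @export
extract_oea <- function(pairs, aln, classes) {
  idx <- which(classes == "OEA")
  if (!length(idx)) {
    return(data.table(orphan_seq = character(0), orphan_qual = character(0),
                      anchor_chrom = character(0), anchor_pos = integer(0),
                      anchor_strand = character(0), anchor_end = integer(0),
                      sample_id = character(0), population = character(0),
                      pair_id = character(0)))
  }
  a <- aln[idx]
  anchor_is_1 <- a$m1_mapped
  p <- pairs[match(a$pair_id, pairs$pair_id)]
  dt <- data.table(
    orphan_seq = fifelse(anchor_is_1, p$seq2, p$seq1),
    orphan_qual = fifelse(anchor_is_1, p$qual2, p$qual1),
    anchor_chrom = fifelse(anchor_is_1, a$m1_chrom, a$m2_chrom),
    anchor_pos = fifelse(anchor_is_1, a$m1_pos, a$m2_pos),
    anchor_strand = fifelse(anchor_is_1, a$m1_strand, a$m2_strand),
    sample_id = p$sample_id, population = p$population, pair_id = a$pair_id)
  read_len <- fifelse(anchor_is_1, nchar(p$seq1), nchar(p$seq2))
  dt[, anchor_end := anchor_pos + read_len]
  setcolorder(dt, c("orphan_seq", "orphan_qual", "anchor_chrom", "anchor_pos",
                    "anchor_strand", "anchor_end", "sample_id", "population",
                    "pair_id"))
  dt[]
}

#' Pool OEA records across samples by anchor chromosome
#'
#' @param oea_list list of per-sample OEA tables from [extract_oea()].
#' @param ref_chroms optional character vector of valid chromosome names;
#'   an anchor on an unknown chromosome is an error.
#' @return named list of `data.table`s, one per anchor chromosome, each
#'   sorted by `anchor_pos`.
#' @export
pool_oea <- function(oea_list, ref_chroms = NULL) {
  pooled <- rbindlist(oea_list, use.names = TRUE)
  if (!is.null(ref_chroms)) {
    bad <- setdiff(unique(pooled$anchor_chrom), ref_chroms)
    if (length(bad)) stop("anchor chromosome(s) absent from reference: ",
                          paste(bad, collapse = ", "))
  }
  if (!nrow(pooled)) return(list())
  setorder(pooled, anchor_chrom, anchor_pos, pair_id)
  split(pooled, by = "anchor_chrom", sorted = TRUE)
}

#' Orient an orphan read onto the inserted sequence's forward sense
#'
#' An orphan whose anchor maps to the forward strand lies downstream of the
#' anchor and was sequenced on the reverse strand of the insertion, so it is
#' reverse-complemented; an orphan with a reverse-strand anchor is returned
#' as stored.
#'
#' @param orphan_seq orphan sequence(s).
#' @param anchor_strand `"+"` or `"-"`, recycled.
#' @return oriented sequence(s).
#' @export
orient_orphan <- function(orphan_seq, anchor_strand) {
  flip <- anchor_strand == "+"
  out <- orphan_seq
  if (any(flip)) out[flip] <- revcomp(orphan_seq[flip])
  out
}
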