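## Breakpoint estimation from stranded anchor clusters, post-hoc carrier
## calling by re-mapping orphan reads onto the final sequences, gene-context
## classification, and evidence-read scoring.

#' Carrier-calling configuration
#'
#' @param min_reads_carrier minimum orphan reads a sample must contribute to
#'   count as a carrier (3, the convention for shallow ~4x data).
#' @param min_pop_freq minimum overall carrier fraction for a call to be
#'   kept ("common": at least 1% of the cohort).
#' @param seed_len exact-seed length for read-to-sequence mapping.
#' @param map_identity minimum identity of the ungapped extension.
#' @return a `carrier_config` list.
#' @export
carrier_config <- function(min_reads_carrier = 3L, min_pop_freq = 0.01,
                           seed_len = 15L, map_identity = 0.95) {
  stopifnot(min_reads_carrier >= 1L)
  structure(list(min_reads_carrier = as.integer(min_reads_carrier),
                 min_pop_freq = min_pop_freq,
                 seed_len = as.integer(seed_len),
                 map_identity = map_identity),
            class = "carrier_config")
}

#' Estimate the insertion breakpoint from an anchor cluster
#'
#' Forward-strand anchors flank the insertion on the left, reverse-strand
#' anchors on the right. With both strands present and reconcilable (left
#' edge at most 500 nt past the right edge), the breakpoint is the point
#' midway between the rightmost forward-anchor end `L` and the leftmost
#' reverse-anchor start `R`; otherwise the cluster span is reported as an
#' interval (~1 kb effective resolution).
#'
#' @param cand candidate with `anchor_cluster` and `anchor_records` set.
#' @param tol reconciliation tolerance (nt) between the two flanks.
#' @return list `(chrom, start, end)`, 0-based half-open; `start == end` is
#'   a point estimate.
#' @export
estimate_breakpoint <- function(cand, tol = 500L) {
  cl <- cand$anchor_cluster
  if (is.null(cl) || cl$in_window_count == 0L) stop("empty anchor cluster")
  ar <- cand$anchor_records[anchor_chrom == cl$chrom &
                              anchor_pos >= cl$window_start &
                              anchor_pos < cl$window_end]
  plus <- ar[anchor_strand == "+"]
  minus <- ar[anchor_strand == "-"]
  if (nrow(plus) && nrow(minus)) {
    L <- max(plus$anchor_end)
    R <- min(minus$anchor_pos)
    if (L <= R + tol) {
      bp <- as.integer(floor((L + R) / 2))
      bp <- min(max(bp, cl$window_start), cl$window_end)  # stay in cluster
      return(list(chrom = cl$chrom, start = bp, end = bp))
    }
  }
  span_start <- min(ar$anchor_pos)
  span_end <- max(ar$anchor_end)
  list(chrom = cl$chrom, start = span_start, end = span_end)
}

## index the target's seed k-mers once: data.table(kmer, offset, strand)
build_seed_index <- function(target, seed_len) {
  fw <- seq_kmers(target, seed_len)
  rv <- seq_kmers(revcomp(target), seed_len)
  rbindlist(list(
    data.table(kmer = fw, offset = seq_along(fw), strand = "+"),
    data.table(kmer = rv, offset = seq_along(rv), strand = "-")))
}

#' Map reads onto a micSeq by exact seed plus ungapped extension
#'
#' A read hits iff it shares an exact `seed_len`-mer with the sequence on
#' either strand and the implied ungapped placement reaches
#' `cfg$map_identity` identity over the read/target overlap.
#'
#' @param reads character vector of reads.
#' @param micseq_seq target sequence (`>= cfg$seed_len` nt).
#' @param cfg a [carrier_config()].
#' @return list with `hit` (logical per read) and `coverage` (integer
#'   per-base vector over the target).
#' @export
map_reads_to_micseq <- function(reads, micseq_seq, cfg = carrier_config()) {
  L <- nchar(micseq_seq)
  stopifnot(L >= cfg$seed_len)
  idx <- build_seed_index(micseq_seq, cfg$seed_len)
  hit <- logical(length(reads))
  coverage <- integer(L)
  rk <- seqs_kmers_dt(reads, cfg$seed_len)
  if (!nrow(rk)) return(list(hit = hit, coverage = coverage))
  m <- merge(rk, idx, by = "kmer", allow.cartesian = TRUE)
  if (!nrow(m)) return(list(hit = hit, coverage = coverage))
  placements <- unique(m[, .(read_idx, strand,
                             tstart = offset - off + 1L)])
  setorder(placements, read_idx, strand, tstart)
  rc_cache <- character(length(reads))
  for (pi in seq_len(nrow(placements))) {
    i <- placements$read_idx[pi]
    if (hit[i]) next
    rd <- reads[i]
    rl <- nchar(rd)
    strand <- placements$strand[pi]
    ts <- placements$tstart[pi]
    # overlap of [ts, ts+rl) with [1, L] in forward-target coordinates
    tcoord <- if (strand == "+") ts else L - (ts + rl - 1L) + 1L
    rstart <- max(1L, 1L - (tcoord - 1L))
    tstart <- max(1L, tcoord)
    olen <- min(rl - rstart + 1L, L - tstart + 1L)
    if (olen < cfg$seed_len) next
    if (strand == "-") {
      if (rc_cache[i] == "") rc_cache[i] <- revcomp(rd)
      rd <- rc_cache[i]
    }
    rpart <- substring(rd, rstart, rstart + olen - 1L)
    tpart <- substring(micseq_seq, tstart, tstart + olen - 1L)
    idn <- mean(utf8ToInt(rpart) == utf8ToInt(tpart))
    if (idn >= cfg$map_identity) {
      hit[i] <- TRUE
      span <- tstart:(tstart + olen - 1L)
      coverage[span] <- coverage[span] + 1L
    }
  }
  list(hit = hit, coverage = coverage)
}

#' Call per-sample carriers and population frequencies
#'
#' A sample carries the micSeq iff at least `cfg$min_reads_carrier` of its
#' orphan reads map to it; per-population frequency is the carrier fraction
#' among that population's samples.
#'
#' @param micseq_seq final micSeq sequence.
#' @param orphans per-sample orphan reads: `data.table(orphan_seq,
#'   anchor_strand, sample_id, population)` (all samples pooled).
#' @param samples cohort roster `data.table(sample_id, population)` - gives
#'   denominators including samples contributing no orphans.
#' @param cfg a [carrier_config()].
#' @return list with `carriers` (`data.table(sample_id, population,
#'   n_reads, carrier)`), `pop_freq` (named numeric), `overall_freq`, and
#'   `kept` (`overall_freq >= cfg$min_pop_freq`).
#' @export
call_carriers <- function(micseq_seq, orphans, samples,
                          cfg = carrier_config()) {
  counts <- data.table(sample_id = samples$sample_id,
                       population = samples$population)
  if (nrow(orphans)) {
    oriented <- orient_orphan(orphans$orphan_seq, orphans$anchor_strand)
    mp <- map_reads_to_micseq(oriented, micseq_seq, cfg)
    per <- data.table(sample_id = orphans$sample_id,
                      hit = mp$hit)[, .(n = sum(hit)), by = sample_id]
    counts[, n_reads := per$n[match(sample_id, per$sample_id)]]
  } else counts[, n_reads := 0L]
  counts[is.na(n_reads), n_reads := 0L]
  counts[, carrier := n_reads >= cfg$min_reads_carrier]
  pf <- counts[, .(freq = mean(carrier)), by = population]
  pop_freq <- setNames(pf$freq, pf$population)
  overall <- mean(counts$carrier)
  list(carriers = counts[], pop_freq = pop_freq, overall_freq = overall,
       kept = overall >= cfg$min_pop_freq)
}

#' Classify the gene context of a breakpoint
#'
#' The most specific overlapping feature wins (`exon` > `utr` > `intron`);
#' a breakpoint within `flank` nt of a gene boundary but outside every gene
#' is `flank_5kb`; otherwise `intergenic`.
#'
#' @param breakpoint list `(chrom, start, end)`, 0-based half-open.
#' @param annotation `GRanges` from [read_bed_annotation()] (feature types
#'   `gene`, `exon`, `utr`, `intron`).
#' @param flank flank width in nt.
#' @return one of `"exon"`, `"utr"`, `"intron"`, `"flank_5kb"`,
#'   `"intergenic"`.
#' @export
classify_gene_context <- function(breakpoint, annotation, flank = 5000L) {
  bp <- GenomicRanges::GRanges(
    breakpoint$chrom,
    IRanges::IRanges(start = breakpoint$start + 1L,
                     end = max(breakpoint$end, breakpoint$start + 1L)))
  ov <- annotation[S4Vectors::queryHits(
    GenomicRanges::findOverlaps(annotation, bp, ignore.strand = TRUE))]
  types <- unique(ov$type)
  for (t in c("exon", "utr", "intron")) if (t %in% types) return(t)
  if ("gene" %in% types) return("intron")  # inside a gene, no sub-feature
  genes <- annotation[annotation$type == "gene"]
  if (length(genes)) {
    near <- GenomicRanges::findOverlaps(
      genes, bp, maxgap = flank, ignore.strand = TRUE)
    if (length(near)) return("flank_5kb")
  }
  "intergenic"
}

#' Count evidence reads (expression / TF-binding support)
#'
#' Maps each dataset's reads onto each micSeq and reports the count; a
#' micSeq is flagged expressed/bound when any treatment dataset exceeds
#' `expressed_threshold` reads. Control datasets, when given, contribute a
#' side-by-side mean.
#'
#' @param micseqs named character vector of final micSeq sequences.
#' @param evidence_reads named list of read vectors (treatment datasets).
#' @param control_reads optional named list of read vectors.
#' @param expressed_threshold flag threshold (reads).
#' @param cfg a [carrier_config()] (mapping parameters).
#' @return `data.table(micseq_id, dataset, role, n_mapped)` with attributes
#'   `flags` (named logical) and `summary` (`data.table(micseq_id,
#'   treatment_mean, control_mean)`).
#' @export
score_evidence <- function(micseqs, evidence_reads, control_reads = NULL,
                           expressed_threshold = 100L,
                           cfg = carrier_config()) {
  count_one <- function(reads, sq) sum(map_reads_to_micseq(reads, sq, cfg)$hit)
  rows <- list()
  for (mid in names(micseqs)) {
    for (ds in names(evidence_reads)) {
      rows[[length(rows) + 1L]] <- data.table(
        micseq_id = mid, dataset = ds, role = "treatment",
        n_mapped = count_one(evidence_reads[[ds]], micseqs[[mid]]))
    }
    for (ds in names(control_reads %||% list())) {
      rows[[length(rows) + 1L]] <- data.table(
        micseq_id = mid, dataset = ds, role = "control",
        n_mapped = count_one(control_reads[[ds]], micseqs[[mid]]))
    }
  }
  out <- rbindlist(rows)
  flags <- vapply(names(micseqs), function(mid)
    any(out[micseq_id == mid & role == "treatment", n_mapped] >
          expressed_threshold), logical(1))
  smry <- out[, .(treatment_mean = mean(n_mapped[role == "treatment"]),
                  control_mean = if (any(role == "control"))
                    mean(n_mapped[role == "control"]) else NA_real_),
              by = micseq_id]
  setattr(out, "flags", flags)
  setattr(out, "summary", smry)
  out[]
}
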