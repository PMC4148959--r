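## Candidate collection and false-candidate removal. Per-k assemblies are
## merged through a sequence-similarity graph (edge iff e-value < 1e-10);
## each connected component contributes its longest member as one candidate.
## Candidates then pass an order-fixed filter chain: known/low-complexity ->
## anchor cluster -> local reference -> contaminant, with an append-only
## audit trail.

#' Filter configuration
#'
#' @param evalue_edge similarity-graph edge threshold.
#' @param ref_identity,ref_cov_frac a candidate counts as "alignable" to a
#'   screen sequence when identity `>= ref_identity` over `>= ref_cov_frac`
#'   of its length.
#' @param dust_frac fail the low-complexity screen when more than this
#'   fraction of the candidate is DUST-masked.
#' @param cluster_window anchor-cluster window width (nt).
#' @param cluster_min_frac minimum fraction of anchors inside the best
#'   window.
#' @param local_ref_pad padding around the anchor cluster for the
#'   local-reference screen (nt).
#' @return a `filter_config` list.
#' @export
filter_config <- function(evalue_edge = 1e-10, ref_identity = 0.95,
                          ref_cov_frac = 0.9, dust_frac = 0.8,
                          cluster_window = 4000L, cluster_min_frac = 0.5,
                          local_ref_pad = 1000L) {
  stopifnot(cluster_window > 0, ref_identity >= 0, ref_identity <= 1,
            ref_cov_frac >= 0, ref_cov_frac <= 1,
            cluster_min_frac >= 0, cluster_min_frac <= 1)
  structure(list(evalue_edge = evalue_edge, ref_identity = ref_identity,
                 ref_cov_frac = ref_cov_frac, dust_frac = dust_frac,
                 cluster_window = as.integer(cluster_window),
                 cluster_min_frac = cluster_min_frac,
                 local_ref_pad = as.integer(local_ref_pad)),
            class = "filter_config")
}

#' Connected components of the contig similarity graph
#'
#' Contigs (from one anchor chromosome) are nodes; an edge joins two contigs
#' whose best local alignment (either strand) has e-value below
#' `cfg$evalue_edge`. Singletons - sequences assembled at a single k with no
#' similar partner - are retained as their own components.
#'
#' @param contigs contig table from [assemble_multik()].
#' @param cfg a [filter_config()].
#' @return integer vector of component ids, parallel to `contigs` rows.
#' @export
build_similarity_graph <- function(contigs, cfg = filter_config()) {
  n <- nrow(contigs)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  scoring <- default_scoring()
  sm <- scoring_matrix(scoring)
  kp <- ka_params(scoring$match, scoring$mismatch)
  seqs <- contigs$seq
  rcs <- revcomp(seqs)
  lens <- nchar(seqs)
  edges <- list()
  for (j in seq(2L, n)) {
    prev <- seq_len(j - 1L)
    pat <- Biostrings::DNAStringSet(c(seqs[prev], rcs[prev]))
    sc <- Biostrings::pairwiseAlignment(
      pat, seqs[j], type = "local", substitutionMatrix = sm,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext,
      scoreOnly = TRUE)
    s <- pmax(sc[prev], sc[prev + (j - 1L)])
    ev <- kp$K * lens[prev] * lens[j] * exp(-kp$lambda * s)
    hit <- which(ev < cfg$evalue_edge)
    for (i in hit) edges[[length(edges) + 1L]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, unlist(edges))
  }
  as.integer(igraph::components(g)$membership)
}

#' Pick one representative candidate per component
#'
#' The longest member represents its component; ties go to the higher mean
#' k-mer coverage, then the lexicographically smaller sequence. The
#' candidate carries the union of its members' supporting OEA records.
#'
#' @param contigs contig table (with `read_support` attribute).
#' @param membership component ids from [build_similarity_graph()].
#' @return list of candidate objects (`id`, `seq`, `len`,
#'   `member_contigs`, `anchor_records`, `filter_trail`). Anchor records are
#'   attached later (see [merge_candidates()]).
#' @export
pick_representatives <- function(contigs, membership) {
  if (!nrow(contigs)) return(list())
  lapply(sort(unique(membership)), function(m) {
    mem <- contigs[which(membership == m)]
    setorder(mem, -len, -mean_kmer_cov, seq)
    rep_row <- mem[1]
    structure(list(id = rep_row$contig_id, seq = rep_row$seq,
                   len = rep_row$len, k = rep_row$k,
                   mean_kmer_cov = rep_row$mean_kmer_cov,
                   member_contigs = mem$contig_id,
                   anchor_records = NULL,
                   anchor_cluster = NULL,
                   filter_trail = list()),
              class = "candidate_micseq")
  })
}

#' @export
print.candidate_micseq <- function(x, ...) {
  cat(sprintf("<candidate %s> %d nt, k=%s, cov=%.1f, members=%d, filters=%d\n",
              x$id, x$len, x$k, x$mean_kmer_cov, length(x$member_contigs),
              length(x$filter_trail)))
  invisible(x)
}

add_trail <- function(cand, filter_name, pass, detail = "") {
  cand$filter_trail[[length(cand$filter_trail) + 1L]] <-
    list(filter = filter_name, pass = pass, detail = detail)
  cand
}

#' Known-sequence and low-complexity screen
#'
#' Fails a candidate that (a) aligns to the reference at identity `>=
#' ref_identity` over `>= ref_cov_frac` of its length (a known sequence), or
#' (b) is DUST-masked over more than `dust_frac` of its length.
#'
#' @param cand candidate from [pick_representatives()].
#' @param reference reference genome (named character vector or
#'   `DNAStringSet`).
#' @param cfg a [filter_config()].
#' @return the candidate with `pass` logical attribute and updated trail.
#' @export
filter_known_and_lowcomplexity <- function(cand, reference,
                                           cfg = filter_config()) {
  df <- dust_fraction(cand$seq)
  if (df > cfg$dust_frac) {
    return(add_trail(cand, "known_lowcomplexity", FALSE,
                     sprintf("low complexity: %.2f masked", df)))
  }
  hit <- align_to_reference(cand$seq, reference)
  if (hit$identity >= cfg$ref_identity && hit$cov_frac >= cfg$ref_cov_frac) {
    return(add_trail(cand, "known_lowcomplexity", FALSE,
                     sprintf("known: id=%.3f cov=%.2f on %s",
                             hit$identity, hit$cov_frac, hit$chrom)))
  }
  add_trail(cand, "known_lowcomplexity", TRUE,
            sprintf("dust=%.2f best_ref_id=%.3f cov=%.2f", df, hit$identity,
                    hit$cov_frac))
}

#' Best fixed-width anchor window
#'
#' Among windows `[p, p + window)` anchored at each anchor position `p`
#' (sorted), returns the leftmost window holding the maximum number of
#' anchors.
#'
#' @param positions integer anchor positions (one chromosome).
#' @param window window width (nt).
#' @return `list(window_start, window_end, in_window_count)`.
#' @export
best_anchor_window <- function(positions, window = 4000L) {
  p <- sort(positions)
  n <- length(p)
  # count of anchors in [p_i, p_i + window)
  counts <- findInterval(p + window - 0.5, p) - seq_len(n) + 1L
  i <- which.max(counts)
  list(window_start = p[i], window_end = p[i] + as.integer(window),
       in_window_count = counts[i])
}

#' Anchor-cluster filter
#'
#' A true insertion concentrates its anchors near one locus; a candidate is
#' kept iff at least `cluster_min_frac` of its anchors (distinct pairs) fall
#' in one `cluster_window`-nt window. Anchors on the modal chromosome are
#' windowed; anchors elsewhere count only in the denominator.
#'
#' @param cand candidate with `anchor_records` (`data.table` with
#'   `anchor_chrom`, `anchor_pos`, `pair_id`).
#' @param cfg a [filter_config()].
#' @return candidate with `anchor_cluster` set
#'   (`chrom`, `window_start`, `window_end`, `in_window_count`,
#'   `total_count`, `fraction`) and updated trail.
#' @export
anchor_cluster_filter <- function(cand, cfg = filter_config()) {
  ar <- unique(cand$anchor_records, by = "pair_id")
  if (is.null(ar) || !nrow(ar)) stop("candidate has no anchor records")
  tabs <- ar[, .N, by = anchor_chrom][order(-N, anchor_chrom)]
  modal <- tabs$anchor_chrom[1]
  on_modal <- ar[anchor_chrom == modal]
  w <- best_anchor_window(on_modal$anchor_pos, cfg$cluster_window)
  total <- nrow(ar)
  frac <- w$in_window_count / total
  cand$anchor_cluster <- list(chrom = modal, window_start = w$window_start,
                              window_end = w$window_end,
                              in_window_count = w$in_window_count,
                              total_count = total, fraction = frac)
  add_trail(cand, "anchor_cluster", frac >= cfg$cluster_min_frac,
            sprintf("%d/%d anchors in [%d,%d) on %s", w$in_window_count,
                    total, w$window_start, w$window_end, modal))
}

#' Local-reference screen
#'
#' Extracts the reference sequence spanning the candidate's anchor cluster
#' padded by `local_ref_pad` on each side (clipped at chromosome ends) and
#' fails the candidate if it is alignable to that segment.
#'
#' @inheritParams filter_known_and_lowcomplexity
#' @export
local_reference_filter <- function(cand, reference, cfg = filter_config()) {
  cl <- cand$anchor_cluster
  if (is.null(cl)) stop("anchor_cluster_filter must run first")
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  chrom_seq <- reference[[cl$chrom]]
  ws <- max(0L, cl$window_start - cfg$local_ref_pad)
  we <- min(nchar(chrom_seq), cl$window_end + cfg$local_ref_pad)
  segment <- substr(chrom_seq, ws + 1L, we)   # 0-based half-open -> substr
  hit <- align_to_reference(cand$seq, c(local = segment))
  fail <- hit$identity >= cfg$ref_identity && hit$cov_frac >= cfg$ref_cov_frac
  add_trail(cand, "local_reference", !fail,
            sprintf("segment [%d,%d) id=%.3f cov=%.2f", ws, we,
                    hit$identity, hit$cov_frac))
}

#' Contaminant screen
#'
#' Fails a candidate alignable to any supplied contaminant sequence (e.g. a
#' viral genome); skipped, with a trail note, when no contaminant set is
#' given.
#'
#' @param cand candidate.
#' @param contaminants named character vector / `DNAStringSet`, or `NULL`.
#' @param cfg a [filter_config()].
#' @export
contaminant_filter <- function(cand, contaminants = NULL,
                               cfg = filter_config()) {
  if (is.null(contaminants) || length(contaminants) == 0L) {
    return(add_trail(cand, "contaminant", TRUE, "skipped"))
  }
  hit <- align_to_reference(cand$seq, contaminants)
  fail <- hit$identity >= cfg$ref_identity && hit$cov_frac >= cfg$ref_cov_frac
  add_trail(cand, "contaminant", !fail,
            if (fail) sprintf("matches %s id=%.3f cov=%.2f", hit$chrom,
                              hit$identity, hit$cov_frac)
            else "no contaminant hit")
}

trail_passed <- function(cand) {
  all(vapply(cand$filter_trail, `[[`, logical(1), "pass"))
}

#' Run the full filter chain on a list of candidates
#'
#' Order-fixed: known/low-complexity, anchor cluster, local reference,
#' contaminant. Later filters only run while the candidate is still alive,
#' but every applied filter is recorded exactly once in the trail.
#'
#' @param candidates list of candidates.
#' @param reference reference genome.
#' @param contaminants optional contaminant sequences.
#' @param cfg a [filter_config()].
#' @return list with `passed` and `failed` candidate lists.
#' @export
run_filters <- function(candidates, reference, contaminants = NULL,
                        cfg = filter_config()) {
  passed <- list(); failed <- list()
  for (cand in candidates) {
    cand <- filter_known_and_lowcomplexity(cand, reference, cfg)
    if (trail_passed(cand)) cand <- anchor_cluster_filter(cand, cfg)
    if (trail_passed(cand)) cand <- local_reference_filter(cand, reference, cfg)
    if (trail_passed(cand)) cand <- contaminant_filter(cand, contaminants, cfg)
    if (trail_passed(cand)) passed[[length(passed) + 1L]] <- cand
    else failed[[length(failed) + 1L]] <- cand
  }
  list(passed = passed, failed = failed)
}

#' Merge per-k contigs into filtered candidates for one chromosome
#'
#' Convenience wrapper: similarity graph, representatives, anchor
#' attachment (reads supporting each candidate's member contigs vote with
#' their anchors), then [run_filters()].
#'
#' @param contigs contig table for one anchor chromosome.
#' @param oea pooled OEA table for that chromosome (row order matching the
#'   read indices used at assembly time).
#' @param reference,contaminants,cfg see [run_filters()].
#' @return list with `passed`, `failed`.
#' @export
merge_candidates <- function(contigs, oea, reference, contaminants = NULL,
                             cfg = filter_config()) {
  membership <- build_similarity_graph(contigs, cfg)
  cands <- pick_representatives(contigs, membership)
  supp <- attr(contigs, "read_support")
  cands <- lapply(cands, function(cand) {
    cand$anchor_records <- candidate_anchors(cand, contigs, oea)
    cand
  })
  run_filters(cands, reference, contaminants, cfg)
}

## anchors of OEA reads sharing a k-mer with any member contig (per-candidate
## re-derivation keeps anchor sets exact after merging across k)
candidate_anchors <- function(cand, contigs, oea) {
  mem <- contigs[contig_id %in% cand$member_contigs]
  hit <- rep(FALSE, nrow(oea))
  oriented <- orient_orphan(oea$orphan_seq, oea$anchor_strand)
  for (i in seq_len(nrow(mem))) {
    k <- mem$k[i]
    ck <- unique(canonical_kmers(seq_kmers(mem$seq[i], k)))
    rk <- seqs_kmers_dt(oriented[!hit], k)
    if (!nrow(rk)) next
    rk[, kmer := canonical_kmers(kmer)]
    match_idx <- unique(rk[kmer %in% ck, read_idx])
    hit[which(!hit)[match_idx]] <- TRUE
  }
  oea[hit]
}

#' Trim reference-derived flanks off a candidate
#'
#' Orphan reads straddling the insertion boundary carry reference sequence,
#' so assembled candidates extend past the novel insertion into its flanks.
#' Each end of the candidate is aligned to the local reference segment
#' around the anchor cluster; an end-anchored alignment at identity `>=
#' cfg$ref_identity` marks that stretch as flank and it is removed, leaving
#' the novel core.
#'
#' @param cand candidate with `anchor_cluster` set.
#' @param reference reference genome (named character or `DNAStringSet`).
#' @param cfg a [filter_config()].
#' @param probe how many terminal nt of the candidate to align per end.
#' @return the candidate with `seq`/`len` replaced by the core and a
#'   `flank_trim` trail entry.
#' @export
trim_reference_flanks <- function(cand, reference, cfg = filter_config(),
                                  probe = 250L) {
  cl <- cand$anchor_cluster
  if (is.null(cl)) stop("anchor_cluster_filter must run first")
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  chrom_seq <- reference[[cl$chrom]]
  ws <- max(0L, cl$window_start - cfg$local_ref_pad)
  we <- min(nchar(chrom_seq), cl$window_end + cfg$local_ref_pad)
  seg <- substr(chrom_seq, ws + 1L, we)
  scoring <- default_scoring()
  sm <- scoring_matrix(scoring)
  end_flank <- function(part) {
    # returns pattern range of a high-identity local hit within `part`
    aln <- Biostrings::pairwiseAlignment(
      part, seg, type = "local", substitutionMatrix = sm,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
    al <- nchar(as.character(Biostrings::alignedPattern(aln)))
    idn <- if (al > 0) Biostrings::nmatch(aln) / al else 0
    pr <- Biostrings::pattern(aln)
    list(start = IRanges::start(pr), end = IRanges::end(pr),
         identity = idn, len = al)
  }
  L <- nchar(cand$seq)
  p <- min(L, probe)
  core_start <- 1L; core_end <- L
  a5 <- end_flank(substr(cand$seq, 1L, p))
  if (a5$identity >= cfg$ref_identity && a5$len >= 20L && a5$start <= 5L) {
    core_start <- a5$end + 1L
  }
  a3 <- end_flank(substr(cand$seq, L - p + 1L, L))
  if (a3$identity >= cfg$ref_identity && a3$len >= 20L && a3$end >= p - 5L) {
    core_end <- L - p + a3$start - 1L
  }
  trimmed <- L - (core_end - core_start + 1L)
  if (core_start <= core_end && trimmed > 0L) {
    cand$seq <- substr(cand$seq, core_start, core_end)
    cand$len <- nchar(cand$seq)
  }
  add_trail(cand, "flank_trim", TRUE,
            sprintf("trimmed %d nt of reference flank (%d-%d kept)",
                    max(trimmed, 0L), core_start, core_end))
}

#' Group surviving candidates into genomic regions and rescue-fragmented ones
#'
#' Two candidates share a region when their anchor-cluster windows overlap.
#' Regions with more than one candidate are reassembled from the region's
#' orphan reads at the relaxed coverage cutoff; the longest rescue contig
#' replaces the region's candidates (longest member wins if rescue fails).
#'
#' @param passed list of candidates that survived [run_filters()].
#' @param oea pooled OEA table for the chromosome.
#' @param acfg an [assembly_config()].
#' @return list of candidates, one per region.
#' @export
rescue_regions <- function(passed, oea, acfg = assembly_config()) {
  if (length(passed) <= 1L) return(passed)
  cl <- rbindlist(lapply(passed, function(cand)
    data.table(ws = cand$anchor_cluster$window_start,
               we = cand$anchor_cluster$window_end)))
  ir <- IRanges::IRanges(start = cl$ws + 1L, end = cl$we)
  comp <- igraph::components(igraph::graph_from_data_frame(
    d = as.data.frame(IRanges::findOverlaps(ir, ir))[, 1:2],
    directed = FALSE,
    vertices = data.frame(name = seq_along(passed))))$membership
  out <- list()
  for (m in sort(unique(comp))) {
    members <- passed[comp == m]
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- members[[1]]
      next
    }
    ws <- min(vapply(members, function(x) x$anchor_cluster$window_start, numeric(1)))
    we <- max(vapply(members, function(x) x$anchor_cluster$window_end, numeric(1)))
    reg <- oea[anchor_pos >= ws & anchor_pos < we]
    rc <- rescue_assemble(orient_orphan(reg$orphan_seq, reg$anchor_strand),
                          acfg, reg$sample_id)
    best_member <- members[[order(-vapply(members, `[[`, numeric(1), "len"))[1]]]
    if (!is.null(rc) && rc$len >= best_member$len) {
      merged <- best_member
      merged$id <- paste0(rc$contig_id, "_rescue")
      merged$seq <- rc$seq; merged$len <- rc$len; merged$k <- rc$k
      merged$mean_kmer_cov <- rc$mean_kmer_cov
      merged$member_contigs <- unlist(lapply(members, `[[`, "member_contigs"))
      merged$anchor_records <- unique(rbindlist(
        lapply(members, `[[`, "anchor_records")), by = "pair_id")
      merged <- add_trail(merged, "rescue",
                          TRUE, sprintf("region [%d,%d): %d candidates -> %d nt",
                                        ws, we, length(members), rc$len))
      out[[length(out) + 1L]] <- merged
    } else {
      out[[length(out) + 1L]] <- add_trail(best_member, "rescue", TRUE,
                                           "rescue no longer than best member")
    }
  }
  out
}
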