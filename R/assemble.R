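## Multi-k de Bruijn assembly of pooled orphan reads. k-mers are counted
## double-stranded (a k-mer and its reverse complement are one edge); the
## mean k-mer multiplicity of a contig is the commonness signal that the
## coverage cutoff (50x by default) thresholds. Traversal and tie-breaks are
## lexicographic, so assembly is a pure function of the read multiset.

#' Assembly configuration
#'
#' @param k_values odd k-mer sizes; default 19..59 step 4.
#' @param cov_cutoff mean k-mer coverage a contig must reach.
#' @param rescue_cov_cutoff relaxed cutoff used by [rescue_assemble()] in
#'   regions holding more than one surviving candidate.
#' @param min_contig_len minimum reported contig length (nt).
#' @return an `assembly_config` list.
#' @export
assembly_config <- function(k_values = seq(19L, 59L, by = 4L),
                            cov_cutoff = 50, rescue_cov_cutoff = 20,
                            min_contig_len = 100L) {
  k_values <- as.integer(k_values)
  stopifnot(all(k_values %% 2L == 1L), all(k_values >= 3L),
            cov_cutoff > rescue_cov_cutoff, rescue_cov_cutoff > 0)
  structure(list(k_values = k_values, cov_cutoff = cov_cutoff,
                 rescue_cov_cutoff = rescue_cov_cutoff,
                 min_contig_len = as.integer(min_contig_len)),
            class = "assembly_config")
}

canonical_kmers <- function(kmers) {
  rc <- revcomp(kmers)
  pmin(kmers, rc)
}

#' Build a de Bruijn graph from reads
#'
#' Nodes are (k-1)-mers, edges are k-mers with double-stranded multiplicities
#' (k-mer and reverse complement identified). k-mers containing `N` are
#' skipped.
#'
#' @param reads character vector of reads.
#' @param k odd k-mer size.
#' @return `data.table(kmer, mult)` of canonical k-mers, sorted; zero rows
#'   (with a warning) when `k` exceeds every read length.
#' @export
build_dbg <- function(reads, k) {
  km <- seqs_kmers_dt(reads, k)
  if (!nrow(km)) {
    warning("k = ", k, " exceeds every read length; empty graph")
    return(data.table(kmer = character(0), mult = integer(0)))
  }
  km <- km[!grepl("N", kmer, fixed = TRUE)]
  if (!nrow(km)) return(data.table(kmer = character(0), mult = integer(0)))
  km[, kmer := canonical_kmers(kmer)]
  g <- km[, .(mult = .N), by = kmer]
  setorder(g, kmer)
  g[]
}

## expand canonical edge table to a directed edge table (both orientations)
directed_edges <- function(g, k) {
  rc <- revcomp(g$kmer)
  pal <- rc == g$kmer
  ed <- data.table(kmer = c(g$kmer, rc[!pal]),
                   mult = c(g$mult, g$mult[!pal]))
  ed[, node_from := substr(kmer, 1L, k - 1L)]
  ed[, node_to := substr(kmer, 2L, k)]
  setorder(ed, kmer)
  ed
}

## compress maximal unbranched paths of a directed edge table into unitigs;
## O(E) with integer-indexed adjacency, edges visited in lexicographic order
compress_unitigs <- function(ed, k) {
  empty <- data.table(seq = character(0), mean_mult = numeric(0),
                      n_edges = integer(0), is_tip = logical(0))
  if (!nrow(ed)) return(empty)
  setorder(ed, kmer)
  nodes <- sort(unique(c(ed$node_from, ed$node_to)))
  fi <- match(ed$node_from, nodes)
  ti <- match(ed$node_to, nodes)
  nn <- length(nodes); ne <- nrow(ed)
  outdeg <- tabulate(fi, nn)
  indeg <- tabulate(ti, nn)
  simple_node <- indeg == 1L & outdeg == 1L
  out_edge <- rep(NA_integer_, nn)          # defined where outdeg == 1
  single_out <- which(outdeg[fi] == 1L)
  out_edge[fi[single_out]] <- single_out
  last_char <- substr(ed$kmer, k, k)
  mult <- ed$mult
  used <- logical(ne)
  seqs <- character(0); means <- numeric(0); nedges <- integer(0)
  tips <- logical(0)
  walk_from <- function(e) {
    path <- integer(64); path[1] <- e; np <- 1L
    cur <- ti[e]
    while (simple_node[cur]) {
      e2 <- out_edge[cur]
      if (is.na(e2) || used[e2]) break
      used[e2] <<- TRUE
      np <- np + 1L
      if (np > length(path)) path <- c(path, integer(length(path)))
      path[np] <- e2
      cur <- ti[e2]
    }
    path <- path[seq_len(np)]
    seqs <<- c(seqs, paste0(ed$kmer[e],
                            paste(last_char[path[-1]], collapse = "")))
    means <<- c(means, mean(mult[path]))
    nedges <<- c(nedges, np)
    tips <<- c(tips, indeg[fi[e]] == 0L || outdeg[cur] == 0L)
  }
  for (e in which(!simple_node[fi])) {      # path starts (lexicographic)
    if (used[e]) next
    used[e] <- TRUE
    walk_from(e)
  }
  for (e in which(!used)) {                 # isolated cycles
    if (used[e]) next
    used[e] <- TRUE
    walk_from(e)
  }
  if (!length(seqs)) return(empty)
  data.table(seq = seqs, mean_mult = means, n_edges = nedges, is_tip = tips)
}

## drop reverse-complement duplicate contigs, keep lexicographically smaller
dedupe_rc <- function(ut) {
  if (!nrow(ut)) return(ut)
  ut[, seq := pmin(seq, revcomp(seq))]
  ut <- ut[, .(mean_mult = max(mean_mult), n_edges = max(n_edges),
               is_tip = any(is_tip)), by = seq]
  setorder(ut, seq)
  ut
}

#' Assemble at a single k
#'
#' Builds the graph, clips low-multiplicity tips (shorter than `2k`, mean
#' multiplicity below `cov_cutoff/4`), deletes edges with multiplicity below
#' `cov_cutoff`, recompresses, and reports contigs of length `>=`
#' `min_contig_len` whose mean k-mer coverage reaches the cutoff, together
#' with per-sample read support (reads sharing at least one k-mer).
#'
#' @param reads character vector of (oriented) reads.
#' @param k odd k-mer size.
#' @param cov_cutoff mean k-mer coverage threshold.
#' @param min_contig_len minimum contig length.
#' @param sample_ids optional per-read sample ids for the support map.
#' @return `data.table(contig_id, seq, k, len, mean_kmer_cov)` plus
#'   attribute `read_support` (`data.table(contig_id, sample_id, n_reads)`).
#' @export
assemble_k <- function(reads, k, cov_cutoff = 50, min_contig_len = 100L,
                       sample_ids = NULL) {
  empty <- data.table(contig_id = character(0), seq = character(0),
                      k = integer(0), len = integer(0),
                      mean_kmer_cov = numeric(0))
  setattr(empty, "read_support",
          data.table(contig_id = character(0), sample_id = character(0),
                     n_reads = integer(0)))
  g <- suppressWarnings(build_dbg(reads, k))
  if (!nrow(g)) return(empty)
  ed <- directed_edges(g, k)
  ut <- compress_unitigs(ed, k)
  # tip clipping: short dead-end unitigs of low mean multiplicity
  clip <- ut$is_tip & nchar(ut$seq) < 2L * k & ut$mean_mult < cov_cutoff / 4
  if (any(clip)) {
    drop_kmers <- unique(canonical_kmers(unlist(
      lapply(ut$seq[clip], seq_kmers, w = k))))
    g <- g[!kmer %in% drop_kmers]
  }
  g <- g[mult >= cov_cutoff]
  if (!nrow(g)) return(empty)
  ut <- dedupe_rc(compress_unitigs(directed_edges(g, k), k))
  ut <- ut[nchar(seq) >= min_contig_len & mean_mult >= cov_cutoff]
  if (!nrow(ut)) return(empty)
  ut <- orient_contigs(ut, reads, k)
  out <- data.table(contig_id = sprintf("k%d_c%03d", k, seq_len(nrow(ut))),
                    seq = ut$seq, k = k, len = nchar(ut$seq),
                    mean_kmer_cov = ut$mean_mult)
  setattr(out, "read_support", contig_read_support(out, reads, k, sample_ids))
  out
}

## reads sharing >= 1 canonical k-mer with each contig, counted per sample
contig_read_support <- function(contigs, reads, k, sample_ids) {
  if (is.null(sample_ids)) sample_ids <- rep("pooled", length(reads))
  if (!nrow(contigs) || !length(reads)) {
    return(data.table(contig_id = character(0), sample_id = character(0),
                      n_reads = integer(0)))
  }
  ck <- rbindlist(lapply(seq_len(nrow(contigs)), function(i)
    data.table(contig_id = contigs$contig_id[i],
               kmer = unique(canonical_kmers(seq_kmers(contigs$seq[i], k))))))
  rk <- seqs_kmers_dt(reads, k)
  rk <- rk[!grepl("N", kmer, fixed = TRUE)]
  rk[, kmer := canonical_kmers(kmer)]
  rk <- unique(rk)
  hits <- merge(rk, ck, by = "kmer", allow.cartesian = TRUE)
  hits <- unique(hits[, .(read_idx, contig_id)])
  hits[, sample_id := sample_ids[read_idx]]
  hits[, .(n_reads = uniqueN(read_idx)), by = .(contig_id, sample_id)]
}

## canonical k-mer counting loses strand; re-orient each contig to the
## majority orientation of the input reads (stranded k-mer vote)
orient_contigs <- function(ut, reads, k) {
  rk <- seqs_kmers_dt(reads, k)
  if (!nrow(rk)) return(ut)
  counts <- rk[, .(n = .N), by = kmer]
  setkey(counts, kmer)
  votes <- function(s) {
    km <- seq_kmers(s, k)
    sum(counts[.(km)]$n, na.rm = TRUE)
  }
  flip <- vapply(ut$seq, function(s) votes(revcomp(s)) > votes(s), logical(1))
  if (any(flip)) ut[flip, seq := revcomp(seq)]
  ut
}

#' Assemble over all configured k values
#'
#' Union of [assemble_k()] over `cfg$k_values`; near-duplicate contigs from
#' different k are retained here and resolved downstream by the similarity
#' graph.
#'
#' @param reads character vector of (oriented) reads.
#' @param cfg an [assembly_config()].
#' @param sample_ids optional per-read sample ids.
#' @param cov_cutoff override of `cfg$cov_cutoff` (used by rescue).
#' @return contig table as in [assemble_k()], `contig_id`s made unique,
#'   with a combined `read_support` attribute.
#' @export
assemble_multik <- function(reads, cfg = assembly_config(),
                            sample_ids = NULL, cov_cutoff = NULL) {
  cc <- cov_cutoff %||% cfg$cov_cutoff
  parts <- lapply(cfg$k_values, function(k)
    assemble_k(reads, k, cc, cfg$min_contig_len, sample_ids))
  out <- rbindlist(parts)
  supp <- rbindlist(lapply(parts, attr, "read_support"))
  setattr(out, "read_support", supp)
  out[]
}

#' Rescue assembly of a multi-candidate region at the relaxed cutoff
#'
#' When one genomic region yields more than one surviving candidate at the
#' stringent cutoff, the candidates may be fragments of one longer
#' insertion. The region's orphan reads are reassembled at
#' `cfg$rescue_cov_cutoff` and the single longest contig is returned.
#'
#' @param reads oriented orphan reads whose anchors fall in the region.
#' @param cfg an [assembly_config()].
#' @param sample_ids optional per-read sample ids.
#' @return one-row contig table (longest contig), or `NULL` if nothing
#'   reaches `min_contig_len`.
#' @export
rescue_assemble <- function(reads, cfg = assembly_config(), sample_ids = NULL) {
  ct <- assemble_multik(reads, cfg, sample_ids,
                        cov_cutoff = cfg$rescue_cov_cutoff)
  if (!nrow(ct)) return(NULL)
  setorder(ct, -len, -mean_kmer_cov, seq)
  best <- ct[1]
  supp <- attr(ct, "read_support")
  setattr(best, "read_support", supp[contig_id == best$contig_id])
  best
}
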