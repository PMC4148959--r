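## Local alignment with a Karlin-Altschul e-value, a DUST-style
## low-complexity masker, and a seed-and-extend screen against long
## references. The alignment itself is Smith-Waterman via
## Biostrings::pairwiseAlignment; the statistics layer is ours.

#' Karlin-Altschul parameters for a match/mismatch scoring scheme
#'
#' `lambda` solves `E[exp(lambda * S)] = 1` for the per-position score `S`
#' under uniform base composition (probability 1/4 per base: match
#' probability 1/4). `K` is a fixed calibration constant (0.1, the typical
#' ungapped-regime magnitude); at the e-value thresholds used here
#' (`1e-10`) the separation between near-identical and unrelated sequences
#' spans many orders of magnitude, so the result is insensitive to `K`.
#'
#' @param match,mismatch match/mismatch scores (mismatch negative).
#' @return `list(lambda, K)`.
#' @export
ka_params <- function(match = 1, mismatch = -2) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-6, 10), tol = 1e-12)$root
  list(lambda = lambda, K = 0.1)
}

default_scoring <- function() {
  list(match = 1, mismatch = -2, gap_open = 5, gap_ext = 2)
}

scoring_matrix <- function(scoring) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- scoring$match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Best local alignment of two sequences with an e-value
#'
#' Smith-Waterman under match +1 / mismatch -2 / gap open -5 / gap extend
#' -2 by default; the e-value is `K * m * n * exp(-lambda * S)` with
#' `(lambda, K)` from [ka_params()].
#'
#' @param a,b DNA strings.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @return `list(score, identity, aln_len, evalue)`; `identity` is matches
#'   over alignment columns, `aln_len` the number of alignment columns.
#' @export
local_align <- function(a, b, scoring = default_scoring()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "local",
    substitutionMatrix = scoring_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_ext)
  s <- Biostrings::score(aln)
  pat <- as.character(Biostrings::alignedPattern(aln))
  al <- nchar(pat)
  nm <- Biostrings::nmatch(aln)
  kp <- ka_params(scoring$match, scoring$mismatch)
  ev <- kp$K * nchar(a) * nchar(b) * exp(-kp$lambda * s)
  list(score = s, identity = if (al > 0) nm / al else 0,
       aln_len = al, q_span = nchar(gsub("-", "", pat, fixed = TRUE)),
       evalue = ev)
}

## best of forward and reverse-complement local alignment
local_align_2str <- function(a, b, scoring = default_scoring()) {
  f <- local_align(a, b, scoring)
  r <- local_align(revcomp(a), b, scoring)
  if (r$score > f$score) r else f
}

#' DUST-style low-complexity mask fraction
#'
#' Scores 64-nt windows (stepping 32) by triplet-frequency skew,
#' `sum(c_t (c_t - 1) / 2) / (n_triplets - 1)`; windows scoring above the
#' threshold are masked. Windows shorter than 6 nt are ignored.
#'
#' @param seq DNA string.
#' @param window window width (nt).
#' @param threshold DUST score above which a window is masked.
#' @return fraction of positions masked, in `[0, 1]`.
#' @export
dust_fraction <- function(seq, window = 64L, threshold = 2.0) {
  L <- nchar(seq)
  if (L < 6L) return(0)
  starts <- unique(c(seq(1L, max(1L, L - window + 1L), by = max(1L, window %/% 2L)),
                     max(1L, L - window + 1L)))
  masked <- logical(L)
  for (s in starts) {
    e <- min(s + window - 1L, L)
    if (e - s + 1L < 6L) next
    w <- substr(seq, s, e)
    tr <- seq_kmers(w, 3L)
    ct <- table(tr)
    score <- sum(ct * (ct - 1) / 2) / (length(tr) - 1L)
    if (score > threshold) masked[s:e] <- TRUE
  }
  mean(masked)
}

#' Seed-and-extend alignment of a query against reference sequences
#'
#' Exact seeds of `seed_len` nt on both strands locate candidate loci; each
#' seeded locus is refined by local alignment of the query against the
#' reference window around it. Used by the known-sequence, local-reference
#' and contaminant screens.
#'
#' @param query DNA string.
#' @param reference named character vector or `DNAStringSet`.
#' @param seed_len exact seed length.
#' @param scoring see [local_align()].
#' @param max_loci refine at most this many distinct seeded loci per strand
#'   and reference sequence.
#' @return `list(identity, cov_frac, chrom, evalue)` for the best hit
#'   (`cov_frac` = aligned query span / query length), or zeros when no seed
#'   matches.
#' @export
align_to_reference <- function(query, reference, seed_len = 15L,
                               scoring = default_scoring(), max_loci = 8L) {
  if (methods::is(reference, "DNAStringSet")) {
    refs <- setNames(as.character(reference), names(reference))
  } else refs <- reference
  qlen <- nchar(query)
  best <- list(identity = 0, cov_frac = 0, chrom = NA_character_, evalue = Inf)
  total_ref <- sum(nchar(refs))
  for (qs in c(query, revcomp(query))) {
    seeds <- unique(seq_kmers(qs, seed_len))
    if (!length(seeds)) next
    qdict <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (ci in seq_along(refs)) {
      mt <- Biostrings::matchPDict(qdict, Biostrings::DNAString(refs[[ci]]))
      st <- unlist(lapply(seq_along(mt), function(i) {
        s <- IRanges::start(mt[[i]])
        if (length(s)) s - (match(seeds[i], seq_kmers(qs, seed_len)) - 1L) else integer(0)
      }))
      if (!length(st)) next
      # cluster implied query-start offsets into loci
      st <- sort(unique(pmax(1L, st)))
      loci <- split(st, cumsum(c(1L, diff(st) > qlen)))
      if (length(loci) > max_loci) {
        sizes <- vapply(loci, length, integer(1))
        loci <- loci[order(-sizes)[seq_len(max_loci)]]
      }
      for (lc in loci) {
        ws <- max(1L, min(lc) - qlen %/% 2L)
        we <- min(nchar(refs[[ci]]), max(lc) + qlen + qlen %/% 2L)
        res <- local_align(qs, substr(refs[[ci]], ws, we), scoring)
        cov <- min(1, res$q_span / qlen)
        ev <- res$evalue * total_ref / nchar(refs[[ci]]) / max(nchar(qs), 1) *
          nchar(qs)                  # rescale database size
        if (res$identity * cov > best$identity * best$cov_frac) {
          best <- list(identity = res$identity, cov_frac = cov,
                       chrom = names(refs)[ci] %||% as.character(ci),
                       evalue = ev)
        }
      }
    }
  }
  best
}
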