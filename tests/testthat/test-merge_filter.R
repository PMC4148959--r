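# quadratic-time Smith-Waterman with affine gaps (Gotoh), independent of the
# package's alignment path; gap of length L costs open + L * ext
sw_oracle <- function(a, b, match = 1, mismatch = -2, open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

test_that("local alignment scores match a dynamic-programming oracle", {
  set.seed(71)
  for (i in 1:50) {
    la <- sample(20:80, 1); lb <- sample(20:80, 1)
    a <- rand_dna(la)
    # half the cases share a planted common segment
    b <- if (i %% 2 == 0) rand_dna(lb) else
      paste0(rand_dna(10), substr(a, 5, min(la, 40)), rand_dna(10))
    res <- local_align(a, b)
    expect_equal(res$score, sw_oracle(a, b))
  }
})

test_that("e-values separate identical from unrelated sequences", {
  set.seed(72)
  x <- rand_dna(300)
  self <- local_align(x, x)
  expect_equal(self$identity, 1.0)
  expect_lt(self$evalue, 1e-10)
  # two independent random 300-mers never reach the edge threshold
  for (i in 1:100) {
    ev <- local_align(rand_dna(300), rand_dna(300))$evalue
    expect_gt(ev, 1e-10)
  }
})

test_that("Karlin-Altschul lambda solves the score-moment equation", {
  kp <- ka_params(1, -2)
  f <- 0.25 * exp(kp$lambda * 1) + 0.75 * exp(kp$lambda * -2)
  expect_equal(f, 1, tolerance = 1e-9)
})

test_that("similarity components: identical merge, chains close transitively, singletons survive", {
  a <- rand_dna(300, 81)
  b <- a                                   # identical twin
  c_ <- rand_dna(300, 82)                  # unrelated
  contigs <- data.table::data.table(
    contig_id = c("A", "B", "C"), seq = c(a, b, c_), k = c(19L, 23L, 31L),
    len = 300L, mean_kmer_cov = 60)
  m <- build_similarity_graph(contigs)
  expect_equal(m[1], m[2])
  expect_false(m[3] == m[1])
  # chain: A ~ B, B ~ C2, A vs C2 unrelated halves -> one component
  half1 <- rand_dna(200, 83); half2 <- rand_dna(200, 84)
  chain <- data.table::data.table(
    contig_id = c("A", "B", "C"),
    seq = c(half1, paste0(half1, half2), half2),
    k = 19L, len = c(200L, 400L, 200L), mean_kmer_cov = 60)
  expect_equal(length(unique(build_similarity_graph(chain))), 1L)
  # a contig assembled at a single k with no partner stays its own candidate
  cands <- pick_representatives(contigs, m)
  expect_equal(length(cands), 2L)
  expect_true(any(vapply(cands, function(x) x$id == "C", TRUE)))
})

test_that("representatives are the longest member, ties by coverage then sequence", {
  contigs <- data.table::data.table(
    contig_id = c("x", "y", "z"),
    seq = c(rand_dna(220, 91), rand_dna(180, 92), rand_dna(220, 93)),
    k = 19L, len = c(220L, 180L, 220L), mean_kmer_cov = c(55, 80, 70))
  cands <- pick_representatives(contigs, rep(1L, 3))
  expect_equal(length(cands), 1L)
  expect_equal(cands[[1]]$id, "z")         # 220 nt, higher coverage
  expect_equal(cands[[1]]$len, 220L)
  # property: representative length equals max member length
  set.seed(94)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    lens <- sample(100:300, n, replace = TRUE)
    ct <- data.table::data.table(
      contig_id = paste0("c", seq_len(n)),
      seq = vapply(lens, rand_dna, ""), k = 19L, len = lens,
      mean_kmer_cov = runif(n, 50, 90))
    rep_ <- pick_representatives(ct, rep(1L, n))[[1]]
    expect_equal(rep_$len, max(lens))
  }
})

test_that("known-sequence and low-complexity screens fail the right candidates", {
  ref <- setNames(rand_dna(20000, 95), "chr1")
  mkcand <- function(seq) structure(
    list(id = "c1", seq = seq, len = nchar(seq), k = 19L, mean_kmer_cov = 60,
         member_contigs = "c1", anchor_records = NULL, anchor_cluster = NULL,
         filter_trail = list()), class = "candidate_micseq")
  # verbatim reference copy -> known
  known <- micseqr:::trail_passed(
    filter_known_and_lowcomplexity(mkcand(substr(ref, 5001, 5300)), ref))
  expect_false(known)
  # dinucleotide repeat -> low complexity
  expect_false(micseqr:::trail_passed(
    filter_known_and_lowcomplexity(mkcand(strrep("AT", 100)), ref)))
  # random novel sequence -> passes
  expect_true(micseqr:::trail_passed(
    filter_known_and_lowcomplexity(mkcand(rand_dna(300, 96)), ref)))
  expect_gt(dust_fraction(strrep("AT", 100)), 0.8)
  expect_lt(dust_fraction(rand_dna(300, 97)), 0.5)
})

test_that("anchor clustering matches the brute-force window oracle", {
  mkcand <- function(pos, chrom = "chr1") structure(
    list(id = "c", seq = rand_dna(200), len = 200L, k = 19L,
         mean_kmer_cov = 60, member_contigs = "c",
         anchor_records = data.table::data.table(
           anchor_chrom = chrom, anchor_pos = pos,
           anchor_strand = "+", pair_id = paste0("p", seq_along(pos))),
         anchor_cluster = NULL, filter_trail = list()),
    class = "candidate_micseq")
  # 10 anchors within 500 nt -> fraction 1, pass
  c1 <- anchor_cluster_filter(mkcand(seq(1000L, 1450L, by = 50L)))
  expect_true(micseqr:::trail_passed(c1))
  expect_equal(c1$anchor_cluster$fraction, 1.0)
  # 10 anchors spread over 100 kb -> max window holds 1, fail
  c2 <- anchor_cluster_filter(mkcand(seq(0L, 99000L, by = 11000L)))
  expect_false(micseqr:::trail_passed(c2))
  expect_equal(c2$anchor_cluster$fraction, 1 / 10)
  # 6 of 10 anchors in one 4 kb span -> 0.6, pass, window equals oracle
  pos <- c(seq(20000L, 22500L, by = 500L), c(1L, 50000L, 80000L, 99000L))
  c3 <- anchor_cluster_filter(mkcand(pos))
  expect_true(micseqr:::trail_passed(c3))
  expect_equal(c3$anchor_cluster$fraction, 0.6)
  o <- window_oracle(pos, 4000L)
  expect_equal(c3$anchor_cluster$window_start, unname(o["start"]))
  expect_equal(c3$anchor_cluster$in_window_count, unname(o["count"]))
  # randomized agreement with the oracle
  set.seed(98)
  for (i in 1:50) {
    pos <- sort(sample.int(200000L, sample(5:40, 1)))
    cc <- anchor_cluster_filter(mkcand(pos))$anchor_cluster
    o <- window_oracle(pos, 4000L)
    expect_equal(cc$in_window_count, unname(o["count"]))
    expect_equal(cc$window_start, unname(o["start"]))
  }
  # anchors on several chromosomes: modal chromosome windowed, rest dilute
  mixed <- mkcand(c(rep(5000L, 6L), 1L), chrom = c(rep("chr1", 6), "chr2"))
  mixed$anchor_records$pair_id <- paste0("q", 1:7)
  cm <- anchor_cluster_filter(mixed)
  expect_equal(cm$anchor_cluster$chrom, "chr1")
  expect_equal(cm$anchor_cluster$fraction, 6 / 7)
})

test_that("local-reference screen removes candidates explained by the anchor locus", {
  ref <- setNames(rand_dna(20000, 99), "chr1")
  base <- structure(
    list(id = "c", seq = substr(ref, 8001, 8300), len = 300L, k = 19L,
         mean_kmer_cov = 60, member_contigs = "c",
         anchor_records = data.table::data.table(
           anchor_chrom = "chr1", anchor_pos = seq(7800L, 8200L, 50L),
           anchor_strand = "+",
           pair_id = paste0("p", 1:9)),
         anchor_cluster = NULL, filter_trail = list()),
    class = "candidate_micseq")
  cand <- anchor_cluster_filter(base)
  expect_false(micseqr:::trail_passed(local_reference_filter(cand, ref)))
  novel <- base; novel$seq <- rand_dna(300, 100)
  novel <- anchor_cluster_filter(novel)
  expect_true(micseqr:::trail_passed(local_reference_filter(novel, ref)))
  # cluster at the chromosome start: padding clips to 0, no error
  edge <- base
  edge$anchor_records$anchor_pos <- seq(0L, 400L, 50L)
  edge <- anchor_cluster_filter(edge)
  out <- local_reference_filter(edge, ref)
  expect_equal(length(out$filter_trail), 2L)
})

test_that("contaminant screen flags the packaged synthetic virus and skips cleanly", {
  cont <- read_fasta(system.file("extdata", "synthetic_contaminants.fa",
                                 package = "micseqr"))
  contaminants <- setNames(cont$seq, cont$id)
  mk <- function(seq) structure(
    list(id = "c", seq = seq, len = nchar(seq), filter_trail = list()),
    class = "candidate_micseq")
  viral <- contaminant_filter(mk(substr(contaminants[[1]], 100, 450)),
                              contaminants)
  expect_false(micseqr:::trail_passed(viral))
  clean <- contaminant_filter(mk(rand_dna(300, 101)), contaminants)
  expect_true(micseqr:::trail_passed(clean))
  skipped <- contaminant_filter(mk(rand_dna(300, 102)), NULL)
  expect_true(micseqr:::trail_passed(skipped))
  expect_match(skipped$filter_trail[[1]]$detail, "skipped")
})

test_that("the filter chain applies in fixed order and records every verdict once", {
  sim <- small_sim(seed = 51L, freq = 0.5, len = 300L,
                   n = c(EUR = 30L, AFR = 30L), ref_len = 30000L,
                   pos = 15000L)
  cls <- classify_pairs(sim$pairs, 20L)
  oea <- pool_oea(list(extract_oea(sim$pairs, sim$pairs, cls)))$chr1
  oriented <- orient_orphan(oea$orphan_seq, oea$anchor_strand)
  contigs <- assemble_multik(oriented, assembly_config(k_values = c(19L, 27L)),
                             oea$sample_id)
  res <- merge_candidates(contigs, oea, sim$pop$reference)
  for (cand in c(res$passed, res$failed)) {
    names_seen <- vapply(cand$filter_trail, `[[`, "", "filter")
    expect_equal(names_seen, unique(names_seen))
    expect_equal(names_seen,
                 c("known_lowcomplexity", "anchor_cluster", "local_reference",
                   "contaminant")[seq_along(names_seen)])
  }
  expect_gte(length(res$passed), 1L)
})
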