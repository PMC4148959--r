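# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures.

rand_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# dense deterministic tiling: every start position, `copies` reads each
# (forward majority), so every k-mer of the source - including terminal ones
# - has multiplicity >= copies. Exact reconstruction needs copies >= cutoff.
tile_reads <- function(source, read_len = 100L, copies = 60L) {
  L <- nchar(source)
  starts <- seq_len(max(1L, L - read_len + 1L))
  fwd_n <- ceiling((copies + 1L) / 2)
  rc_n <- copies - fwd_n
  fwd <- substring(source, starts, pmin(starts + read_len - 1L, L))
  c(rep(fwd, each = fwd_n),
    if (rc_n > 0) rep(micseqr::revcomp(fwd), each = rc_n))
}

# sparse random sampling at a true base coverage (for below-cutoff cases)
sample_reads <- function(source, read_len = 100L, cov = 10, seed = 1L) {
  set.seed(seed)
  L <- nchar(source)
  n <- max(1L, round(cov * L / read_len))
  starts <- sample.int(max(1L, L - read_len + 1L), n, replace = TRUE)
  reads <- substring(source, starts, pmin(starts + read_len - 1L, L))
  flip <- seq_len(n) %% 2L == 0L
  reads[flip] <- micseqr::revcomp(reads[flip])
  reads
}

# minimal pair table with alignments, for classify/extract tests
make_aln_row <- function(m1 = list(), m2 = list()) {
  d <- function(m, mapped = TRUE, chrom = "chr1", pos = 1000L, strand = "+",
                mapq = 60L) {
    if (isFALSE(m$mapped %||% mapped)) {
      list(mapped = FALSE, chrom = NA_character_, pos = NA_integer_,
           strand = NA_character_, mapq = NA_integer_)
    } else {
      list(mapped = TRUE, chrom = m$chrom %||% chrom,
           pos = as.integer(m$pos %||% pos), strand = m$strand %||% strand,
           mapq = as.integer(m$mapq %||% mapq))
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  a <- d(m1); b <- d(m2)
  data.table::data.table(
    pair_id = "p1",
    m1_mapped = a$mapped, m1_chrom = a$chrom, m1_pos = a$pos,
    m1_strand = a$strand, m1_mapq = a$mapq,
    m2_mapped = b$mapped, m2_chrom = b$chrom, m2_pos = b$pos,
    m2_strand = b$strand, m2_mapq = b$mapq)
}

# small standard cohort for pipeline-level tests
small_sim <- function(seed = 7L, freq = 0.5, len = 400L,
                      n = c(EUR = 35L, ASN = 35L, AFR = 30L),
                      ref_len = 50000L, pos = 25000L) {
  cfg <- sim_config(ref_len = ref_len, n_individuals = n,
                    insertions = data.frame(len = len, chrom = "chr1",
                                            pos = pos, freq = freq,
                                            population = NA_character_),
                    seed = seed)
  simulate_cohort(cfg)
}
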