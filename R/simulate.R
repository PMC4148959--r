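## Seeded cohort simulator: a random reference, a diploid population
## carrying non-reference insertions at configured allele frequencies,
## Illumina-like FR paired-end reads at shallow coverage, and an idealized
## aligner that maps a read iff >= 95% of its bases derive from reference
## sequence. The simulator is the pipeline's ground truth: pairs straddling
## an insertion boundary become OEA, pairs inside a long insertion become
## full orphans.

#' Simulation configuration
#'
#' @param ref_len chromosome length (nt); every chromosome has this length.
#' @param n_chroms number of chromosomes (`chr1`, `chr2`, ...).
#' @param n_individuals named integer vector: samples per population.
#' @param insertions `data.frame` with columns `len`, `chrom`, `pos`
#'   (0-based reference insertion point), `freq` (target allele frequency in
#'   `(0, 1]`), and optional `population` (`NA` = shared across the cohort).
#' @param read_len read length (nt).
#' @param insert_mean,insert_sd fragment (insert) size distribution;
#'   truncated below at `2 * read_len`.
#' @param coverage mean per-individual base coverage (diploid).
#' @param base_error_rate i.i.d. substitution error rate per base.
#' @param map_ref_frac a read is "mapped" by the ideal aligner iff at least
#'   this fraction of its bases derives from reference sequence.
#' @param min_spacing minimum distance between insertion loci (nt).
#' @param seed RNG seed; all outputs are a pure function of the config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(ref_len = 100000L, n_chroms = 1L,
                       n_individuals = c(EUR = 4L, ASN = 4L, AFR = 4L),
                       insertions = data.frame(len = 400L, chrom = "chr1",
                                               pos = 50000L, freq = 0.5,
                                               population = NA_character_),
                       read_len = 100L, insert_mean = 300, insert_sd = 30,
                       coverage = 4, base_error_rate = 0.002,
                       map_ref_frac = 0.95, min_spacing = 10000L,
                       seed = 1L) {
  ins <- as.data.table(as.data.frame(insertions))
  if (is.null(ins$population)) ins[, population := NA_character_]
  if (nrow(ins)) {
    stopifnot(all(ins$freq > 0 & ins$freq <= 1),
              all(ins$pos >= 0 & ins$pos <= ref_len),
              all(ins$chrom %in% paste0("chr", seq_len(n_chroms))))
    for (cn in unique(ins$chrom)) {
      p <- sort(ins[chrom == cn, pos])
      if (length(p) > 1L && any(diff(p) < min_spacing)) {
        stop("insertion loci on ", cn, " closer than min_spacing (",
             min_spacing, " nt)")
      }
    }
  }
  structure(list(ref_len = as.integer(ref_len),
                 n_chroms = as.integer(n_chroms),
                 n_individuals = n_individuals, insertions = ins,
                 read_len = as.integer(read_len), insert_mean = insert_mean,
                 insert_sd = insert_sd, coverage = coverage,
                 base_error_rate = base_error_rate,
                 map_ref_frac = map_ref_frac,
                 min_spacing = as.integer(min_spacing),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Build the simulated population
#'
#' Draws the reference and insertion sequences (insertions are rejected and
#' redrawn if DUST-masked or alignable to the reference, so novelty holds by
#' construction) and per-individual genotypes, binomially at each
#' insertion's target allele frequency (restricted to its population when
#' private).
#'
#' @param cfg a [sim_config()]. Sets the RNG seed.
#' @return list with `reference` (named character), `samples`
#'   (`data.table(sample_id, population)`), `insertions`
#'   (`data.table(ins_id, chrom, pos, len, freq, population, seq)`),
#'   `genotypes` (matrix individuals x insertions, copies 0/1/2) and
#'   `hap_alleles` (list of two 0/1 matrices).
#' @export
make_population <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  reference <- setNames(random_dna(cfg$n_chroms, cfg$ref_len), chroms)
  samples <- rbindlist(lapply(names(cfg$n_individuals), function(p)
    data.table(sample_id = sprintf("%s_%02d", p, seq_len(cfg$n_individuals[[p]])),
               population = p)))
  ins <- copy(cfg$insertions)
  n_ins <- nrow(ins)
  seqs <- character(n_ins)
  for (i in seq_len(n_ins)) {
    repeat {
      s <- random_dna(1L, ins$len[i])
      if (dust_fraction(s) > 0.5) next
      hit <- align_to_reference(s, reference)
      if (hit$identity >= 0.95 && hit$cov_frac >= 0.9) next
      seqs[i] <- s
      break
    }
  }
  if (n_ins) {
    ins[, `:=`(ins_id = sprintf("ins%02d", seq_len(n_ins)), seq = seqs)]
    setcolorder(ins, c("ins_id", "chrom", "pos", "len", "freq", "population",
                       "seq"))
  } else {
    ins <- data.table(ins_id = character(0), chrom = character(0),
                      pos = integer(0), len = integer(0), freq = numeric(0),
                      population = character(0), seq = character(0))
  }
  n_ind <- nrow(samples)
  geno <- matrix(0L, n_ind, n_ins,
                 dimnames = list(samples$sample_id, ins$ins_id))
  hap1 <- hap2 <- matrix(0L, n_ind, n_ins,
                         dimnames = dimnames(geno))
  for (j in seq_len(n_ins)) {
    eligible <- if (is.na(ins$population[j])) rep(TRUE, n_ind)
                else samples$population == ins$population[j]
    g <- integer(n_ind)
    g[eligible] <- rbinom(sum(eligible), 2L, ins$freq[j])
    geno[, j] <- g
    h1 <- integer(n_ind); h2 <- integer(n_ind)
    h1[g == 2L] <- 1L; h2[g == 2L] <- 1L
    het <- which(g == 1L)
    if (length(het)) {
      first <- runif(length(het)) < 0.5
      h1[het[first]] <- 1L
      h2[het[!first]] <- 1L
    }
    hap1[, j] <- h1; hap2[, j] <- h2
  }
  list(reference = reference, samples = samples, insertions = ins,
       genotypes = geno, hap_alleles = list(hap1, hap2))
}

## haplotype layout for one individual/chromosome: sequence plus insertion
## intervals in haplotype coordinates (0-based half-open)
build_haplotype <- function(ref_seq, ins_sub) {
  if (!nrow(ins_sub)) {
    return(list(seq = ref_seq,
                ins_start = integer(0), ins_end = integer(0),
                ins_ref_pos = integer(0), ins_id = character(0)))
  }
  setorder(ins_sub, pos)
  pieces <- character(2L * nrow(ins_sub) + 1L)
  prev <- 0L
  off <- 0L
  ins_start <- integer(nrow(ins_sub))
  for (i in seq_len(nrow(ins_sub))) {
    pieces[2L * i - 1L] <- substr(ref_seq, prev + 1L, ins_sub$pos[i])
    pieces[2L * i] <- ins_sub$seq[i]
    ins_start[i] <- ins_sub$pos[i] + off
    off <- off + ins_sub$len[i]
    prev <- ins_sub$pos[i]
  }
  pieces[2L * nrow(ins_sub) + 1L] <- substr(ref_seq, prev + 1L, nchar(ref_seq))
  list(seq = paste(pieces, collapse = ""),
       ins_start = ins_start, ins_end = ins_start + ins_sub$len,
       ins_ref_pos = ins_sub$pos, ins_id = ins_sub$ins_id)
}

## project 0-based haplotype positions to reference positions; positions
## inside an insertion project to the insertion point
project_to_ref <- function(h, hap) {
  if (!length(hap$ins_start)) return(h)
  cum <- cumsum(hap$ins_end - hap$ins_start)
  j <- findInterval(h, hap$ins_end)        # insertions entirely at or before h
  inside <- findInterval(h, hap$ins_start) > j
  out <- h - ifelse(j > 0L, cum[pmax(j, 1L)], 0L)
  if (any(inside)) {
    k <- findInterval(h[inside], hap$ins_start)
    out[inside] <- hap$ins_ref_pos[k]
  }
  out
}

## bases of [a, b) (hap coords) that fall inside insertions
insert_overlap <- function(a, b, hap) {
  if (!length(hap$ins_start)) return(integer(length(a)))
  ov <- integer(length(a))
  for (i in seq_along(hap$ins_start)) {
    ov <- ov + pmax(0L, pmin(b, hap$ins_end[i]) - pmax(a, hap$ins_start[i]))
  }
  ov
}

#' Simulate reads and ideal alignments for a population
#'
#' Fragments are drawn per haplotype at `coverage/2`x, FR orientation, with
#' normally distributed insert sizes truncated at `2 * read_len`;
#' substitution errors are injected i.i.d.; base qualities are the Phred
#' score matching `base_error_rate`. The ideal alignment of each mate is
#' computed from truth: mapped iff at least `map_ref_frac` of its bases
#' derive from reference sequence, at its reference projection, MAPQ 60.
#'
#' @param pop population from [make_population()].
#' @param cfg the same [sim_config()].
#' @param seed optional RNG seed for this step; by default the RNG state
#'   left by [make_population()] is used (so [simulate_cohort()] is
#'   reproducible end to end).
#' @return `data.table`, one row per pair: `pair_id`, `sample_id`,
#'   `population`, `seq1`, `qual1`, `seq2`, `qual2`, ideal-alignment
#'   columns (`m1_mapped` ... `m2_mapq`) and `truth_class`.
#' @export
simulate_reads <- function(pop, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rl <- cfg$read_len
  qchar <- if (cfg$base_error_rate <= 0) "J" else
    intToUtf8(min(41L, as.integer(round(-10 * log10(cfg$base_error_rate)))) + 33L)
  qual <- strrep(qchar, rl)
  out <- vector("list", nrow(pop$samples) * cfg$n_chroms * 2L)
  slot <- 0L
  for (si in seq_len(nrow(pop$samples))) {
    sid <- pop$samples$sample_id[si]
    popl <- pop$samples$population[si]
    for (ci in seq_len(cfg$n_chroms)) {
      chrom_name <- paste0("chr", ci)
      for (hi in 1:2) {
        am <- pop$hap_alleles[[hi]]
        alleles <- setNames(as.integer(am[si, ]), colnames(am))
        ins_sub <- pop$insertions[chrom == chrom_name &
                                    alleles[ins_id] == 1L]
        hap <- build_haplotype(pop$reference[[chrom_name]], copy(ins_sub))
        hl <- nchar(hap$seq)
        n_pairs <- as.integer(round(cfg$coverage / 2 * hl / (2 * rl)))
        if (n_pairs == 0L) next
        isize <- pmin(pmax(as.integer(round(rnorm(n_pairs, cfg$insert_mean,
                                                  cfg$insert_sd))),
                           2L * rl), hl)
        start <- as.integer(floor(runif(n_pairs, 0, hl - isize + 1)))
        la <- start; lb <- start + rl              # left read interval
        ra <- start + isize - rl; rb <- start + isize
        lseq <- substring(hap$seq, la + 1L, lb)
        rseq <- revcomp(substring(hap$seq, ra + 1L, rb))
        lov <- insert_overlap(la, lb, hap)
        rov <- insert_overlap(ra, rb, hap)
        max_ins <- as.integer(floor((1 - cfg$map_ref_frac) * rl))
        lmap <- lov <= max_ins
        rmap <- rov <= max_ins
        # leftmost reference-derived base of each mate
        lstarts <- adjust_start(la, hap)
        rstarts <- adjust_start(ra, hap)
        lpos <- project_to_ref(lstarts, hap)
        rpos <- project_to_ref(rstarts, hap)
        flip <- runif(n_pairs) < 0.5
        pair_id <- sprintf("%s_%s_h%d_%06d", sid, chrom_name, hi, seq_len(n_pairs))
        dt <- data.table(
          pair_id = pair_id, sample_id = sid, population = popl,
          seq1 = fifelse(flip, rseq, lseq), qual1 = qual,
          seq2 = fifelse(flip, lseq, rseq), qual2 = qual,
          m1_mapped = fifelse(flip, rmap, lmap),
          m1_chrom = fifelse(fifelse(flip, rmap, lmap), chrom_name, NA_character_),
          m1_pos = fifelse(fifelse(flip, rmap, lmap),
                           fifelse(flip, rpos, lpos), NA_integer_),
          m1_strand = fifelse(fifelse(flip, rmap, lmap),
                              fifelse(flip, "-", "+"), NA_character_),
          m1_mapq = fifelse(fifelse(flip, rmap, lmap), 60L, NA_integer_),
          m2_mapped = fifelse(flip, lmap, rmap),
          m2_chrom = fifelse(fifelse(flip, lmap, rmap), chrom_name, NA_character_),
          m2_pos = fifelse(fifelse(flip, lmap, rmap),
                           fifelse(flip, lpos, rpos), NA_integer_),
          m2_strand = fifelse(fifelse(flip, lmap, rmap),
                              fifelse(flip, "+", "-"), NA_character_),
          m2_mapq = fifelse(fifelse(flip, lmap, rmap), 60L, NA_integer_))
        dt[, truth_class := fifelse(m1_mapped & m2_mapped, "concordant",
                             fifelse(!m1_mapped & !m2_mapped, "full_orphan",
                                     "oea"))]
        out[[slot <- slot + 1L]] <- dt
      }
    }
  }
  reads <- rbindlist(out[seq_len(slot)])
  inject_errors(reads, cfg)
}

## leftmost reference-derived base: a start inside an insertion advances to
## the insertion's end (in hap coords)
adjust_start <- function(a, hap) {
  if (!length(hap$ins_start)) return(a)
  j <- findInterval(a, hap$ins_start)
  inside <- j > 0L & a < hap$ins_end[pmax(j, 1L)]
  a[inside] <- hap$ins_end[j[inside]]
  a
}

## i.i.d. substitution errors on both mates, in place
inject_errors <- function(reads, cfg) {
  e <- cfg$base_error_rate
  if (e <= 0 || !nrow(reads)) return(reads)
  bases <- c("A", "C", "G", "T")
  for (col in c("seq1", "seq2")) {
    seqs <- reads[[col]]
    n_err <- rbinom(length(seqs), nchar(seqs), e)
    k <- 1L
    while (k <= max(n_err)) {
      # one substitution round for every read still owing >= k errors
      # (positions drawn independently; coinciding draws are negligible at
      # realistic error rates)
      idx <- which(n_err >= k)
      s <- seqs[idx]
      pos <- 1L + as.integer(floor(runif(length(idx)) * nchar(s)))
      old <- match(substr(s, pos, pos), bases)
      shift <- sample.int(3L, length(idx), replace = TRUE)
      substr(s, pos, pos) <- bases[((old - 1L + shift) %% 4L) + 1L]
      seqs[idx] <- s
      k <- k + 1L
    }
    set(reads, j = col, value = seqs)
  }
  reads
}

#' Simulate a complete cohort
#'
#' [make_population()] plus [simulate_reads()] under one seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `pop` (see [make_population()]) and `pairs` (see
#'   [simulate_reads()]).
#' @export
simulate_cohort <- function(cfg) {
  pop <- make_population(cfg)
  pairs <- simulate_reads(pop, cfg)
  list(pop = pop, pairs = pairs, cfg = cfg)
}

#' Write a simulated cohort to disk
#'
#' `ref.fa`, `truth.json`, and per-sample `X_1.fastq` / `X_2.fastq` /
#' `X.sam` (name-grouped, with `@SQ` header).
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(setNames(as.character(sim$pop$reference),
                       names(sim$pop$reference)), file.path(dir, "ref.fa"))
  truth <- list(
    insertions = as.data.frame(sim$pop$insertions),
    genotypes = as.data.frame(as.table(sim$pop$genotypes)),
    samples = as.data.frame(sim$pop$samples))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  ref_lengths <- setNames(nchar(sim$pop$reference), names(sim$pop$reference))
  for (sid in sim$pop$samples$sample_id) {
    p <- sim$pairs[sample_id == sid]
    write_fastq_pairs(p, file.path(dir, paste0(sid, "_1.fastq")),
                      file.path(dir, paste0(sid, "_2.fastq")))
    write_sam(p, ref_lengths, file.path(dir, paste0(sid, ".sam")), pairs = p)
  }
  invisible(dir)
}
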