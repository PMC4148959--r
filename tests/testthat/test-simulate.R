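test_that("config validation rejects crowded or misplaced insertions", {
  expect_error(sim_config(insertions = data.frame(
    len = 200L, chrom = "chr1", pos = c(10000L, 12000L), freq = 0.5,
    population = NA_character_)), "min_spacing")
  expect_error(sim_config(ref_len = 5000L, insertions = data.frame(
    len = 200L, chrom = "chr2", pos = 1000L, freq = 0.5,
    population = NA_character_)))
})

test_that("degenerate frequencies behave: zero insertions and freq 1", {
  cfg0 <- sim_config(ref_len = 10000L, n_individuals = c(EUR = 3L),
                     insertions = data.frame(len = integer(0),
                                             chrom = character(0),
                                             pos = integer(0),
                                             freq = numeric(0)),
                     seed = 2L, base_error_rate = 0)
  pop0 <- make_population(cfg0)
  sim0 <- simulate_reads(pop0, cfg0)
  # every read is an exact substring of the reference
  ref <- pop0$reference[["chr1"]]
  hits <- vapply(seq_len(min(200L, nrow(sim0))), function(i) {
    grepl(sim0$seq1[i], ref, fixed = TRUE) ||
      grepl(revcomp(sim0$seq1[i]), ref, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  expect_true(all(sim0$truth_class == "concordant"))
  cfg1 <- sim_config(ref_len = 20000L, n_individuals = c(AFR = 6L),
                     insertions = data.frame(len = 300L, chrom = "chr1",
                                             pos = 10000L, freq = 1.0,
                                             population = NA_character_),
                     seed = 3L)
  pop1 <- make_population(cfg1)
  expect_true(all(pop1$genotypes == 2L))
})

test_that("realized allele frequencies stay within 3 SE of the target", {
  for (s in 1:20) {
    cfg <- sim_config(ref_len = 15000L,
                      n_individuals = c(EUR = 70L, ASN = 70L, AFR = 60L),
                      insertions = data.frame(len = 200L, chrom = "chr1",
                                              pos = 7000L, freq = 0.3,
                                              population = NA_character_),
                      seed = s)
    pop <- make_population(cfg)
    f_hat <- mean(pop$genotypes[, 1]) / 2
    se <- sqrt(0.3 * 0.7 / (2 * 200))
    expect_lte(abs(f_hat - 0.3), 3 * se)
  }
})

test_that("read-pair count matches the coverage arithmetic within 5%", {
  cfg <- sim_config(ref_len = 100000L, n_individuals = c(EUR = 1L),
                    insertions = data.frame(len = integer(0),
                                            chrom = character(0),
                                            pos = integer(0),
                                            freq = numeric(0)),
                    coverage = 4, read_len = 100L, seed = 4L)
  sim <- simulate_cohort(cfg)
  expected <- 4 * 100000 / (2 * 100)
  expect_lt(abs(nrow(sim$pairs) - expected) / expected, 0.05)
})

test_that("identical seeds give byte-identical cohorts and FASTQ output", {
  cfg <- sim_config(ref_len = 15000L, n_individuals = c(EUR = 3L, AFR = 3L),
                    insertions = data.frame(len = 250L, chrom = "chr1",
                                            pos = 7000L, freq = 0.5,
                                            population = NA_character_),
                    seed = 11L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_equal(s1$pairs, s2$pairs)
  expect_equal(s1$pop$reference, s2$pop$reference)
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(s1, d1); write_cohort(s2, d2)
  sid <- s1$pop$samples$sample_id[1]
  f1 <- file.path(d1, paste0(sid, "_1.fastq"))
  f2 <- file.path(d2, paste0(sid, "_1.fastq"))
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the ideal aligner reproduces the OEA geometry", {
  cfg <- sim_config(ref_len = 30000L, n_individuals = c(EUR = 15L),
                    insertions = data.frame(len = 500L, chrom = "chr1",
                                            pos = 15000L, freq = 1.0,
                                            population = NA_character_),
                    seed = 13L)
  sim <- simulate_cohort(cfg)
  oea <- sim$pairs[truth_class == "oea"]
  expect_gt(nrow(oea), 0L)
  # exactly one mate mapped; anchors hug the insertion point
  expect_true(all(xor(oea$m1_mapped, oea$m2_mapped)))
  anchor_pos <- ifelse(oea$m1_mapped, oea$m1_pos, oea$m2_pos)
  expect_true(all(abs(anchor_pos - 15000L) < cfg$insert_mean + 4 * 30 + 100))
  # pairs wholly inside the 500 nt insertion are full orphans
  fo <- sim$pairs[truth_class == "full_orphan"]
  expect_gt(nrow(fo), 0L)
  expect_true(all(!fo$m1_mapped & !fo$m2_mapped))
  # concordant pairs pass the classifier as concordant
  conc <- classify_pairs(sim$pairs[truth_class == "concordant"], 20L)
  expect_true(all(conc == "CONCORDANT"))
})

test_that("OEA counts track the boundary-geometry expectation across seeds", {
  # a fragment yields an OEA pair when it straddles a boundary with one
  # read >= 95% on reference and its mate > 5% inside the insert; with
  # insert length well above fragment length both boundaries contribute
  # roughly (insert_mean - read_len) of eligible fragment starts per
  # haplotype at rate coverage/2 / (2 * read_len)
  counts <- integer(10)
  expected <- numeric(10)
  for (s in 1:10) {
    cfg <- sim_config(ref_len = 20000L, n_individuals = c(EUR = 10L),
                      insertions = data.frame(len = 600L, chrom = "chr1",
                                              pos = 10000L, freq = 1.0,
                                              population = NA_character_),
                      seed = 100L + s)
    sim <- simulate_cohort(cfg)
    counts[s] <- sum(sim$pairs$truth_class == "oea")
    n_hap <- 2L * 10L
    pair_rate <- cfg$coverage / 2 / (2 * cfg$read_len)   # pairs per hap base
    expected[s] <- 2 * n_hap * pair_rate * (cfg$insert_mean - cfg$read_len)
  }
  # within 3 SE of the mean expectation (Poisson-ish)
  se <- sqrt(mean(expected))
  expect_lt(abs(mean(counts) - mean(expected)), 3 * se)
})
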