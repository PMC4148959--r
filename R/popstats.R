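## Population-stratification statistics on carrier/allele frequencies:
## allele-count reconstruction from printed frequencies and a two-sided
## Fisher's exact test of African vs pooled non-African counts.

#' Reconstruct an integer allele count from a printed frequency
#'
#' `round(freq * n * ploidy)` with ties rounded half up, so a frequency
#' printed at two decimals recovers the count it was derived from.
#'
#' @param freq frequency in `[0, 1]` (vectorised).
#' @param n number of samples.
#' @param ploidy copies per sample (2 for diploid allele counts, 1 to treat
#'   printed values as carrier frequencies).
#' @return integer count(s).
#' @export
reconstruct_counts <- function(freq, n, ploidy = 2L) {
  stopifnot(all(freq >= 0 & freq <= 1))
  as.integer(floor(freq * n * ploidy + 0.5))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test: the p-value sums hypergeometric probabilities of
#' all tables with the observed margins whose probability does not exceed
#' the observed table's. A degenerate margin (a zero row or column sum)
#' returns `p = 1`.
#'
#' @param a,b,c,d cell counts (rows: groups; columns: allele present /
#'   absent), or `a` may be a 2x2 matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    m <- a
  } else {
    m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  }
  stopifnot(all(m >= 0), all(m == floor(m)))
  if (sum(m) == 0 || any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1.0)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Per-micSeq stratification report (African vs pooled non-African)
#'
#' For each row, allele counts are reconstructed per population
#' ([reconstruct_counts()]), African counts are tested against the pooled
#' non-African counts with [fisher_exact_2x2()], and the African-maximum
#' flag is set iff the African frequency strictly exceeds both others.
#'
#' @param freqs `data.frame`/`data.table` with columns `id`, `freq_eur`,
#'   `freq_asn`, `freq_afr`.
#' @param n_samples named vector/list with `eur`, `asn`, `afr` sample sizes.
#' @param ploidy copies per sample (see [reconstruct_counts()]).
#' @param alpha significance level for the summary count.
#' @return `data.table(id, freq_eur, freq_asn, freq_afr, afr_count,
#'   nonafr_count, p, african_max, significant)` with attribute `summary`
#'   (`list(n_african_max, n_significant)`).
#' @export
stratification_report <- function(freqs, n_samples, ploidy = 2L,
                                  alpha = 0.05) {
  freqs <- as.data.table(freqs)
  n_eur <- n_samples[["eur"]]; n_asn <- n_samples[["asn"]]
  n_afr <- n_samples[["afr"]]
  out <- freqs[, {
    afr_c <- reconstruct_counts(freq_afr, n_afr, ploidy)
    non_c <- reconstruct_counts(freq_eur, n_eur, ploidy) +
      reconstruct_counts(freq_asn, n_asn, ploidy)
    afr_tot <- n_afr * ploidy
    non_tot <- (n_eur + n_asn) * ploidy
    p <- mapply(function(ac, nc) fisher_exact_2x2(
      ac, afr_tot - ac, nc, non_tot - nc), afr_c, non_c)
    .(id = id, freq_eur = freq_eur, freq_asn = freq_asn, freq_afr = freq_afr,
      afr_count = afr_c, nonafr_count = non_c, p = p,
      african_max = freq_afr > freq_eur & freq_afr > freq_asn,
      significant = p < alpha)
  }]
  setattr(out, "summary", list(n_african_max = sum(out$african_max),
                               n_significant = sum(out$significant)))
  out[]
}

#' Packaged validation frequency table
#'
#' Carrier/allele frequencies of 15 experimentally genotyped micSeqs in 38
#' validation individuals (14 European, 12 Asian, 12 African), shipped as a
#' plain-text fixture.
#'
#' @return `data.table(id, freq_eur, freq_asn, freq_afr)` plus attribute
#'   `n_samples = list(eur = 14, asn = 12, afr = 12)`.
#' @export
micseq_validation_freqs <- function() {
  path <- system.file("extdata", "validation_freqs.tsv", package = "micseqr",
                      mustWork = TRUE)
  dt <- fread(path)
  setattr(dt, "n_samples", list(eur = 14L, asn = 12L, afr = 12L))
  dt[]
}
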