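#' Reverse-complement character DNA sequences
#'
#' Vectorised over a character vector; tolerates `N`.
#'
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Decode / encode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return `phred_to_int`: list of integer vectors; `int_to_phred`:
#'   character vector.
#' @export
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

#' @rdname phred_to_int
#' @param q list of integer vectors (or one integer vector) of Phred scores.
#' @export
int_to_phred <- function(q) {
  if (!is.list(q)) q <- list(q)
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

## random DNA, seeded by caller
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

## all substrings of width w (k-mers) of one string; character(0) if too short
seq_kmers <- function(s, w) {
  L <- nchar(s)
  if (L < w) return(character(0))
  substring(s, seq_len(L - w + 1L), seq_len(L - w + 1L) + w - 1L)
}

## k-mers of many strings as one data.table(kmer, read_idx)
seqs_kmers_dt <- function(seqs, w) {
  L <- nchar(seqs)
  keep <- L >= w
  idx <- which(keep)
  if (!length(idx)) return(data.table(kmer = character(0), read_idx = integer(0)))
  nk <- L[idx] - w + 1L
  read_idx <- rep(idx, nk)
  starts <- sequence(nk)
  data.table(kmer = substring(seqs[read_idx], starts, starts + w - 1L),
             read_idx = read_idx, off = starts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
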