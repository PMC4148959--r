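## Sliding-window quality trimming. A read is scanned 5'->3' in windows of
## `window` positions stepping by one; at the first window whose mean Phred
## quality drops below `min_mean_qual` the read is truncated at that window's
## first base. Pairs are dropped whole if either mate falls below `min_len`.

#' Trimming configuration
#'
#' Defaults mirror the conventional sliding-window trim: window of 4
#' positions, mean quality threshold Q25, minimum surviving length 20 nt.
#' Trailing windows shorter than `window` are averaged over their actual
#' length.
#'
#' @param window window width in read positions.
#' @param min_mean_qual minimum mean Phred quality per window.
#' @param min_len minimum retained read length; shorter results are dropped.
#' @return a `trim_config` list.
#' @export
trim_config <- function(window = 4L, min_mean_qual = 25, min_len = 20L) {
  stopifnot(window >= 1L, min_len >= 1L)
  structure(list(window = as.integer(window),
                 min_mean_qual = min_mean_qual,
                 min_len = as.integer(min_len)),
            class = "trim_config")
}

## length of the retained prefix given integer qualities (0 = drop all)
trim_cut_point <- function(q, cfg) {
  L <- length(q)
  if (L == 0L) return(0L)
  w <- cfg$window
  # running mean over windows starting at every position (trailing windows
  # shortened to the read end)
  cs <- cumsum(c(0, q))
  starts <- seq_len(L)
  ends <- pmin(starts + w - 1L, L)
  means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
  bad <- which(means < cfg$min_mean_qual)
  if (!length(bad)) L else bad[1] - 1L
}

#' Trim a single read by sliding-window quality
#'
#' @param seq DNA string.
#' @param qual integer Phred vector or Phred+33 string of the same length.
#' @param cfg a [trim_config()].
#' @return `list(seq, qual)` with the retained prefix, or `NULL` when the
#'   read is dropped (retained length below `cfg$min_len`).
#' @export
trim_read <- function(seq, qual, cfg = trim_config()) {
  if (is.character(qual)) qual <- utf8ToInt(qual) - 33L
  if (nchar(seq) != length(qual)) stop("seq and qual lengths differ")
  cut <- trim_cut_point(qual, cfg)
  if (cut < cfg$min_len) return(NULL)
  list(seq = substr(seq, 1L, cut), qual = qual[seq_len(cut)])
}

#' Trim both mates of a pair; drop the pair if either mate drops
#'
#' @param pair list or one-row data.frame with `seq1`, `qual1`, `seq2`,
#'   `qual2` (qualities as Phred+33 strings or integer vectors).
#' @param cfg a [trim_config()].
#' @return the pair with trimmed sequences/qualities, or `NULL` if dropped.
#' @export
trim_pair <- function(pair, cfg = trim_config()) {
  t1 <- trim_read(pair$seq1[[1]], pair$qual1[[1]], cfg)
  if (is.null(t1)) return(NULL)
  t2 <- trim_read(pair$seq2[[1]], pair$qual2[[1]], cfg)
  if (is.null(t2)) return(NULL)
  out <- pair
  out$seq1 <- t1$seq; out$qual1 <- intToUtf8(t1$qual + 33L)
  out$seq2 <- t2$seq; out$qual2 <- intToUtf8(t2$qual + 33L)
  out
}

#' Trim a whole pair table
#'
#' Vectorised driver for [trim_pair()]. The cut point depends only on the
#' quality string, so it is computed once per distinct quality string -
#' cohorts with a homogeneous quality model trim in O(1) scans.
#'
#' @param pairs pair table (see [read_fastq_pairs()]).
#' @param cfg a [trim_config()].
#' @return list with `pairs` (trimmed survivors) and counts `n_in`,
#'   `n_dropped`.
#' @export
trim_pairs <- function(pairs, cfg = trim_config()) {
  cut_for <- function(quals) {
    uq <- unique(quals)
    cuts <- vapply(uq, function(q) trim_cut_point(utf8ToInt(q) - 33L, cfg), integer(1))
    cuts[match(quals, uq)]
  }
  c1 <- cut_for(pairs$qual1)
  c2 <- cut_for(pairs$qual2)
  keep <- c1 >= cfg$min_len & c2 >= cfg$min_len
  out <- pairs[keep]
  k1 <- c1[keep]; k2 <- c2[keep]
  out[, `:=`(seq1 = substr(seq1, 1L, k1), qual1 = substr(qual1, 1L, k1),
             seq2 = substr(seq2, 1L, k2), qual2 = substr(qual2, 1L, k2))]
  list(pairs = out, n_in = nrow(pairs), n_dropped = sum(!keep))
}
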