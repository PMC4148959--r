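# Independent oracles shared by the unit and acceptance suites. Each is a
# direct, brute-force restatement of the definition it checks, kept free of
# the package's own code paths.

# sliding-window trimming: evaluate every window mean independently and
# truncate at the first failing window's first base
oracle_cut <- function(q, window, min_mean) {
  L <- length(q)
  for (s in seq_len(L)) {
    e <- min(s + window - 1L, L)
    if (mean(q[s:e]) < min_mean) return(s - 1L)
  }
  L
}

# O(n^2) anchor-window search over windows anchored at each position
window_oracle <- function(positions, window) {
  p <- sort(positions)
  best <- c(count = -1L, start = NA_integer_)
  for (s in p) {
    cnt <- sum(p >= s & p < s + window)
    if (cnt > best["count"]) best <- c(count = cnt, start = s)
  }
  best
}

# exhaustive two-sided Fisher: sum hypergeometric probabilities of all
# same-margin tables at most as probable as the observed one
fisher_oracle <- function(a, b, c, d, tol = 1e-7) {
  K <- a + b
  n1 <- a + c
  N <- a + b + c + d
  if (K == 0 || n1 == 0 || K == N || n1 == N) return(1.0)
  xs <- max(0, K + n1 - N):min(K, n1)
  probs <- dhyper(xs, n1, N - n1, K)
  obs <- dhyper(a, n1, N - n1, K)
  sum(probs[probs <= obs * (1 + tol)])
}

# recovery rule: a call recovers a truth insertion when they align at
# >= 95% identity over >= 80% of the shorter sequence (either strand)
recovers <- function(call_seq, truth_seq) {
  shorter <- min(nchar(call_seq), nchar(truth_seq))
  fwd <- local_align(call_seq, truth_seq)
  rev <- local_align(revcomp(call_seq), truth_seq)
  best <- if (rev$score > fwd$score) rev else fwd
  best$identity >= 0.95 && best$q_span >= 0.8 * shorter
}
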