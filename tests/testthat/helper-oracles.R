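# independent oracles used by the unit and acceptance tests; these stay
# deliberately separate from the package's own computational paths

# exact upper-tail Poisson probability by direct pmf summation
poisson_tail_oracle <- function(rc, lambda, kmax = 5000L) {
  if (rc == 0) return(1)
  k <- rc:kmax
  sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
}

# read set whose i-th window of `window` bp holds exactly rc[i] read starts
reads_with_window_counts <- function(rc, window = 100L) {
  starts <- unlist(lapply(seq_along(rc), function(i) {
    if (rc[i] == 0) return(integer())
    (i - 1L) * window + (seq_len(rc[i]) - 1L) %% window + 1L
  }))
  genome <- Biostrings::DNAStringSet(
    c(chr1 = strrep("A", length(rc) * window)))
  list(reads = mk_reads("chr1", starts, width = 49L), genome = genome)
}

# brute-force pmf of the digital-expression conditional distribution,
# straight from its closed form (log-transformed only to avoid overflow)
ac_pmf_oracle <- function(k, x, r) {
  exp(lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) +
        k * log(r) - (x + k + 1) * log(1 + r))
}

# brute-force two-sided p: term-by-term tail summation, doubled smaller tail
ac_p_oracle <- function(x, y, r, kmax = 20000L) {
  lower <- sum(ac_pmf_oracle(0:y, x, r))
  upper <- sum(ac_pmf_oracle(y:kmax, x, r))
  min(1, 2 * min(lower, upper))
}

# hand-rolled BH step-up (q_(i) = min_{j>=i} p_(j) m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}
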