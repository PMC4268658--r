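# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct lchoose arithmetic for the Fisher test,
# a naive O(m^2) step-up for BH, and plain O(n*m) scans for interval work.

# two-sided Fisher p by direct hypergeometric enumeration (lchoose, not dhyper)
oracle_fisher <- function(a, b, cc, d, rel_tol = 1e-7) {
  m <- a + b
  n <- cc + d
  k <- a + cc
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

# naive O(m^2) Benjamini-Hochberg step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    cands <- vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# brute-force: does query row i overlap (>= 1 bp, half-open) any feature row?
brute_overlap_any <- function(queries, features) {
  vapply(seq_len(nrow(queries)), function(i) {
    any(features$chrom == queries$chrom[i] &
          features$start < queries$end[i] &
          features$end > queries$start[i])
  }, logical(1))
}

# random interval set on a toy genome
random_intervals <- function(n, chroms = c("chr1", "chr2"), size = 1e5,
                             min_w = 50, max_w = 2000) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(size - wi, 1) - 1L, integer(1))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = s, end = s + w)
}

# exhaustive majority-vote annotation of one read (all alignments, no
# sampling), mirroring the documented rules independently of the package
oracle_annotate <- function(cat, hierarchy) {
  tab <- table(cat)
  winners <- names(tab)[tab == max(tab)]
  hierarchy[min(match(winners, hierarchy))]
}
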