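# Shared fixtures and independent oracles. The worked single-gene example
# has P_N = 11, P_S = 17 at n = 20 with 7/4 and 6/11 split at the 15%
# cutoff, D_N = 15, D_S = 8.

table2Gene <- function(mN = 500, mS = 200) {
  GeneVariation("worked_example",
                SFS(c(5, 2, 2, 1, 1, rep(0, 14)), sampleSize = 20),
                SFS(c(4, 2, 3, 2, 2, 1, 1, 1, rep(0, 6), 1, rep(0, 4)),
                    sampleSize = 20),
                dN = 15, dS = 8, mN = mN, mS = mS)
}

randomSFS <- function(n, lambda = 2, folded = FALSE) {
  len <- if (folded) n %/% 2L else n - 1L
  SFS(stats::rpois(len, lambda), sampleSize = n, folded = folded)
}

randomRecord <- function(n = 20, lambda = 2) {
  GeneVariation(paste0("g", sample.int(1e6, 1)),
                randomSFS(n, lambda), randomSFS(n, lambda),
                dN = stats::rpois(1, 8) + 1, dS = stats::rpois(1, 8) + 1,
                mN = 300, mS = 100)
}

# independent two-sided Fisher oracle: enumerate the full hypergeometric
# support for the observed margins and sum probabilities <= observed
# (with the same 1 + 1e-7 relative guard the conventional test uses)
fisherOracle <- function(a, b, c, d) {
  r1 <- a + c  # nonsynonymous row: polymorphism + divergence
  r2 <- b + d
  c1 <- a + b  # polymorphism column
  if (r1 == 0 || r2 == 0 || c1 == 0 || (a + b + c + d - c1) == 0)
    return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  pr <- stats::dhyper(k, r1, r2, c1)
  sum(pr[pr <= stats::dhyper(a, r1, r2, c1) * (1 + 1e-7)])
}

# brute-force projection oracle: expected downsampled SFS by enumerating
# every m-subset of n haplotypes for each source class
projectionOracle <- function(counts, n, m) {
  out <- numeric(m - 1)
  subsets <- utils::combn(n, m)
  for (i in seq_len(n - 1)) {
    if (counts[i] == 0) next
    derived <- seq_len(i)  # haplotypes 1..i carry the derived allele
    for (s in seq_len(ncol(subsets))) {
      j <- sum(subsets[, s] %in% derived)
      if (j >= 1 && j <= m - 1)
        out[j] <- out[j] + counts[i] / ncol(subsets)
    }
  }
  out
}
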