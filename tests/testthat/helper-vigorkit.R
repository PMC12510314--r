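# Shared fixtures, built in code.

# Long-hand transcription of the Weir & Cockerham (1984) haploid
# variance-component formulas (Weir 1996 ANOVA form), written sum-by-sum
# and independently of the package's vectorized implementation.
wc_haploid_oracle <- function(ref1, alt1, ref2, alt2) {
  n1 <- ref1 + alt1
  n2 <- ref2 + alt2
  p1 <- alt1 / n1
  p2 <- alt2 / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- ((n1 + n2) - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  a <- (msp - msg) / nc
  c(a = a, d = a + msg)
}

# Exhaustive mean pairwise Hamming distance per bp (pairwise-complete).
pi_pairwise_oracle <- function(alleles, span) {
  n <- nrow(alleles)
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(alleles[i, ]) & !is.na(alleles[j, ])
      # per-site pairwise-complete: each site contributes its mismatch
      # averaged over the pairs observing it
      tot <- tot + sum(alleles[i, ok] != alleles[j, ok])
      np <- np + 1
    }
  }
  tot / np / span
}

# Per-site pairwise-complete oracle (matches the n/(n-1) estimator under
# missingness): average mismatch fraction among observed pairs, per site.
pi_sitewise_oracle <- function(alleles, span) {
  s <- 0
  for (k in seq_len(ncol(alleles))) {
    x <- alleles[, k]
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) next
    mism <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) mism <- mism + (x[i] != x[j])
    s <- s + mism / choose(n, 2)
  }
  s / span
}

# Quadratic-depletion fraction bound solved by bisection on the bound
# complex concentration: (L - B)(T - B) = kd * B, B in [0, min(L, T)].
fraction_bound_bisection <- function(L, T, kd, tol = 1e-12) {
  f <- function(B) (L - B) * (T - B) - kd * B
  lo <- 0
  hi <- min(L, T)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / T
}

# Alignment of two clean clades separated by many fixed differences, with
# a few private mutations per taxon.
two_clade_alignment <- function(n_per_clade = 5, n_sites = 300,
                                n_fixed = 60, n_private = 3, seed = 42) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  anc <- sample(aa, n_sites, replace = TRUE)
  anc2 <- anc
  fixed_pos <- sample(n_sites, n_fixed)
  anc2[fixed_pos] <- vapply(anc[fixed_pos], function(x)
    sample(setdiff(aa, x), 1), character(1))
  mk <- function(base, label) {
    s <- base
    pos <- sample(n_sites, n_private)
    s[pos] <- vapply(s[pos], function(x) sample(setdiff(aa, x), 1),
                     character(1))
    paste(s, collapse = "")
  }
  seqs <- c(
    vapply(seq_len(n_per_clade), function(i) mk(anc), character(1)),
    vapply(seq_len(n_per_clade), function(i) mk(anc2), character(1))
  )
  names(seqs) <- c(paste0("A", seq_len(n_per_clade)),
                   paste0("B", seq_len(n_per_clade)))
  seqs
}

# Star-like alignment: independent private mutations only (no shared
# internal signal).
star_alignment <- function(n_taxa = 6, n_sites = 120, n_private = 6,
                           seed = 7) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  set.seed(seed)
  anc <- sample(aa, n_sites, replace = TRUE)
  seqs <- vapply(seq_len(n_taxa), function(i) {
    s <- anc
    pos <- sample(n_sites, n_private)
    s[pos] <- vapply(s[pos], function(x) sample(setdiff(aa, x), 1),
                     character(1))
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(n_taxa))
  seqs
}

.revcomp_test <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Reference with balanced CG / CHG / CHH cytosines.
balanced_bs_ref <- function(n_units = 20) {
  paste(rep("TACGTTCAGTTCATT", n_units), collapse = "")
}
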