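# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms.

# Maximum number of nested allowed base pairs, by exhaustive recursion over
# "first base unpaired or paired with some k" (no DP reuse of the package's
# Nussinov implementation).
brute_force_max_pairs <- function(seq, min_hairpin = 3L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  rec <- function(i, j) {
    if (j - i < min_hairpin + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + min_hairpin + 1L):j) {
      if (ok(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  n <- length(ch)
  if (n < min_hairpin + 2L) return(0L)
  rec(1L, n)
}

# AUC by exhaustive pair counting (concordant = 1, tied = 1/2).
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# All valid structures up to a length, pooled (used by several property tests).
all_structures_up_to <- function(L, min_hairpin = 3L) {
  unlist(lapply(seq(0L, L), enumerate_structures, min_hairpin = min_hairpin))
}

# Random dot-bracket structure drawn uniformly from the exhaustive enumeration.
sample_structures <- function(n, L, seed) {
  pool <- enumerate_structures(L)
  set.seed(seed)
  sample(pool, n, replace = TRUE)
}
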