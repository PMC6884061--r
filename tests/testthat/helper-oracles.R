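# Independent oracles used across tests.

# Pure-R brute-force best global alignment score: recursion over all
# monotone op paths with affine gap-run state.  Independent of the compiled
# code; only usable for very short sequences.
r_enum_global <- function(a, b, scheme) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      s <- if (av[i] == bv[j]) scheme$match else scheme$mismatch
      best <- max(best, s + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= n) {
      cost <- if (state == 1L) scheme$gap_extend else
        scheme$gap_open + scheme$gap_extend
      best <- max(best, cost + rec(i + 1L, j, 1L))
    }
    if (j <= m) {
      cost <- if (state == 2L) scheme$gap_extend else
        scheme$gap_open + scheme$gap_extend
      best <- max(best, cost + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, -1L)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Exact upper binomial tail via explicit summation of choose() terms
# (independent of stats::pbinom).
exact_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), 0))
}

# Expected pairwise dissimilarity between two copies mutated independently
# from the ancestor at per-site rate r, uniform over 3 alternatives.
expected_pairwise <- function(r) 2 * r - (4 / 3) * r^2
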