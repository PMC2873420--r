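# Independent brute-force alignment oracle.
#
# A pairwise alignment is equivalent to an increasing matching of aligned
# residue pairs; residues between consecutive pairs form one gap run per
# sequence (any other arrangement costs extra gap opens and can only lower
# the score, so the maximum is unaffected). The oracle enumerates every
# increasing matching recursively and scores it directly:
#   score = sum of pair scores - affine gap costs,
# with a gap of length k costing gap_open + k * gap_extend. Local scores
# ignore terminal gaps (and include the empty alignment at 0); global scores
# charge terminal gaps and include the all-gap alignment.
#
# This shares no code with the DP engine. Exhaustive and exact for short
# sequences: C(m+n, m) matchings, 12870 at 8x8.
oracle_scores <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  S <- scheme$matrix
  gap <- function(k) if (k > 0) scheme$gap_open + k * scheme$gap_extend else 0
  best_local <- 0
  best_global <- -(gap(m) + gap(n)) # empty matching
  rec <- function(ilast, jlast, sc, ifirst, jfirst) {
    best_local <<- max(best_local, sc)
    best_global <<- max(best_global,
                        sc - gap(ifirst - 1) - gap(jfirst - 1) -
                          gap(m - ilast) - gap(n - jlast))
    if (ilast < m && jlast < n) {
      for (i in (ilast + 1):m) {
        for (j in (jlast + 1):n) {
          sc2 <- sc + S[A[i], B[j]] - gap(i - ilast - 1) - gap(j - jlast - 1)
          rec(i, j, sc2, ifirst, jfirst)
        }
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      rec(i, j, S[A[i], B[j]], i, j)
    }
  }
  list(local = best_local, global = best_global)
}
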