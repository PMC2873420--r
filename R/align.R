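#' Maximum-scoring local (Smith-Waterman) alignment
#'
#' Affine-gap local alignment under a [substitution_scheme()]. Tie-breaking is
#' deterministic: among equal-scoring end cells the smallest (query end,
#' target end) is taken, and the traceback prefers aligned columns over gaps.
#' 'X' residues score 0 against everything and never count as identities.
#'
#' @param query,target peptide strings (non-empty, residues `ARNDCQEGHILKMFPSTWYV`
#'   plus `X`).
#' @param scheme a [substitution_scheme()].
#' @return A `local_alignment` object: list with `query_interval` and
#'   `target_interval` (0-based half-open), `aligned_query`, `aligned_target`
#'   (gapped strings), `score`, `identities`.
#' @export
local_align <- function(query, target, scheme = substitution_scheme()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  a <- encode_peptide(query, "query")
  b <- encode_peptide(target, "target")
  res <- .gotoh_local(a, b, expanded_matrix(scheme),
                      scheme$gap_open, scheme$gap_extend)
  build_alignment(res, query, target, local = TRUE)
}

#' End-to-end global (Needleman-Wunsch) alignment
#'
#' Affine-gap global alignment spanning both sequences entirely; the result
#' has the same shape as [local_align()] with intervals covering both full
#' sequences. Global scores may be negative.
#'
#' @inheritParams local_align
#' @param a,b peptide strings.
#' @return A `local_alignment` object spanning both sequences.
#' @export
global_align <- function(a, b, scheme = substitution_scheme()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  ai <- encode_peptide(a, "query")
  bi <- encode_peptide(b, "target")
  res <- .gotoh_global(ai, bi, expanded_matrix(scheme),
                       scheme$gap_open, scheme$gap_extend)
  build_alignment(res, a, b, local = FALSE)
}

build_alignment <- function(res, query, target, local) {
  path <- res$path
  if (!nzchar(path)) {
    aln <- list(query_interval = c(0L, 0L), target_interval = c(0L, 0L),
                aligned_query = "", aligned_target = "",
                score = res$score, identities = 0L)
    return(structure(aln, class = "local_alignment"))
  }
  ops <- strsplit(path, "")[[1]]
  qs <- res$qstart # 0-based start (residues consumed before alignment)
  ts <- res$tstart
  qchars <- strsplit(query, "")[[1]]
  tchars <- strsplit(target, "")[[1]]
  nq <- sum(ops != "I")
  nt <- sum(ops != "D")
  aq <- character(length(ops))
  at <- character(length(ops))
  qi <- qs
  ti <- ts
  ident <- 0L
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == "M") {
      qi <- qi + 1L; ti <- ti + 1L
      aq[k] <- qchars[qi]; at[k] <- tchars[ti]
      if (aq[k] == at[k] && aq[k] != "X") ident <- ident + 1L
    } else if (op == "D") {
      qi <- qi + 1L
      aq[k] <- qchars[qi]; at[k] <- "-"
    } else {
      ti <- ti + 1L
      aq[k] <- "-"; at[k] <- tchars[ti]
    }
  }
  aln <- list(
    query_interval = c(qs, qs + nq),
    target_interval = c(ts, ts + nt),
    aligned_query = paste(aq, collapse = ""),
    aligned_target = paste(at, collapse = ""),
    score = res$score,
    identities = ident
  )
  structure(aln, class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("alignment score %g, identities %d, query [%d,%d), target [%d,%d)\n",
              x$score, x$identities,
              x$query_interval[1], x$query_interval[2],
              x$target_interval[1], x$target_interval[2]))
  if (nzchar(x$aligned_query)) {
    cat(" ", x$aligned_query, "\n ", x$aligned_target, "\n", sep = "")
  }
  invisible(x)
}

#' Corrected percent identity
#'
#' The survey's acceptance statistic: identical aligned positions divided by
#' the full ungapped query length, times 100. Dividing by the query length
#' (not the alignment length) is what makes the PID "corrected" — partial
#' hits are penalised for the query residues they fail to cover.
#'
#' @param aln a `local_alignment` from [local_align()] or [global_align()].
#' @param query_length full ungapped length of the query.
#' @return percent in `[0, 100]`.
#' @export
corrected_pid <- function(aln, query_length) {
  if (!is.numeric(query_length) || query_length <= 0)
    stop("query_length must be a positive count")
  span <- aln$query_interval[2] - aln$query_interval[1]
  if (query_length < span)
    stop("query_length smaller than the aligned query interval")
  100 * aln$identities / query_length
}

#' Empirical shuffle-test significance for a local alignment score
#'
#' Distribution-free replacement for analytic alignment statistics: the
#' target is shuffled (composition-preserving) `n_shuffles` times, the best
#' local score against the query recomputed each time, and the p-value is the
#' plus-one estimator `(1 + #[null >= score]) / (n_shuffles + 1)`.
#'
#' @param score observed local alignment score.
#' @param query,target the original peptides.
#' @param scheme a [substitution_scheme()].
#' @param n_shuffles number of shuffles, at least 99.
#' @param rng_seed integer seed; the test is reproducible given the seed.
#' @return list with `p_value` and `n_shuffles` (class `significance_estimate`).
#' @export
empirical_significance <- function(score, query, target,
                                   scheme = substitution_scheme(),
                                   n_shuffles = 199, rng_seed = 1L) {
  if (n_shuffles < 99) stop("n_shuffles must be at least 99")
  a <- encode_peptide(query, "query")
  b <- encode_peptide(target, "target")
  nulls <- with_seed(rng_seed, {
    .shuffled_scores(a, b, expanded_matrix(scheme),
                     scheme$gap_open, scheme$gap_extend, as.integer(n_shuffles))
  })
  p <- (1 + sum(nulls >= score)) / (n_shuffles + 1)
  structure(list(p_value = p, n_shuffles = as.integer(n_shuffles)),
            class = "significance_estimate")
}

# run code under a local RNG seed without disturbing the caller's RNG state;
# the seed expression is forced first (it may itself consume the caller's RNG)
with_seed <- function(seed, code) {
  force(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}
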