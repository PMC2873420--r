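#' Build an ungapped position-specific log-odds profile
#'
#' Column scores are `ln((count + pseudocount * b_r) / ((n + pseudocount) *
#' b_r))` for residue r with background frequency `b_r` over n instances —
#' a Laplace-smoothed log-odds against the background. Instances must be
#' pre-aligned and equal length (gap columns removed).
#'
#' @param instances character vector of equal-length domain peptides (>= 2).
#' @param background residue frequencies over the 20 residues.
#' @param pseudocount smoothing weight (default 1).
#' @param name domain label (`AD`, `B`, `C`, `D`, `DD`, ...).
#' @return object of class `domain_profile`: `name`, `columns` (L x 20 score
#'   matrix), `length`, `score_threshold` (NA until calibrated).
#' @export
build_profile <- function(instances, background = aa_background(),
                          pseudocount = 1, name = "domain") {
  if (length(instances) < 2) stop("at least 2 instances are required")
  lens <- nchar(instances)
  if (length(unique(lens)) != 1)
    stop("instances must be pre-aligned to equal length")
  L <- lens[1]
  n <- length(instances)
  background <- background[AA20] / sum(background[AA20])
  mat <- matrix(0, L, 20, dimnames = list(NULL, AA20))
  chars <- do.call(rbind, strsplit(instances, ""))
  for (pos in seq_len(L)) {
    counts <- table(factor(chars[, pos], levels = AA20))
    mat[pos, ] <- log((as.numeric(counts) + pseudocount * background) /
                        ((n + pseudocount) * background))
  }
  structure(list(name = name, columns = mat, length = L,
                 score_threshold = NA_real_),
            class = "domain_profile")
}

# window scores at every offset; 'X' residues contribute 0
profile_window_scores <- function(sequence, profile) {
  idx <- encode_peptide(sequence) + 1L # 1..21, 21 = X
  L <- profile$length
  n <- length(idx)
  if (n < L) return(numeric(0))
  cols <- cbind(profile$columns, X = 0)
  n_off <- n - L + 1L
  scores <- numeric(n_off)
  # column-sliced accumulation keeps this vectorised over offsets
  for (k in seq_len(L)) {
    scores <- scores + cols[k, idx[k:(k + n_off - 1L)]]
  }
  scores
}

#' Scan a protein with a calibrated profile
#'
#' Sliding-window sum of column scores at every offset; reports maximal
#' non-overlapping windows with score at or above the profile threshold,
#' chosen greedily by descending score (ties by smaller start).
#'
#' @param protein peptide string (or a 1-row [proteome()] slice).
#' @param profile a calibrated [build_profile()].
#' @return data.frame of class `domain_annotations`: `domain`, `start`,
#'   `end` (0-based half-open), `score`. Empty if the protein is shorter
#'   than the profile.
#' @export
scan_profile <- function(protein, profile) {
  sequence <- if (is.character(protein)) protein else protein$sequence[1]
  thr <- profile$score_threshold
  if (is.na(thr))
    stop("profile '", profile$name, "' has no calibrated threshold")
  scores <- profile_window_scores(sequence, profile)
  empty <- data.frame(domain = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(scores)) return(empty)
  cand <- which(scores >= thr)
  if (!length(cand)) return(empty)
  cand <- cand[order(-scores[cand], cand)]
  taken <- logical(length(scores) + profile$length)
  rows <- empty
  for (o in cand) {
    span <- o:(o + profile$length - 1L)
    if (any(taken[span])) next
    taken[span] <- TRUE
    rows <- rbind(rows, data.frame(
      domain = profile$name, start = o - 1L, end = o - 1L + profile$length,
      score = scores[o], stringsAsFactors = FALSE))
  }
  rows <- rows[order(rows$start), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

#' Calibrate a profile's acceptance threshold on a shuffled-background null
#'
#' Threshold = the stated quantile (default 0.99) of best-window scores over
#' `n_null` random background proteins of the stated length. Seeded and
#' deterministic.
#'
#' @param profile a [build_profile()].
#' @param background residue frequencies.
#' @param n_null number of null proteins (>= 1000).
#' @param quantile null quantile for the threshold.
#' @param rng_seed integer seed.
#' @param null_length length of each null protein (default 300).
#' @return the profile with `score_threshold` set.
#' @export
calibrate_threshold <- function(profile, background = aa_background(),
                                n_null = 1000, quantile = 0.99,
                                rng_seed = 1L, null_length = 300L) {
  if (n_null < 1000) stop("n_null must be at least 1000")
  best <- with_seed(rng_seed, {
    vapply(seq_len(n_null), function(i) {
      s <- random_peptide(null_length, background)
      max(profile_window_scores(s, profile))
    }, numeric(1))
  })
  profile$score_threshold <- as.numeric(quantile(best, probs = quantile,
                                                 names = FALSE))
  profile
}

#' Ordered domain-architecture string of a protein
#'
#' Merges the DBD call (from the domain search) with profile annotations,
#' resolves overlaps by keeping the higher score, sorts by start coordinate
#' and joins with `-` (e.g. `"AD-DBD-B-C-DD"`). Absent domains are simply
#' omitted; a protein with no calls yields `""`.
#'
#' @param protein peptide string (or 1-row [proteome()] slice).
#' @param profiles list of calibrated [build_profile()]s.
#' @param dbd_call optional list/row with `start`, `end`, `score` (target
#'   coordinates of an accepted DBD hit).
#' @return single string; the annotation table is in `attr(, "annotations")`.
#' @export
architecture <- function(protein, profiles, dbd_call = NULL) {
  ann <- do.call(rbind, lapply(profiles, function(p) scan_profile(protein, p)))
  if (is.null(ann)) ann <- data.frame(domain = character(0),
                                      start = integer(0), end = integer(0),
                                      score = numeric(0),
                                      stringsAsFactors = FALSE)
  if (!is.null(dbd_call)) {
    ann <- rbind(ann, data.frame(domain = "DBD",
                                 start = as.integer(dbd_call$start),
                                 end = as.integer(dbd_call$end),
                                 score = as.numeric(dbd_call$score),
                                 stringsAsFactors = FALSE))
  }
  if (!nrow(ann)) {
    return(structure("", annotations = ann))
  }
  # overlap resolution: keep the higher score
  ann <- ann[order(-ann$score, ann$start), , drop = FALSE]
  kept <- ann[0, ]
  for (i in seq_len(nrow(ann))) {
    ov <- nrow(kept) > 0 &&
      any(ann$start[i] < kept$end & ann$end[i] > kept$start)
    if (!ov) kept <- rbind(kept, ann[i, ])
  }
  kept <- kept[order(kept$start), , drop = FALSE]
  rownames(kept) <- NULL
  structure(paste(kept$domain, collapse = "-"), annotations = kept)
}
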