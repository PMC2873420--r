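#' Substitution scheme for protein alignment
#'
#' Bundles a 20x20 residue similarity matrix, affine gap penalties and the
#' background residue frequencies used for null sequence generation and
#' profile log-odds. The default is BLOSUM62 with gap open 11 / extend 1,
#' the classic protein-search parameterisation; a gap of length k costs
#' `gap_open + k * gap_extend`.
#'
#' @param matrix 20x20 symmetric integer similarity matrix with the standard
#'   residue order `ARNDCQEGHILKMFPSTWYV` on rows and columns. Default:
#'   BLOSUM62 (from Biostrings).
#' @param gap_open positive integer gap-opening penalty.
#' @param gap_extend positive integer gap-extension penalty,
#'   `gap_open >= gap_extend >= 1`.
#' @param background named numeric vector of residue frequencies over the 20
#'   residues; defaults to the Robinson-Robinson frequencies used by BLAST.
#' @return An object of class `substitution_scheme`.
#' @export
substitution_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                                background = NULL) {
  if (is.null(matrix)) matrix <- blosum62_matrix()
  if (is.null(background)) background <- aa_background()
  if (!is.matrix(matrix) || nrow(matrix) != 20 || ncol(matrix) != 20)
    stop("matrix must be 20x20 over the standard residues")
  if (is.null(rownames(matrix))) {
    rownames(matrix) <- colnames(matrix) <- AA20
  }
  matrix <- matrix[AA20, AA20]
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop("gap penalties must satisfy gap_open >= gap_extend >= 1")
  background <- background[AA20]
  if (anyNA(background) || any(background <= 0))
    stop("background must be positive over all 20 residues")
  background <- background / sum(background)
  structure(
    list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
         background = background),
    class = "substitution_scheme"
  )
}

#' @export
print.substitution_scheme <- function(x, ...) {
  cat(sprintf("substitution_scheme: 20x20 matrix, gap open %g / extend %g\n",
              x$gap_open, x$gap_extend))
  invisible(x)
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "double"
  m
}

# Robinson-Robinson amino-acid frequencies (BLAST's protein background)
aa_background <- function() {
  b <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  b / sum(b)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-delimited matrix format used by NCBI BLAST
#' (`#` comment lines, a header row of residue letters, one labelled row per
#' residue) and returns the 20x20 core over the standard residues.
#'
#' @param path path to a matrix file.
#' @return numeric 20x20 matrix with residues as dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  missing <- setdiff(AA20, intersect(rownames(vals), colnames(vals)))
  if (length(missing))
    stop("matrix lacks standard residues: ", paste(missing, collapse = ","))
  vals[AA20, AA20]
}

# 21x21 scoring matrix including 'X' (scores 0 against everything),
# used by the DP engine
expanded_matrix <- function(scheme) {
  m <- matrix(0, 21, 21, dimnames = list(AA21, AA21))
  m[AA20, AA20] <- scheme$matrix
  m
}

# encode a peptide as 0-based indices into the expanded matrix;
# errors on residues outside the 20 + 'X'
encode_peptide <- function(seq, what = "sequence") {
  ch <- strsplit(seq, "")[[1]]
  idx <- match(ch, AA21)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop("unknown residue(s) in ", what, ": ", paste(bad, collapse = ","))
  }
  idx - 1L
}
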