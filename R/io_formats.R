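#' Read a peptide multi-FASTA file
#'
#' One record per entry; the header token before the first whitespace becomes
#' the id (the remainder of the description is kept but ignored downstream so
#' ids stay stable join keys). Sequences are uppercased and trailing `*` stop
#' symbols stripped.
#'
#' @param path FASTA file path.
#' @param species optional species label attached to every record.
#' @return data.frame with columns `id`, `species`, `sequence`
#'   (class `proteome`).
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first))
    stop("parse error in ", path, ": empty file")
  if (!startsWith(trimws(lines[first]), ">"))
    stop("parse error in ", path, " at line ", first,
         ": sequence line before any header")
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate id(s) in ", path, ": ", paste(unique(dup), collapse = ","))
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ","))
  proteome(ids, seqs, species)
}

#' Construct a proteome table
#'
#' @param ids unique identifier strings.
#' @param sequences uppercase peptide strings.
#' @param species species label (recycled).
#' @return data.frame of class `proteome`.
#' @export
proteome <- function(ids, sequences, species = NA_character_) {
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("duplicate id(s): ",
                               paste(unique(ids[duplicated(ids)]), collapse = ","))
  if (length(ids) == 0) species <- character(0)
  df <- data.frame(id = as.character(ids), species = as.character(species),
                   sequence = toupper(as.character(sequences)),
                   stringsAsFactors = FALSE)
  class(df) <- c("proteome", "data.frame")
  df
}

#' Write a proteome to multi-FASTA
#'
#' @param prot a [proteome()].
#' @param path output path.
#' @export
write_fasta <- function(prot, path) {
  aas <- Biostrings::AAStringSet(setNames(prot$sequence, prot$id))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' Ordered taxon groups
#'
#' The iteration order of the survey: taxon groups are searched in sequence
#' and the query list grows between groups. Every species must appear in
#' exactly one group.
#'
#' @param groups named list: group name -> character vector of species labels.
#' @return object of class `taxon_ordering`.
#' @export
taxon_ordering <- function(groups) {
  if (!length(groups) || is.null(names(groups)))
    stop("at least one named group is required")
  sp <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(sp))
    stop("species in more than one group: ",
         paste(unique(sp[duplicated(sp)]), collapse = ","))
  structure(list(groups = groups), class = "taxon_ordering")
}

#' Read a proteome manifest
#'
#' Tab-separated columns `file`, `species`, `group`: species labels and taxon
#' groups come from the manifest, not from FASTA headers.
#'
#' @param path manifest TSV path.
#' @param base_dir directory FASTA paths are resolved against.
#' @return list with `proteomes` (named list of [proteome()] by species) and
#'   `ordering` (a [taxon_ordering()], groups in first-appearance order).
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("file", "species", "group")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  proteomes <- list()
  for (i in seq_len(nrow(m))) {
    f <- m$file[i]
    if (!file.exists(f)) f <- file.path(base_dir, m$file[i])
    proteomes[[m$species[i]]] <- read_fasta(f, species = m$species[i])
  }
  groups <- split(m$species, factor(m$group, levels = unique(m$group)))
  list(proteomes = proteomes, ordering = taxon_ordering(as.list(groups)))
}

#' Run configuration
#'
#' Central thresholds of the survey. Defaults encode the published screening
#' rules: corrected PID acceptance at 40%, all nine DNA-contact anchors for
#' the RFX tier, significance alpha 0.01; the RFX-like floor (25%) and the
#' ciliation-call knobs are this pipeline's own plumbing.
#'
#' @param pid_accept_threshold percent PID for the RFX tier (default 40).
#' @param pid_rfxlike_floor percent PID floor for the RFX-like tier (25).
#' @param anchors_required_full anchors required for the RFX tier (9).
#' @param anchors_required_like minimum anchors for the RFX-like tier (5).
#' @param significance_alpha shuffle-test acceptance p-value (0.01).
#' @param cilia_call_fraction fraction of IFT queries that must be conserved
#'   to call a species ciliated (0.5).
#' @param cilia_call_min_pid PID a cell needs to count as conserved (20).
#' @param n_shuffles shuffles per significance test (199).
#' @param random_seed integer seed for the run (1).
#' @return object of class `run_config`.
#' @export
run_config <- function(pid_accept_threshold = 40, pid_rfxlike_floor = 25,
                       anchors_required_full = 9, anchors_required_like = 5,
                       significance_alpha = 0.01, cilia_call_fraction = 0.5,
                       cilia_call_min_pid = 20, n_shuffles = 199,
                       random_seed = 1L) {
  cfg <- list(pid_accept_threshold = pid_accept_threshold,
              pid_rfxlike_floor = pid_rfxlike_floor,
              anchors_required_full = as.integer(anchors_required_full),
              anchors_required_like = as.integer(anchors_required_like),
              significance_alpha = significance_alpha,
              cilia_call_fraction = cilia_call_fraction,
              cilia_call_min_pid = cilia_call_min_pid,
              n_shuffles = as.integer(n_shuffles),
              random_seed = as.integer(random_seed))
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why) {
    if (!ok) stop("config error for '", key, "': ", why, call. = FALSE)
  }
  chk(cfg$pid_rfxlike_floor >= 0, "pid_rfxlike_floor", "must be >= 0")
  chk(cfg$pid_rfxlike_floor < cfg$pid_accept_threshold, "pid_rfxlike_floor",
      "must be below pid_accept_threshold")
  chk(cfg$pid_accept_threshold <= 100, "pid_accept_threshold", "must be <= 100")
  chk(cfg$significance_alpha > 0 && cfg$significance_alpha < 1,
      "significance_alpha", "must be in (0, 1)")
  chk(cfg$anchors_required_like <= cfg$anchors_required_full,
      "anchors_required_like", "must not exceed anchors_required_full")
  chk(cfg$cilia_call_fraction >= 0 && cfg$cilia_call_fraction <= 1,
      "cilia_call_fraction", "must be in [0, 1]")
  chk(cfg$n_shuffles >= 99, "n_shuffles", "must be at least 99")
  invisible(cfg)
}

#' Load a run configuration from a flat YAML file
#'
#' Unspecified keys take the [run_config()] defaults; unknown keys are an
#' error; all invariants are validated.
#'
#' @param path YAML file (may be empty).
#' @return a [run_config()].
#' @export
load_config <- function(path) {
  vals <- if (file.exists(path)) yaml::read_yaml(path) else
    stop("no such file: ", path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ","))
  do.call(run_config, vals)
}

#' Write a run configuration as flat YAML
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a conservation matrix as TSV
#'
#' First row: `species` then the gene names in module-grouped order; one row
#' per species in input order; absent cells (no accepted hit) are empty.
#'
#' @param matrix a `conservation_matrix` (see [scan_matrix()]).
#' @param path output path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  pid <- matrix$pid
  out <- cbind(species = rownames(pid),
               as.data.frame(ifelse(is.na(pid), "",
                                    formatC(pid, format = "fg", digits = 15)),
                             stringsAsFactors = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a conservation matrix TSV
#'
#' @param path TSV written by [write_matrix_tsv()].
#' @param modules optional data.frame (`gene`, `module`) restoring module
#'   grouping; defaults to a single module `all`.
#' @return a `conservation_matrix`.
#' @export
read_matrix_tsv <- function(path, modules = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  genes <- setdiff(names(df), "species")
  pid <- as.matrix(df[, genes, drop = FALSE])
  pid <- apply(pid, 2, function(x) suppressWarnings(as.numeric(x)))
  if (is.null(dim(pid))) pid <- matrix(pid, nrow = nrow(df),
                                       dimnames = list(NULL, genes))
  rownames(pid) <- df$species
  if (is.null(modules))
    modules <- data.frame(gene = genes, module = "all",
                          stringsAsFactors = FALSE)
  structure(list(species = df$species, genes = modules, pid = pid,
                 ciliated = NULL),
            class = "conservation_matrix")
}
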