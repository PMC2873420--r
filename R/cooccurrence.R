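#' Cilia/RFX co-occurrence state of a species
#'
#' The four-state partition: `BOTH` (RFX genes and cilia), `CILIA_ONLY`
#' (ciliated, no RFX), `RFX_ONLY` (RFX, not ciliated), `NEITHER`. Budding
#' yeast is the classic `RFX_ONLY` pattern, Chlamydomonas `CILIA_ONLY`,
#' M. brevicollis `BOTH`.
#'
#' @param rfx_count number of RFX-tier genes (>= 0).
#' @param ciliated logical ciliation flag.
#' @return one of `"BOTH"`, `"CILIA_ONLY"`, `"RFX_ONLY"`, `"NEITHER"`.
#' @export
species_state <- function(rfx_count, ciliated) {
  if (!is.numeric(rfx_count) || rfx_count < 0)
    stop("rfx_count must be a non-negative count")
  has_rfx <- rfx_count >= 1
  if (has_rfx && ciliated) return("BOTH")
  if (!has_rfx && ciliated) return("CILIA_ONLY")
  if (has_rfx && !ciliated) return("RFX_ONLY")
  "NEITHER"
}

#' Integrated survey report
#'
#' Joins the RFX catalog, the IFT conservation matrix, the DBD tree with its
#' clade assignment and the domain-architecture strings into one per-species
#' table plus the four-state summary. Ciliation can be overridden per species
#' (mirroring literature-curated ciliation labels); overrides are logged.
#'
#' @param catalog an `rfx_catalog` from [iterative_survey()].
#' @param matrix a `conservation_matrix` from [scan_matrix()].
#' @param tree optional `ape::phylo` of recovered DBDs.
#' @param clades optional named vector from [assign_clades()].
#' @param architectures optional named character vector: protein id ->
#'   architecture string.
#' @param ciliated_override optional named logical vector: species ->
#'   ciliation flag, taking precedence over the computed call.
#' @return object of class `survey_report`: `per_species` data.frame
#'   (species, rfx_count, ciliated, state, clades, architectures),
#'   `state_counts` (named counts over the four states), `matrix`, `tree`.
#' @export
build_report <- function(catalog, matrix, tree = NULL, clades = NULL,
                         architectures = NULL, ciliated_override = NULL) {
  cat_species <- attr(catalog, "species")
  mat_species <- matrix$species
  if (!setequal(cat_species, mat_species)) {
    stop("species sets differ between catalog and matrix; only in catalog: [",
         paste(setdiff(cat_species, mat_species), collapse = ","),
         "]; only in matrix: [",
         paste(setdiff(mat_species, cat_species), collapse = ","), "]")
  }
  species <- mat_species
  counts <- count_rfx_per_species(catalog)[species]
  ciliated <- matrix$ciliated[species]
  if (!is.null(ciliated_override)) {
    for (sp in intersect(names(ciliated_override), species)) {
      log_msg("INFO", "ciliation override for ", sp, ": ",
              ciliated_override[[sp]])
      ciliated[sp] <- ciliated_override[[sp]]
    }
  }
  states <- vapply(species, function(sp) species_state(counts[[sp]],
                                                       ciliated[[sp]]),
                   character(1))
  clade_col <- vapply(species, function(sp) {
    nm <- catalog$assigned_name[catalog$species == sp]
    if (!length(nm) || is.null(clades)) return("")
    lab <- clades[intersect(nm, names(clades))]
    paste(sprintf("%s:%s", names(lab), lab), collapse = ";")
  }, character(1))
  arch_col <- vapply(species, function(sp) {
    pr <- unique(catalog$protein[catalog$species == sp])
    if (!length(pr) || is.null(architectures)) return("")
    a <- architectures[intersect(pr, names(architectures))]
    paste(sprintf("%s:%s", names(a), a), collapse = ";")
  }, character(1))
  per_species <- data.frame(
    species = species, rfx_count = as.integer(counts),
    ciliated = as.logical(ciliated), state = states,
    clades = clade_col, architectures = arch_col,
    stringsAsFactors = FALSE, row.names = NULL)
  state_counts <- vapply(c("BOTH", "CILIA_ONLY", "RFX_ONLY", "NEITHER"),
                         function(s) sum(states == s), integer(1))
  structure(list(per_species = per_species, state_counts = state_counts,
                 matrix = matrix, tree = tree),
            class = "survey_report")
}

#' @export
print.survey_report <- function(x, ...) {
  cat("survey_report over", nrow(x$per_species), "species\n")
  cat("states:", paste(sprintf("%s=%d", names(x$state_counts),
                               x$state_counts), collapse = " "), "\n")
  invisible(x)
}

#' Write the report bundle as TSV files
#'
#' Writes `report.tsv` (per-species table), `summary.tsv` (four-state
#' counts), `matrix.tsv` (conservation matrix) and, when a tree is present,
#' `dbd_tree.nwk` into `dir`. Deterministic: identical inputs give
#' byte-identical files.
#'
#' @param report a `survey_report`.
#' @param dir output directory (created if needed).
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report$per_species, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(state = names(report$state_counts),
                         n = as.integer(report$state_counts)),
              file.path(dir, "summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_matrix_tsv(report$matrix, file.path(dir, "matrix.tsv"))
  if (!is.null(report$tree))
    write_newick(report$tree, file.path(dir, "dbd_tree.nwk"))
  invisible(dir)
}
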