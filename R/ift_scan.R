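#' The ciliary IFT/BBS query set
#'
#' The 24 query proteins of the conservation scan, organised in the four IFT
#' modules: Motors (DYNC2H1, KIFAP3, KIF17, KIF3B, KIF3A), Complex A (IFT122,
#' IFT140, WDR35, WDR19), Complex B (IFT88, IFT80, IFT172, IFT57, CLUAP1,
#' IFT52, IFT20, IFT81, IFT74) and BBS (BBS5, TTC8, BBS2, ARL6, BBS1, BBS7).
#'
#' @param modules named list: module name -> list of [query_domain()]s (no
#'   anchor sets; full-protein queries).
#' @return object of class `ift_query_set` with fields `modules`, `genes`
#'   (data.frame gene/module in scan order) and `queries` (flat named list).
#' @export
ift_query_set <- function(modules) {
  if (length(modules) != 4)
    warning("the canonical query set has 4 modules; got ", length(modules))
  queries <- list()
  genes <- data.frame(gene = character(0), module = character(0),
                      stringsAsFactors = FALSE)
  for (mod in names(modules)) {
    for (q in modules[[mod]]) {
      queries[[q$name]] <- q
      genes <- rbind(genes, data.frame(gene = q$name, module = mod,
                                       stringsAsFactors = FALSE))
    }
  }
  if (anyDuplicated(genes$gene)) stop("duplicate query gene names")
  structure(list(modules = modules, genes = genes, queries = queries),
            class = "ift_query_set")
}

ift_gene_names <- function() {
  list(
    Motors = c("DYNC2H1", "KIFAP3", "KIF17", "KIF3B", "KIF3A"),
    ComplexA = c("IFT122", "IFT140", "WDR35", "WDR19"),
    ComplexB = c("IFT88", "IFT80", "IFT172", "IFT57", "CLUAP1", "IFT52",
                 "IFT20", "IFT81", "IFT74"),
    BBS = c("BBS5", "TTC8", "BBS2", "ARL6", "BBS1", "BBS7")
  )
}

#' Scan one species against the IFT query set
#'
#' For each query, the best local alignment over the whole proteome; the cell
#' value is the corrected PID (identities over the entire query length) if
#' the shuffle-test p-value passes `significance_alpha`, else absent (`NA`).
#'
#' @param prot a [proteome()].
#' @param queries an [ift_query_set()].
#' @param scheme a [substitution_scheme()].
#' @param config a [run_config()].
#' @param rng_seed integer seed.
#' @return named numeric vector over the 24 genes (`NA` = absent).
#' @export
scan_species <- function(prot, queries, scheme = substitution_scheme(),
                         config = run_config(), rng_seed = 1L) {
  row <- setNames(rep(NA_real_, nrow(queries$genes)), queries$genes$gene)
  if (!nrow(prot)) return(row)
  for (gi in seq_along(row)) {
    g <- names(row)[gi]
    q <- queries$queries[[g]]
    best <- NULL
    best_target <- NULL
    for (pi in seq_len(nrow(prot))) {
      aln <- local_align(q$sequence, prot$sequence[pi], scheme)
      if (is.null(best) || aln$score > best$score) {
        best <- aln
        best_target <- prot$sequence[pi]
      }
    }
    if (best$score <= 0) next
    sig_seed <- (rng_seed + 7919 * gi) %% 2147483647
    sig <- empirical_significance(best$score, q$sequence, best_target, scheme,
                                  n_shuffles = config$n_shuffles,
                                  rng_seed = sig_seed)
    if (sig$p_value <= config$significance_alpha)
      row[gi] <- corrected_pid(best, nchar(q$sequence))
  }
  row
}

#' Build the species x gene conservation matrix
#'
#' One [scan_species()] row per species, plus the computed ciliation flag.
#'
#' @param proteomes named list of [proteome()]s.
#' @param queries an [ift_query_set()].
#' @param scheme a [substitution_scheme()].
#' @param config a [run_config()].
#' @param rng_seed integer seed.
#' @return object of class `conservation_matrix`: `species`, `genes`
#'   (gene/module frame), `pid` (species x gene matrix, `NA` = absent),
#'   `ciliated` (named logical).
#' @export
scan_matrix <- function(proteomes, queries, scheme = substitution_scheme(),
                        config = run_config(), rng_seed = 1L) {
  species <- names(proteomes)
  pid <- matrix(NA_real_, length(species), nrow(queries$genes),
                dimnames = list(species, queries$genes$gene))
  for (si in seq_along(species)) {
    pid[si, ] <- scan_species(proteomes[[si]], queries, scheme, config,
                              rng_seed = (rng_seed + 31L * si) %% 2147483647)
  }
  ciliated <- apply(pid, 1, call_ciliated, config = config)
  structure(list(species = species, genes = queries$genes, pid = pid,
                 ciliated = ciliated),
            class = "conservation_matrix")
}

#' Computed ciliation call for one matrix row
#'
#' A species is called ciliated iff the fraction of IFT queries conserved at
#' PID `>= cilia_call_min_pid` is at least `cilia_call_fraction` (both
#' boundaries inclusive). This is a computed surrogate for
#' literature-curated ciliation labels and can be overridden in the report.
#'
#' @param row named numeric row from [scan_species()] (`NA` = absent).
#' @param config a [run_config()].
#' @return logical flag.
#' @export
call_ciliated <- function(row, config = run_config()) {
  present <- !is.na(row) & row >= config$cilia_call_min_pid
  mean(present) >= config$cilia_call_fraction
}

#' Per-module present fraction for one matrix row
#'
#' Enables "cilia present but BBS module lost" style reports.
#'
#' @param row named numeric row from [scan_species()].
#' @param queries an [ift_query_set()].
#' @return named numeric vector: fraction of genes present per module.
#' @export
module_completeness <- function(row, queries) {
  vapply(split(queries$genes$gene, queries$genes$module),
         function(g) mean(!is.na(row[g])), numeric(1))
}
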