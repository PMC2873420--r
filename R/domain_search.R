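#' A searchable seed domain with anchor positions
#'
#' The searchable unit of the survey: a DBD peptide plus the 0-based positions
#' of its DNA-contact anchor residues. RFX DBD seeds are 76 residues long and
#' carry exactly nine anchors.
#'
#' @param name label for the query.
#' @param sequence peptide string.
#' @param anchors integer vector of 0-based anchor positions within the
#'   sequence (may be empty for full-protein queries).
#' @param provenance free-text note on where the domain came from.
#' @return object of class `query_domain`.
#' @export
query_domain <- function(name, sequence, anchors = integer(),
                         provenance = "") {
  sequence <- toupper(sequence)
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) && any(anchors < 0 | anchors >= nchar(sequence)))
    stop("anchors must be 0-based positions within the sequence")
  structure(list(name = name, sequence = sequence, anchors = anchors,
                 provenance = provenance),
            class = "query_domain")
}

#' @export
print.query_domain <- function(x, ...) {
  cat(sprintf("query_domain %s: %d aa, %d anchors\n",
              x$name, nchar(x$sequence), length(x$anchors)))
  invisible(x)
}

#' Count conserved anchor residues in an alignment
#'
#' An anchor counts as conserved only if it (a) falls inside the aligned
#' query interval, (b) is aligned to a residue (not a gap), and (c) is
#' identical between query and target at that column. Anchors outside the
#' aligned region are not conserved.
#'
#' @param aln a `local_alignment` whose query side is `query$sequence`.
#' @param query a [query_domain()].
#' @return integer count, at most `length(query$anchors)`.
#' @export
check_anchors <- function(aln, query) {
  anchors <- query$anchors
  if (!length(anchors) || !nzchar(aln$aligned_query)) return(0L)
  aq <- strsplit(aln$aligned_query, "")[[1]]
  at <- strsplit(aln$aligned_target, "")[[1]]
  qpos <- aln$query_interval[1] - 1L # 0-based position before the column
  n <- 0L
  for (k in seq_along(aq)) {
    if (aq[k] != "-") {
      qpos <- qpos + 1L
      if (qpos %in% anchors && at[k] != "-" &&
          aq[k] == at[k] && aq[k] != "X") {
        n <- n + 1L
      }
    }
  }
  n
}

# map the query's anchor positions through the alignment onto the target;
# returns 0-based positions relative to the extracted (degapped) target
# interval; anchors aligned to gaps or outside the interval are dropped
map_anchors_to_target <- function(aln, query) {
  anchors <- query$anchors
  if (!length(anchors) || !nzchar(aln$aligned_query)) return(integer())
  aq <- strsplit(aln$aligned_query, "")[[1]]
  at <- strsplit(aln$aligned_target, "")[[1]]
  qpos <- aln$query_interval[1] - 1L
  tpos <- -1L # 0-based within the target interval
  out <- integer()
  for (k in seq_along(aq)) {
    if (at[k] != "-") tpos <- tpos + 1L
    if (aq[k] != "-") {
      qpos <- qpos + 1L
      if (qpos %in% anchors && at[k] != "-") out <- c(out, tpos)
    }
  }
  out
}

#' Find significant domain hits in a proteome
#'
#' Aligns every query against every protein, keeps per protein the best hit
#' per query by (score, then PID), and retains hits whose shuffle-test
#' p-value is at most `significance_alpha`. Each retained hit carries its
#' corrected PID, conserved-anchor count and the extracted (degapped) target
#' region.
#'
#' @param prot a [proteome()].
#' @param queries list of [query_domain()]s.
#' @param scheme a [substitution_scheme()].
#' @param config a [run_config()].
#' @param rng_seed integer seed for the significance shuffles.
#' @return data.frame of class `domain_hits`, sorted by (species, protein id,
#'   descending pid); the matched `query_domain` objects are in
#'   `attr(, "queries")` indexed by the `query` column.
#' @export
find_domain_hits <- function(prot, queries, scheme = substitution_scheme(),
                             config = run_config(), rng_seed = 1L) {
  if (!length(queries)) stop("at least one query is required")
  rows <- list()
  alns <- list()
  for (pi in seq_len(nrow(prot))) {
    target <- prot$sequence[pi]
    for (qi in seq_along(queries)) {
      q <- queries[[qi]]
      aln <- local_align(q$sequence, target, scheme)
      if (aln$score <= 0) next
      sig_seed <- (rng_seed + 7919 * pi + qi) %% 2147483647
      sig <- empirical_significance(aln$score, q$sequence, target, scheme,
                                    n_shuffles = config$n_shuffles,
                                    rng_seed = sig_seed)
      if (sig$p_value > config$significance_alpha) next
      pid <- corrected_pid(aln, nchar(q$sequence))
      extracted <- gsub("-", "", aln$aligned_target, fixed = TRUE)
      key <- length(rows) + 1L
      rows[[key]] <- data.frame(
        species = prot$species[pi], protein = prot$id[pi], query = q$name,
        score = aln$score, pid = pid,
        anchors_conserved = check_anchors(aln, q),
        n_anchors = length(q$anchors),
        p_value = sig$p_value,
        start = aln$target_interval[1], end = aln$target_interval[2],
        domain_seq = extracted, stringsAsFactors = FALSE)
      alns[[key]] <- aln
    }
  }
  if (!length(rows)) {
    hits <- data.frame(species = character(0), protein = character(0),
                       query = character(0), score = numeric(0),
                       pid = numeric(0), anchors_conserved = integer(0),
                       n_anchors = integer(0), p_value = numeric(0),
                       start = integer(0), end = integer(0),
                       domain_seq = character(0), stringsAsFactors = FALSE)
  } else {
    hits <- do.call(rbind, rows)
  }
  ord <- order(hits$species, hits$protein, -hits$pid, -hits$score)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "alignments") <- alns[ord]
  attr(hits, "queries") <- queries
  class(hits) <- c("domain_hits", "data.frame")
  hits
}

#' Tiered classification of a candidate domain hit
#'
#' The published screening rule: a hit is `RFX` iff its corrected PID reaches
#' the 40% acceptance threshold and all nine anchors are conserved; it is
#' `RFX_LIKE` iff (not RFX and) PID is at least the like-tier floor with at
#' least five anchors; otherwise `NONE`. A hit found via an expanded query
#' that carries fewer than the full nine seed-rooted anchors cannot
#' demonstrate all-nine conservation and is capped at `RFX_LIKE`.
#'
#' @param hit one row of a `domain_hits` frame (list or 1-row data.frame).
#' @param config a [run_config()].
#' @return `"RFX"`, `"RFX_LIKE"` or `"NONE"`.
#' @export
classify_candidate <- function(hit, config = run_config()) {
  pid <- hit$pid
  anchors <- hit$anchors_conserved
  n_anchors <- if (!is.null(hit$n_anchors)) hit$n_anchors else
    config$anchors_required_full
  full_ok <- n_anchors >= config$anchors_required_full &&
    anchors == config$anchors_required_full
  if (pid >= config$pid_accept_threshold && full_ok) return("RFX")
  if (pid >= config$pid_rfxlike_floor &&
      anchors >= config$anchors_required_like) return("RFX_LIKE")
  "NONE"
}

# reduce hits to the single best per protein (score, then pid), classify,
# and drop NONE
call_proteins <- function(hits, config) {
  if (!nrow(hits)) return(hits[0, ])
  keep <- integer(0)
  for (p in unique(hits$protein)) {
    idx <- which(hits$protein == p)
    best <- idx[order(-hits$score[idx], -hits$pid[idx])][1]
    keep <- c(keep, best)
  }
  calls <- hits[keep, , drop = FALSE]
  calls$tier <- vapply(seq_len(nrow(calls)),
                       function(i) classify_candidate(calls[i, ], config),
                       character(1))
  out <- calls[calls$tier != "NONE", , drop = FALSE]
  attr(out, "alignments") <- attr(hits, "alignments")[keep][calls$tier != "NONE"]
  attr(out, "queries") <- attr(hits, "queries")
  out
}

#' Iterative RFX survey across ordered taxon groups
#'
#' The survey procedure: taxon groups are processed in order; within a group
#' every species is searched with the query list frozen at group start; after
#' each group, the extracted DBD of every newly accepted RFX-tier call (with
#' anchors mapped through its alignment) is appended to the query list for
#' subsequent groups. Queries are deduplicated by exact sequence. Calls are
#' named `<species>_cRFX<k>` by descending PID within species.
#'
#' @param proteomes named list of [proteome()]s, one per species.
#' @param ordering a [taxon_ordering()] covering every species.
#' @param seeds list of seed [query_domain()]s.
#' @param scheme a [substitution_scheme()].
#' @param config a [run_config()].
#' @param rng_seed integer seed.
#' @param expand if FALSE, query expansion is disabled (seeds only).
#' @return an `rfx_catalog`: data.frame of calls with columns species,
#'   protein, assigned_name, tier, pid, anchors_conserved, p_value, start,
#'   end, domain_seq, query; `attr(, "species")` lists all surveyed species
#'   and `attr(, "rfx_count")` the per-species RFX-tier counts.
#' @export
iterative_survey <- function(proteomes, ordering, seeds,
                             scheme = substitution_scheme(),
                             config = run_config(), rng_seed = 1L,
                             expand = TRUE) {
  stopifnot(inherits(ordering, "taxon_ordering"))
  all_species <- unlist(ordering$groups, use.names = FALSE)
  missing <- setdiff(names(proteomes), all_species)
  if (length(missing))
    stop("species not in the taxon ordering: ", paste(missing, collapse = ","))
  queries <- seeds
  seen <- vapply(queries, function(q) q$sequence, character(1))
  calls <- list()
  gi <- 0L
  for (gname in names(ordering$groups)) {
    gi <- gi + 1L
    new_queries <- list()
    si <- 0L
    for (sp in ordering$groups[[gname]]) {
      si <- si + 1L
      if (is.null(proteomes[[sp]])) next
      sp_seed <- (rng_seed + 104729 * gi + 1009 * si) %% 2147483647
      hits <- find_domain_hits(proteomes[[sp]], queries, scheme, config,
                               rng_seed = sp_seed)
      sp_calls <- call_proteins(hits, config)
      if (nrow(sp_calls)) {
        calls[[length(calls) + 1L]] <- sp_calls
        if (expand) {
          alns <- attr(sp_calls, "alignments")
          qmap <- setNames(attr(sp_calls, "queries"),
                           vapply(attr(sp_calls, "queries"),
                                  function(q) q$name, character(1)))
          for (i in which(sp_calls$tier == "RFX")) {
            q <- qmap[[sp_calls$query[i]]]
            mapped <- map_anchors_to_target(alns[[i]], q)
            nq <- query_domain(
              name = sprintf("%s_%s_exp", sp, sp_calls$protein[i]),
              sequence = sp_calls$domain_seq[i], anchors = mapped,
              provenance = sprintf("expanded from %s via %s", q$name, sp))
            new_queries[[length(new_queries) + 1L]] <- nq
          }
        }
      }
    }
    for (nq in new_queries) {
      if (!nq$sequence %in% seen) {
        queries[[length(queries) + 1L]] <- nq
        seen <- c(seen, nq$sequence)
      }
    }
  }
  catalog <- if (length(calls)) {
    df <- do.call(rbind, lapply(calls, function(x) {
      attr(x, "alignments") <- NULL
      attr(x, "queries") <- NULL
      as.data.frame(x)
    }))
    rownames(df) <- NULL
    df
  } else {
    data.frame(species = character(0), protein = character(0),
               query = character(0), score = numeric(0), pid = numeric(0),
               anchors_conserved = integer(0), n_anchors = integer(0),
               p_value = numeric(0), start = integer(0), end = integer(0),
               domain_seq = character(0), tier = character(0),
               stringsAsFactors = FALSE)
  }
  # assigned names: cRFX1..k per species by descending pid over both tiers
  catalog$assigned_name <- NA_character_
  for (sp in unique(catalog$species)) {
    idx <- which(catalog$species == sp)
    idx <- idx[order(-catalog$pid[idx], catalog$protein[idx])]
    catalog$assigned_name[idx] <- sprintf("%s_cRFX%d", sp, seq_along(idx))
  }
  catalog <- catalog[order(catalog$species, catalog$assigned_name), ,
                     drop = FALSE]
  rownames(catalog) <- NULL
  species <- sort(unique(c(names(proteomes), all_species)))
  counts <- vapply(species, function(sp) {
    length(unique(catalog$protein[catalog$species == sp &
                                    catalog$tier == "RFX"]))
  }, integer(1))
  structure(catalog, species = species, rfx_count = counts,
            class = c("rfx_catalog", "data.frame"))
}

#' Number of RFX-tier genes per species
#'
#' Counts distinct proteins with an RFX-tier call; RFX-like calls are
#' excluded (they are not regarded as RFX TFs).
#'
#' @param catalog an `rfx_catalog` from [iterative_survey()].
#' @return named integer vector over all surveyed species (zeros included).
#' @export
count_rfx_per_species <- function(catalog) {
  attr(catalog, "rfx_count")
}

#' Write an RFX catalog as TSV
#'
#' Columns: species, protein, assigned_name, tier, pid, anchors_conserved,
#' p_value, start, end (0-based half-open), domain_seq, query.
#'
#' @param catalog an `rfx_catalog`.
#' @param path output path.
#' @export
write_catalog_tsv <- function(catalog, path) {
  cols <- c("species", "protein", "assigned_name", "tier", "pid",
            "anchors_conserved", "p_value", "start", "end", "domain_seq",
            "query")
  df <- as.data.frame(catalog)[, cols, drop = FALSE]
  df$pid <- formatC(df$pid, format = "fg", digits = 15)
  df$p_value <- formatC(df$p_value, format = "fg", digits = 15)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RFX catalog TSV back into an `rfx_catalog`
#'
#' @param path TSV written by [write_catalog_tsv()].
#' @param species full vector of surveyed species (species without calls are
#'   needed to restore zero counts); defaults to the species present in the
#'   file.
#' @return an `rfx_catalog`.
#' @export
read_catalog_tsv <- function(path, species = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(species)) species <- sort(unique(df$species))
  counts <- vapply(species, function(sp) {
    length(unique(df$protein[df$species == sp & df$tier == "RFX"]))
  }, integer(1))
  structure(df, species = species, rfx_count = counts,
            class = c("rfx_catalog", "data.frame"))
}
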