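#' Default anchor positions of the packaged DBD seeds
#'
#' Nine 0-based positions within the 76-residue DBD marking the DNA-contact
#' anchor residues. The published anchor set is shown only graphically in the
#' source literature, so the packaged default is a synthetic stand-in:
#' nine fixed positions spread over the domain, configurable wherever a
#' [query_domain()] is built.
#'
#' @return integer vector of nine 0-based positions.
#' @export
synthetic_dbd_anchors <- function() {
  c(5L, 12L, 18L, 27L, 33L, 40L, 52L, 61L, 70L)
}

#' Load the packaged synthetic DBD seed queries
#'
#' Reads the packaged 76-aa synthetic seed DBDs (stand-ins for curated RFX
#' DBD queries from human, worm, fly and yeast) and attaches the anchor set.
#' Both files are plain text under `inst/extdata` and can be swapped for
#' curated real sequences.
#'
#' @param fasta path to a seed FASTA (default: packaged synthetic seeds).
#' @param anchors_file path to a one-position-per-line 0-based anchor file
#'   (default: packaged).
#' @return list of [query_domain()]s.
#' @export
load_dbd_seeds <- function(fasta = system.file("extdata",
                                               "synthetic_dbd_seeds.fasta",
                                               package = "rfxcilia"),
                           anchors_file = system.file(
                             "extdata", "synthetic_dbd_anchors.txt",
                             package = "rfxcilia")) {
  prot <- read_fasta(fasta)
  lines <- readLines(anchors_file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  anchors <- as.integer(lines)
  lapply(seq_len(nrow(prot)), function(i) {
    query_domain(prot$id[i], prot$sequence[i], anchors = anchors,
                 provenance = paste0("packaged synthetic seed (", fasta, ")"))
  })
}

# deterministic construction of the packaged seed set: one ancestral 76-aa
# domain plus four lightly diverged seeds with anchors intact
make_synthetic_dbd_seed_set <- function(rng_seed = 4242L) {
  anchors <- synthetic_dbd_anchors()
  with_seed(rng_seed, {
    anc <- random_peptide(76L, aa_background())
    seeds <- list()
    for (nm in c("DBD_human_syn", "DBD_worm_syn", "DBD_fly_syn",
                 "DBD_yeast_syn")) {
      sq <- evolve_domain(query_domain(nm, anc, anchors), divergence = 0.10,
                          preserve_anchors = TRUE,
                          rng_seed = sample.int(2147483646L, 1L))
      seeds[[nm]] <- query_domain(nm, sq, anchors,
                                  provenance = "synthetic seed set")
    }
    seeds
  })
}

#' Synthetic stand-ins for the 24 ciliary IFT/BBS queries
#'
#' Generates one deterministic random peptide per query gene (lengths 200 to
#' 400, fixed given the seed), organised into the four IFT modules. These are
#' desk-scale stand-ins for the real human query proteins; swap in curated
#' sequences via [ift_query_set()] for real scans.
#'
#' @param rng_seed integer seed (default fixed so the set is stable).
#' @return an [ift_query_set()].
#' @export
synthetic_ift_queries <- function(rng_seed = 3011L) {
  genes <- ift_gene_names()
  with_seed(rng_seed, {
    modules <- lapply(genes, function(gs) {
      lapply(gs, function(g) {
        len <- sample(200:400, 1L)
        query_domain(g, random_peptide(len, aa_background()),
                     provenance = "synthetic IFT stand-in")
      })
    })
    ift_query_set(modules)
  })
}

#' Synthetic reference DBDs for the three RFX clades plus the fungal group
#'
#' Builds a reference panel by evolving group ancestors from the first
#' packaged seed (divergence 0.25 between groups, 0.08 within), giving three
#' metazoan-style groups (`RFX1-3`, `RFX4-6`, `RFX5-7`) and a deeper
#' `Fungus` group (ancestor divergence 0.45). Used for clade assignment of
#' surveyed DBDs.
#'
#' @param rng_seed integer seed.
#' @param n_per_group reference leaves per group.
#' @return list: `seqs` (named peptides), `groups` (named vector leaf ->
#'   group label).
#' @export
synthetic_reference_dbds <- function(rng_seed = 811L, n_per_group = 3L) {
  seed <- load_dbd_seeds()[[1]]
  anchors <- seed$anchors
  groups <- c("RFX1-3", "RFX4-6", "RFX5-7", "Fungus")
  anc_div <- c(0.25, 0.25, 0.25, 0.45)
  with_seed(rng_seed, {
    seqs <- character(0)
    labs <- character(0)
    for (k in seq_along(groups)) {
      anc <- evolve_domain(seed, anc_div[k], TRUE,
                           rng_seed = sample.int(2147483646L, 1L))
      ancq <- query_domain(paste0(groups[k], "_anc"), anc, anchors)
      for (m in seq_len(n_per_group)) {
        nm <- sprintf("%s_ref%d", gsub("-", "", groups[k]), m)
        seqs[nm] <- evolve_domain(ancq, 0.08, TRUE,
                                  rng_seed = sample.int(2147483646L, 1L))
        labs[nm] <- groups[k]
      }
    }
    list(seqs = seqs, groups = labs)
  })
}

#' Synthetic seed alignments for the non-DBD domain profiles
#'
#' Deterministic stand-ins for curated AD/B/C/D/DD domain alignments: one
#' consensus peptide per domain (lengths 30/25/25/20/35) with four instances
#' evolved at divergence 0.1.
#'
#' @param rng_seed integer seed.
#' @param n_instances instances per domain.
#' @return named list: domain name -> character vector of aligned instances.
#' @export
synthetic_profile_seeds <- function(rng_seed = 5309L, n_instances = 4L) {
  lens <- c(AD = 30L, B = 25L, C = 25L, D = 20L, DD = 35L)
  with_seed(rng_seed, {
    out <- list()
    for (nm in names(lens)) {
      cons <- random_peptide(lens[[nm]], aa_background())
      q <- query_domain(nm, cons)
      out[[nm]] <- vapply(seq_len(n_instances), function(i) {
        evolve_domain(q, 0.10, FALSE,
                      rng_seed = sample.int(2147483646L, 1L))
      }, character(1))
    }
    out
  })
}
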