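#' Evolve a seed domain by independent per-site substitution
#'
#' Each position is substituted with probability `divergence`; the replacement
#' residue is drawn from the scheme background excluding the current residue,
#' so a "substitution" always changes the residue. With `preserve_anchors`,
#' anchor positions are never touched. No indels: output length equals seed
#' length, which keeps corrected-PID expectations in closed form.
#'
#' @param seed a [query_domain()] (or plain peptide string).
#' @param divergence per-site substitution probability in `[0, 1]`.
#' @param preserve_anchors if TRUE, anchor positions are left intact.
#' @param rng_seed integer seed; the result is a pure function of inputs.
#' @param background residue frequencies; default [substitution_scheme()]'s.
#' @return peptide string of the same length as the seed.
#' @export
evolve_domain <- function(seed, divergence, preserve_anchors = TRUE,
                          rng_seed = 1L, background = aa_background()) {
  if (!is.numeric(divergence) || divergence < 0 || divergence > 1)
    stop("divergence must lie in [0, 1]")
  sq <- if (inherits(seed, "query_domain")) seed$sequence else seed
  anchors <- if (inherits(seed, "query_domain")) seed$anchors else integer()
  stopifnot(nzchar(sq))
  ch <- strsplit(sq, "")[[1]]
  if (length(anchors) && any(anchors < 0 | anchors >= length(ch)))
    stop("anchors out of seed bounds")
  with_seed(rng_seed, {
    hit <- runif(length(ch)) < divergence
    if (preserve_anchors && length(anchors)) hit[anchors + 1L] <- FALSE
    for (i in which(hit)) {
      cur <- ch[i]
      pool <- background[names(background) != cur]
      ch[i] <- sample(names(pool), 1L, prob = pool)
    }
    paste(ch, collapse = "")
  })
}

#' Implant specification for simulated proteomes
#'
#' @param seed_domain a [query_domain()].
#' @param divergence per-site substitution probability.
#' @param preserve_anchors keep anchor residues intact.
#' @param flank_lengths integer pair: random-flank lengths (N-term, C-term).
#' @param label truth label: `"RFX"`, `"RFX_LIKE"` or `"DECOY"`.
#' @return object of class `implant_spec`.
#' @export
implant_spec <- function(seed_domain, divergence, preserve_anchors = TRUE,
                         flank_lengths = c(100L, 100L), label = "RFX") {
  if (divergence < 0 || divergence > 1) stop("divergence must lie in [0, 1]")
  if (any(flank_lengths < 0)) stop("flank lengths must be >= 0")
  if (!label %in% c("RFX", "RFX_LIKE", "DECOY"))
    stop("label must be RFX, RFX_LIKE or DECOY")
  structure(list(seed_domain = seed_domain, divergence = divergence,
                 preserve_anchors = preserve_anchors,
                 flank_lengths = as.integer(flank_lengths), label = label),
            class = "implant_spec")
}

random_peptide <- function(n, background) {
  if (n == 0) return("")
  paste(sample(names(background), n, replace = TRUE, prob = background),
        collapse = "")
}

#' Simulate a proteome with implanted homologs and decoys
#'
#' Decoys are i.i.d. residues from the background; each implant is an
#' [evolve_domain()] output embedded between random flanks. The truth table
#' records exact implant coordinates (0-based half-open) and labels. The
#' result is a pure function of `rng_seed` and the parameters.
#'
#' @param species species label.
#' @param n_decoys number of pure-decoy proteins.
#' @param implants list of [implant_spec()]s.
#' @param decoy_length_range integer pair of decoy lengths (inclusive).
#' @param rng_seed integer seed.
#' @param background residue frequencies.
#' @return list of class `synthetic_proteome`: `species`, `records`
#'   (a [proteome()]), `truth` (data.frame id, start, end, label).
#' @export
simulate_proteome <- function(species, n_decoys, implants = list(),
                              decoy_length_range = c(200L, 400L),
                              rng_seed = 1L, background = aa_background()) {
  stopifnot(n_decoys >= 0)
  with_seed(rng_seed, {
    ids <- character(0)
    seqs <- character(0)
    truth <- data.frame(id = character(0), start = integer(0),
                        end = integer(0), label = character(0),
                        stringsAsFactors = FALSE)
    for (k in seq_along(implants)) {
      sp <- implants[[k]]
      dom <- evolve_domain(sp$seed_domain, sp$divergence, sp$preserve_anchors,
                           rng_seed = sample.int(2147483646L, 1L),
                           background = background)
      lf <- random_peptide(sp$flank_lengths[1], background)
      rf <- random_peptide(sp$flank_lengths[2], background)
      id <- sprintf("%s_imp%02d", species, k)
      ids <- c(ids, id)
      seqs <- c(seqs, paste0(lf, dom, rf))
      truth <- rbind(truth, data.frame(
        id = id, start = nchar(lf), end = nchar(lf) + nchar(dom),
        label = sp$label, stringsAsFactors = FALSE))
    }
    if (n_decoys > 0) {
      lens <- sample(seq(decoy_length_range[1], decoy_length_range[2]),
                     n_decoys, replace = TRUE)
      for (k in seq_len(n_decoys)) {
        ids <- c(ids, sprintf("%s_dec%03d", species, k))
        seqs <- c(seqs, random_peptide(lens[k], background))
      }
    }
    structure(list(species = species,
                   records = proteome(ids, seqs, species),
                   truth = truth),
              class = "synthetic_proteome")
  })
}

#' Write a synthetic proteome's truth table as TSV
#'
#' @param sim a `synthetic_proteome`.
#' @param path output path.
#' @export
write_truth_tsv <- function(sim, path) {
  write.table(sim$truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evolve a domain along a phylogeny and emit one proteome per leaf
#'
#' The seed domain is evolved along an `ape::phylo` tree: each branch draws a
#' Poisson number of substitution events with mean `branch length x number of
#' mutable (non-anchor) sites`, each event hitting a uniformly chosen
#' non-anchor site (replacement from the background, always a change). Leaf
#' proteomes contain the leaf's domain (with flanks) plus decoys.
#'
#' @param tree an `ape::phylo` with positive branch lengths in expected
#'   substitutions per site.
#' @param seed_domain a [query_domain()].
#' @param rng_seed integer seed.
#' @param n_decoys decoys per leaf proteome.
#' @param flank_lengths flanks around the implanted leaf domain.
#' @param background residue frequencies.
#' @return named list (by leaf label): `synthetic_proteome` objects; the
#'   attribute `leaf_domains` holds the evolved domain per leaf.
#' @export
simulate_clade_series <- function(tree, seed_domain, rng_seed = 1L,
                                  n_decoys = 5L, flank_lengths = c(60L, 60L),
                                  background = aa_background()) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  sq <- seed_domain$sequence
  anchors <- seed_domain$anchors
  mutable <- setdiff(seq_len(nchar(sq)), anchors + 1L)
  with_seed(rng_seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    node_seq <- vector("list", ntip + tree$Nnode)
    node_seq[[root]] <- strsplit(sq, "")[[1]]
    # cladewise order guarantees parents are assigned before children
    tree <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      ch <- node_seq[[parent]]
      nev <- rpois(1, tree$edge.length[e] * length(mutable))
      if (nev > 0) {
        sites <- sample(mutable, nev, replace = TRUE)
        for (s in sites) {
          pool <- background[names(background) != ch[s]]
          ch[s] <- sample(names(pool), 1L, prob = pool)
        }
      }
      node_seq[[child]] <- ch
    }
    out <- list()
    doms <- character(ntip)
    for (i in seq_len(ntip)) {
      leaf <- tree$tip.label[i]
      dom <- paste(node_seq[[i]], collapse = "")
      doms[i] <- dom
      spec <- implant_spec(query_domain(paste0(leaf, "_dom"), dom,
                                        anchors = anchors),
                           divergence = 0, preserve_anchors = TRUE,
                           flank_lengths = flank_lengths, label = "RFX")
      out[[leaf]] <- simulate_proteome(leaf, n_decoys = n_decoys,
                                       implants = list(spec),
                                       rng_seed = sample.int(2147483646L, 1L),
                                       background = background)
    }
    names(doms) <- tree$tip.label
    attr(out, "leaf_domains") <- doms
    out
  })
}
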