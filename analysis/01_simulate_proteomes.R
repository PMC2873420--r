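#!/usr/bin/env Rscript
# Build the synthetic study world: eight species across three taxon groups,
# engineered to span the known biology — metazoan-like species with RFX and
# full IFT complements, a choanoflagellate-like species with two RFX genes
# plus a weak RFX-like domain, fungi that kept cilia but lost BBS, yeasts
# that kept RFX but lost cilia, and a plant-like outgroup with neither.
# Writes FASTA proteomes, truth tables and a manifest under results/world/.

suppressPackageStartupMessages(library(rfxcilia))

out_dir <- "results/world"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

seed0 <- 20260  # study seed; every downstream script reuses the manifest
seeds <- load_dbd_seeds()
ift <- synthetic_ift_queries()

ift_implants <- function(genes, divergence) {
  lapply(ift$queries[genes], function(q) {
    implant_spec(q, divergence, flank_lengths = c(20L, 20L), label = "DECOY")
  })
}
dbd_implant <- function(divergence, seed_q = seeds[[1]]) {
  implant_spec(seed_q, divergence, flank_lengths = c(60L, 60L), label = "RFX")
}
non_bbs <- ift$genes$gene[ift$genes$module != "BBS"]

# the weak RFX-like domain: 46 substituted non-anchor sites (30/76 identity)
nonanchor <- setdiff(0:75, seeds[[1]]$anchors)
ord <- rfxcilia:::with_seed(seed0, sample(nonanchor))
like_dom <- local({
  ch <- strsplit(seeds[[1]]$sequence, "")[[1]]
  for (p in ord[1:46]) ch[p + 1] <- setdiff(rfxcilia:::AA20, ch[p + 1])[1]
  paste(ch, collapse = "")
})

# a canonical full-length RFX protein: AD - DBD - B - C - DD with spacers
prof_seeds <- synthetic_profile_seeds()
canonical_rfx <- rfxcilia:::with_seed(seed0 + 99, {
  sp <- function(n) rfxcilia:::random_peptide(n, rfxcilia:::aa_background())
  dbd <- evolve_domain(seeds[[1]], 0.08, TRUE,
                       rng_seed = sample.int(2147483646L, 1L))
  paste0(prof_seeds$AD[1], sp(25), dbd, sp(20), prof_seeds$B[1], sp(10),
         prof_seeds$C[1], sp(15), prof_seeds$DD[1])
})

species <- list(
  # group 1: metazoan-like, searched first with the raw seeds
  metazoan1 = list(group = "metazoa", implants = c(
    list(implant_spec(query_domain("canonical_rfx", canonical_rfx,
                                   integer()), 0,
                      flank_lengths = c(10L, 10L), label = "RFX"),
         dbd_implant(0.15)),
    ift_implants(ift$genes$gene, 0.10))),
  metazoan2 = list(group = "metazoa", implants = c(
    list(dbd_implant(0.10)),
    ift_implants(ift$genes$gene, 0.15))),
  # group 2: the choanoflagellate-like pattern (2 RFX + 1 RFX-like + cilia)
  choano = list(group = "protists", implants = c(
    list(dbd_implant(0.20), dbd_implant(0.25),
         implant_spec(query_domain("like_dom", like_dom,
                                   seeds[[1]]$anchors), 0,
                      flank_lengths = c(60L, 60L), label = "RFX_LIKE")),
    ift_implants(ift$genes$gene, 0.20))),
  alga = list(group = "protists", implants =
                ift_implants(ift$genes$gene, 0.25)), # cilia, no RFX
  # group 3: fungi and outgroup
  chytrid = list(group = "fungi", implants = c(
    list(dbd_implant(0.30)),
    ift_implants(non_bbs, 0.25))), # kept cilia, lost the BBS module
  yeast1 = list(group = "fungi", implants = list(dbd_implant(0.25))),
  yeast2 = list(group = "fungi", implants = list(dbd_implant(0.30))),
  plant = list(group = "fungi", implants = list())
)

manifest <- data.frame(file = character(0), species = character(0),
                       group = character(0), stringsAsFactors = FALSE)
for (i in seq_along(species)) {
  sp <- names(species)[i]
  sim <- simulate_proteome(sp, n_decoys = 10,
                           implants = species[[sp]]$implants,
                           rng_seed = seed0 + i)
  fasta <- file.path(out_dir, paste0(sp, ".fasta"))
  write_fasta(sim$records, fasta)
  write_truth_tsv(sim, file.path(out_dir, paste0(sp, "_truth.tsv")))
  manifest <- rbind(manifest, data.frame(
    file = basename(fasta), species = sp, group = species[[sp]]$group,
    stringsAsFactors = FALSE))
  message(sprintf("simulated %-10s %2d proteins (%d implants)", sp,
                  nrow(sim$records), length(species[[sp]]$implants)))
}
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_config(run_config(random_seed = seed0),
             file.path(out_dir, "config.yaml"))
message("world written to ", out_dir)
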