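#!/usr/bin/env Rscript
# Neighbor-joining phylogeny of every DBD recovered by the survey, together
# with the synthetic reference panel, plus nearest-reference clade
# assignment. Writes the distance matrix, the Newick tree and clade labels.

suppressPackageStartupMessages(library(rfxcilia))

world <- read_manifest("results/world/manifest.tsv")
catalog <- read_catalog_tsv("results/rfx_catalog.tsv",
                            species = names(world$proteomes))
sch <- substitution_scheme()
refs <- synthetic_reference_dbds()

dbds <- setNames(catalog$domain_seq, catalog$assigned_name)
seqs <- c(refs$seqs, dbds)
dm <- distance_matrix(seqs, sch)
write.table(cbind(label = rownames(dm), as.data.frame(dm)),
            "results/dbd_distances.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

tree <- nj_tree(dm)
write_newick(tree, "results/dbd_tree.nwk")

clades <- assign_clades(tree, refs$groups)
write.table(data.frame(leaf = names(clades), clade = unname(clades)),
            "results/dbd_clades.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("tree over ", length(seqs), " DBDs (",
        length(refs$seqs), " references + ", length(dbds), " calls)")
for (nm in names(clades)) {
  message(sprintf("  %-18s -> %s", nm, clades[[nm]]))
}
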