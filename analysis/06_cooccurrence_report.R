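#!/usr/bin/env Rscript
# Integrated survey report: per-species RFX counts, IFT conservation,
# computed ciliation, cilia/RFX co-occurrence state, clade labels and
# architecture strings; plus the four-state summary.

suppressPackageStartupMessages(library(rfxcilia))

world <- read_manifest("results/world/manifest.tsv")
cfg <- load_config("results/world/config.yaml")
ift <- synthetic_ift_queries()

catalog <- read_catalog_tsv("results/rfx_catalog.tsv",
                            species = names(world$proteomes))
mat <- read_matrix_tsv("results/ift_matrix.tsv", modules = ift$genes)
mat$ciliated <- setNames(apply(mat$pid, 1, call_ciliated, config = cfg),
                         mat$species)
tree <- ape::read.tree("results/dbd_tree.nwk")
clades_df <- read.delim("results/dbd_clades.tsv", stringsAsFactors = FALSE)
clades <- setNames(clades_df$clade, clades_df$leaf)
arch_df <- read.delim("results/architectures.tsv", stringsAsFactors = FALSE)
arch <- setNames(arch_df$architecture, arch_df$protein)

report <- build_report(catalog, mat, tree = tree, clades = clades,
                       architectures = arch)
write_report_bundle(report, "results/report")

print(report)
msg <- utils::capture.output(print(report$per_species, row.names = FALSE))
message(paste(msg, collapse = "\n"))
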