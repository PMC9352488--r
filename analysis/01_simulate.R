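#!/usr/bin/env Rscript
# Stage 1: generate the full synthetic study system — a scale-free PPI
# network with two planted dense modules, curated-style gene lists whose
# intersection recovers the first module, bulk case/control expression with
# a disease-activated co-expression module, an 11-cluster cell population
# with one T2DM-enriched cluster, and a drug library with one planted
# proximal drug. All downstream stages read these files.

suppressMessages(library(proxscreen))

outdir <- "results/synthetic"
cfg <- synth_config(seed = 20260930)
sim <- write_simulation(cfg, outdir)

cat("network:", igraph::vcount(sim$network), "nodes,",
    igraph::ecount(sim$network), "edges\n")
cat("planted cliques:",
    paste(lengths(sim$truth$cliques), collapse = " and "), "nodes\n")
cat("bulk expression:", nrow(sim$expr$values), "genes x",
    ncol(sim$expr$values), "samples\n")
cat("cells:", nrow(sim$cells), " (", sum(sim$cells$qc_fail),
    "with planted QC failures )\n")
cat("drugs:", length(sim$drugs), "(1 planted proximal)\n")
cat("inputs written under", outdir, "\n")
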