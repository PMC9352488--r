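#!/usr/bin/env Rscript
# Stage 5: network-proximity drug screen. For every drug, the average
# weighted closest distance d(S,T) from its targets to the disease gene set
# is standardized against 1000 random target-size-matched node sets,
# giving a z-score and one-sided p; candidates pass global FDR < 0.001.

suppressMessages(library(proxscreen))

datadir <- "results/synthetic"
network <- load_network(file.path(datadir, "network.tsv"), score_threshold = 0.4)
drugs <- read_drug_targets(file.path(datadir, "drug_targets.tsv"))
disease <- readLines("results/disease_genes.txt")

screen <- screen_drugs(network, disease, drugs,
                       proximity_config(n_random = 1000, seed = 20260930))
utils::write.table(screen, "results/proximity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("drugs screened:", nrow(screen), "\n")
cat("candidates at FDR < 0.001:", sum(screen$candidate), "\n")
cat(sprintf("top drug: %s (d = %.3f, z = %.2f, fdr = %.2g)\n",
            screen$drug[1], screen$d[1], screen$z[1], screen$fdr[1]))
if (screen$drug[1] == "DRUG_PLANTED") {
  cat("the planted proximal drug ranks first, as designed\n")
}
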