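#!/usr/bin/env Rscript
# Stage 4: rank the dense-module genes as diagnostic biomarkers in the bulk
# cohort (oriented ROC AUC + two-sided Wilcoxon test), pick the hub gene
# (differential first, AUC second), and expand it into a correlated gene
# set (Pearson r > 0.95, P < 0.001) — the disease gene set for the screen.

suppressMessages(library(proxscreen))

datadir <- "results/synthetic"
expr <- read_expression(file.path(datadir, "expression.tsv"),
                        file.path(datadir, "samples.tsv"))
complexes <- utils::read.delim("results/complexes.tsv",
                               stringsAsFactors = FALSE)
candidates <- sort(unique(unlist(
  strsplit(complexes$members[seq_len(min(2, nrow(complexes)))], ","))))
cat("diagnostic candidates from top complexes:", length(candidates), "\n")

ranking <- rank_candidates(expr, candidates)
utils::write.table(ranking, "results/diagnostics.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("best candidate: %s (AUC %.3f, Wilcoxon p %.2g)\n",
            ranking$gene[1], ranking$auc[1], ranking$wilcoxon_p[1]))

hub <- select_hub(ranking)
if (is.na(hub)) stop("no differentially expressed candidate; cannot continue")
cat("hub gene:", hub, "\n")

expansion <- expand_correlated(expr, hub)
utils::write.table(expansion, "results/expansion.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
disease_set <- sort(c(hub, expansion$gene[expansion$selected]))
writeLines(disease_set, "results/disease_genes.txt")
cat("correlated genes at r > 0.95 & p < 0.001:", sum(expansion$selected),
    "; disease set size:", length(disease_set), "\n")
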