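#!/usr/bin/env Rscript
# Stage 2: single-cell QC, cluster differential abundance, and marker genes.
# Cells pass QC when 100 <= genes <= 7500, mitochondrial content < 35% and
# UMIs > 1000. Cluster abundance is compared between conditions with a
# Fisher exact test; clusters with fold change > 4 or < 0.25 at P < 0.05 are
# the key clusters. Markers require log2FC >= 0.5, expression fraction
# >= 0.35 and P < 0.05.

suppressMessages(library(proxscreen))

datadir <- "results/synthetic"
cells <- read_cells(file.path(datadir, "cells.tsv"))
cells_qc <- qc_filter(cells)
write_cells(cells_qc, "results/cells_qc.tsv")

abundance <- abundance_test(cells_qc)
utils::write.table(abundance, "results/abundance.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("differentially abundant clusters:",
    paste(abundance$cluster[abundance$selected], collapse = ", "), "\n")

counts <- as.matrix(utils::read.delim(file.path(datadir, "cell_expression.tsv"),
                                      row.names = 1, check.names = FALSE))
norm <- log_normalize(counts[, cells_qc$cell_id, drop = FALSE])
markers <- find_markers(norm, cells_qc)
utils::write.table(markers, "results/markers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
top <- top_markers(markers)
cat("markers found:", nrow(markers), "; top-5 table has", nrow(top), "rows\n")
utils::write.table(top, "results/top_markers.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
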