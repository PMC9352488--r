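# Plain-text readers/writers: GMT gene sets, TSV expression/sample tables,
# cell tables, drug-target tables. Everything round-trips.

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then gene ids. Lines
#' with fewer than three fields are an error (with the line number);
#' duplicate genes within a line are collapsed with a warning.
#'
#' @param path GMT file.
#' @return named list of character vectors (empty list for an empty file).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  out <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_ps(sprintf("GMT line %d has %d field(s); need name, description, genes",
                      i, length(fields)))
    }
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d (%s): duplicate genes collapsed",
                      i, fields[1]), call. = FALSE)
      genes <- unique(genes)
    }
    out[[fields[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with its sample-group table
#'
#' The expression TSV has gene ids in the first column and sample ids in the
#' header; the samples TSV maps `sample` to `group`. Every matrix sample must
#' be mapped (error naming the offender); duplicate gene ids and missing
#' values (reported with coordinates) are errors.
#'
#' @param path expression TSV.
#' @param samples_path samples TSV with columns `sample`, `group`.
#' @return an [expression_set()].
#' @export
read_expression <- function(path, samples_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop_ps("duplicate gene id(s): ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- genes
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_ps(sprintf("missing value at gene %s, sample %s",
                    rownames(values)[idx[1]], colnames(values)[idx[2]]))
  }
  smp <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  assert_cols(smp, c("sample", "group"), "samples table")
  unmapped <- setdiff(colnames(values), smp$sample)
  if (length(unmapped)) {
    stop_ps("sample(s) missing from the samples file: ",
            paste(unmapped, collapse = ", "))
  }
  expression_set(values, stats::setNames(smp$group, smp$sample))
}

#' Write an expression set as TSV (matrix + samples table)
#'
#' @param expr an [expression_set()].
#' @param path expression TSV output.
#' @param samples_path samples TSV output (written when the set has groups).
#' @export
write_expression <- function(expr, path, samples_path = NULL) {
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(samples_path) && !is.null(expr$group)) {
    utils::write.table(
      data.frame(sample = expr$samples, group = as.character(expr$group)),
      samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a cell table
#'
#' @param path TSV with columns `cell_id`, `cluster`, `condition`,
#'   `n_genes`, `pct_mito`, `n_umi`.
#' @return data.frame.
#' @export
read_cells <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("cell_id", "cluster", "condition",
                    "n_genes", "pct_mito", "n_umi"), "cells file")
  df
}

#' @rdname read_cells
#' @param cells data.frame as from [gen_cell_table()].
#' @export
write_cells <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a drug-target table
#'
#' @param path TSV with columns `drug`, `target`.
#' @return named list drug -> character vector of targets.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert_cols(df, c("drug", "target"), "drug-target file")
  split(df$target, df$drug)
}

#' @rdname read_drug_targets
#' @param drugs named list drug -> targets.
#' @export
write_drug_targets <- function(drugs, path) {
  df <- data.frame(drug = rep(names(drugs), lengths(drugs)),
                   target = unlist(drugs, use.names = FALSE),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every synthetic input of the pipeline to a directory
#'
#' Runs all generators of a [synth_config()] and writes `network.tsv`,
#' `genesets.gmt`, `expression.tsv`, `samples.tsv`, `cells.tsv`,
#' `cell_expression.tsv` and `drug_targets.tsv` to `outdir`. The planted
#' truth (clique members, module/discriminative genes, planted drug) is
#' returned invisibly for tests.
#'
#' @param config a [synth_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the generated objects and ground truth.
#' @export
write_simulation <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  network <- gen_network(config)
  lists <- gen_gene_lists(network, config)
  clique1 <- network$planted_cliques[[1]]
  module_genes <- sort(clique1)[seq_len(min(config$module_size, length(clique1)))]
  planted_gene <- module_genes[1]
  expr <- gen_expression(config, planted_genes = planted_gene,
                         module_genes = module_genes)
  cells <- gen_cell_table(config)
  cell_expr <- gen_cell_expression(config, cells)
  drugs <- gen_drug_targets(network, clique1, config)
  write_network(network, file.path(outdir, "network.tsv"))
  write_gmt(c(lists, list(planted_module = module_genes)),
            file.path(outdir, "genesets.gmt"))
  write_expression(expr, file.path(outdir, "expression.tsv"),
                   file.path(outdir, "samples.tsv"))
  write_cells(cells, file.path(outdir, "cells.tsv"))
  write_expression(cell_expr, file.path(outdir, "cell_expression.tsv"))
  write_drug_targets(drugs, file.path(outdir, "drug_targets.tsv"))
  invisible(list(network = network, gene_lists = lists, expr = expr,
                 cells = cells, cell_expr = cell_expr, drugs = drugs,
                 truth = list(cliques = network$planted_cliques,
                              module_genes = module_genes,
                              planted_gene = planted_gene,
                              planted_drug = "DRUG_PLANTED",
                              cell_markers = attr(cell_expr, "truth"))))
}
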