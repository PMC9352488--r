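#' Load an interaction network from a TSV/SIF edge list
#'
#' Reads two- or three-column tab-separated edges (`node_a`, `node_b`,
#' optional `score`), drops edges at or below the confidence threshold,
#' removes self-loops and duplicate edges (with a reported count), and
#' returns an undirected simple graph. Score dialect is auto-detected: any
#' score above 1 implies the 0-1000 convention, in which case a threshold
#' given on the 0-1 scale is rescaled (0.4 becomes 400).
#'
#' @param path edge-list file; a header line (`node_a ...`) is auto-detected.
#' @param score_threshold keep edges with score strictly greater than this
#'   (default 0.4). Ignored when the file has no score column.
#' @return an `igraph` with edge attribute `score` when present.
#' @export
load_network <- function(path, score_threshold = 0.4) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_ps("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 2L)) {
    stop_ps(sprintf("unparseable line %d in %s (need >= 2 tab-separated fields)",
                    which(nfield < 2L)[1], path))
  }
  has_header <- identical(fields[[1]][1:2], c("node_a", "node_b")) ||
    (nfield[1] >= 3L && is.na(suppressWarnings(as.numeric(fields[[1]][3]))))
  if (has_header) fields <- fields[-1]
  if (!length(fields)) stop_ps("no edges in network file: ", path)
  a <- vapply(fields, `[`, character(1), 1L)
  b <- vapply(fields, `[`, character(1), 2L)
  has_score <- all(lengths(fields) >= 3L)
  edges <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  if (has_score) {
    score <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    if (anyNA(score)) {
      stop_ps(sprintf("unparseable score on line %d of %s",
                      which(is.na(score))[1] + has_header, path))
    }
    if (max(score) > 1 && score_threshold <= 1) {
      score_threshold <- score_threshold * 1000
      message(sprintf(
        "load_network: 0-1000 score dialect detected; threshold set to %g",
        score_threshold))
    }
    keep <- score > score_threshold
    message(sprintf("load_network: %d of %d edges pass score > %g",
                    sum(keep), length(keep), score_threshold))
    edges <- edges[keep, , drop = FALSE]
    edges$score <- score[keep]
  }
  n_raw <- nrow(edges)
  self <- edges$a == edges$b
  edges <- edges[!self, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "first"))
  dropped <- n_raw - igraph::ecount(g)
  if (dropped > 0) {
    message(sprintf("load_network: dropped %d duplicate/self edge(s)", dropped))
  }
  g
}

#' Write a network edge list
#'
#' @param network an `igraph`.
#' @param path output TSV (`node_a`, `node_b`, `score`).
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  df <- data.frame(node_a = el[, 1], node_b = el[, 2],
                   stringsAsFactors = FALSE)
  score <- igraph::edge_attr(network, "score")
  if (!is.null(score)) df$score <- score
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Intersect gene sets
#'
#' Returns the genes present in every input set (Venn-style core). Warns when
#' the intersection is empty.
#'
#' @param sets list of at least two character vectors.
#' @return character vector of shared genes, sorted.
#' @export
intersect_sets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L) stop_ps("need at least two gene sets")
  common <- sort(Reduce(intersect, sets))
  if (!length(common)) warning("gene sets have an empty intersection", call. = FALSE)
  common
}

#' Restrict a network to a gene subset and drop sparsely connected nodes
#'
#' Takes the induced subgraph on `genes` (all nodes when NULL), then removes
#' nodes whose degree in that subgraph falls below `min_degree` (default:
#' isolated nodes). Removal is single-pass by default; `iterate = TRUE`
#' repeats it to a fixed point (degree-core peeling).
#'
#' @param network an `igraph`.
#' @param genes character vector of node names, or NULL.
#' @param min_degree minimum retained degree (default 1).
#' @param iterate repeat removal until no node falls below `min_degree`.
#' @return the pruned `igraph` (possibly empty, with a warning).
#' @export
prune_low_degree <- function(network, genes = NULL, min_degree = 1L,
                             iterate = FALSE) {
  g <- if (is.null(genes)) network else {
    igraph::induced_subgraph(network, intersect(genes, igraph::V(network)$name))
  }
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < min_degree]
    if (!length(low)) break
    g <- igraph::delete_vertices(g, low)
    if (!iterate) break
  }
  if (igraph::vcount(g) == 0L) {
    warning("pruning removed every node", call. = FALSE)
  }
  g
}
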