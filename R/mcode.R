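# Molecular Complex Detection (MCODE): three stages — local vertex weighting
# by the density of the highest k-core of each node's closed neighborhood,
# seeded expansion governed by the vertex weight percentage (VWP), and
# post-processing (haircut = 2-core of the complex; optional fluff).

graph_density <- function(n, e) if (n >= 2) 2 * e / (n * (n - 1)) else 0

#' MCODE vertex weight
#'
#' Weight of node `v`: take the subgraph induced by `v` and its neighbors,
#' find its highest k-core (maximum-k core, by minimum-degree peeling), and
#' return `k * density` of that core. Isolated vertices weigh 0.
#'
#' @param network an `igraph` with named vertices.
#' @param v a vertex name.
#' @return numeric weight (dimensionless, >= 0).
#' @export
mcode_vertex_weight <- function(network, v) {
  nb <- igraph::neighbors(network, v)$name
  if (!length(nb)) return(0)
  sub <- igraph::induced_subgraph(network, c(v, nb))
  core <- igraph::coreness(sub)
  k <- max(core)
  if (k == 0L) return(0)
  members <- names(core)[core == k]
  core_sub <- igraph::induced_subgraph(sub, members)
  k * graph_density(igraph::vcount(core_sub), igraph::ecount(core_sub))
}

#' MCODE vertex weights for every node
#'
#' @param network an `igraph` with named vertices.
#' @return named numeric vector of weights.
#' @export
mcode_vertex_weights <- function(network) {
  nodes <- igraph::V(network)$name
  vapply(nodes, function(v) mcode_vertex_weight(network, v), numeric(1))
}

#' MCODE complex score
#'
#' Density of the induced subgraph times its member count — the standard
#' MCODE ranking score.
#'
#' @param network an `igraph`.
#' @param members character vector of at least two node names.
#' @return numeric score.
#' @export
score_complex <- function(network, members) {
  if (length(members) < 2L) stop_ps("a complex needs at least two members")
  sub <- igraph::induced_subgraph(network, members)
  graph_density(igraph::vcount(sub), igraph::ecount(sub)) * igraph::vcount(sub)
}

#' Detect dense complexes with MCODE
#'
#' Seeds are taken in descending vertex weight (ties broken by node id).
#' From each unvisited seed, neighbors are included breadth-first when their
#' weight is at least `seed_weight * (1 - vwp)`; vertices already assigned
#' to a complex are never re-seeded nor added to another complex. Post-
#' processing: `haircut` reduces each complex to its 2-core (members with a
#' single internal connection are peeled off); `fluff` adds neighbors whose
#' closed-neighborhood density exceeds `fluff_density` (fluffed nodes may
#' overlap complexes). Complexes with fewer than two members are discarded;
#' output is sorted by descending score.
#'
#' @param network a non-empty `igraph` with named vertices.
#' @param vwp vertex weight percentage, the expansion tolerance (default 0.2).
#' @param haircut apply the 2-core post-processing (default TRUE).
#' @param fluff add dense-neighborhood fringe nodes (default FALSE).
#' @param fluff_density density threshold for fluffing (default 0.5).
#' @return list of complexes, each a list with `seed`, `members` (sorted),
#'   `score`.
#' @export
mcode_find_complexes <- function(network, vwp = 0.2, haircut = TRUE,
                                 fluff = FALSE, fluff_density = 0.5) {
  if (igraph::vcount(network) == 0L) stop_ps("empty network")
  w <- mcode_vertex_weights(network)
  order_idx <- order(-w, names(w))
  visited <- stats::setNames(logical(length(w)), names(w))
  complexes <- list()
  for (seed in names(w)[order_idx]) {
    if (visited[seed]) next
    threshold <- w[seed] * (1 - vwp)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nbrs <- unique(unlist(lapply(
        igraph::adjacent_vertices(network, frontier), function(x) x$name)))
      nbrs <- nbrs[!visited[nbrs] & w[nbrs] >= threshold]
      visited[nbrs] <- TRUE
      members <- c(members, nbrs)
      frontier <- nbrs
    }
    if (haircut && length(members) >= 2L) {
      sub <- igraph::induced_subgraph(network, members)
      core <- igraph::coreness(sub)
      members <- names(core)[core >= 2L]
    }
    if (fluff && length(members)) {
      fringe <- setdiff(unique(unlist(lapply(
        igraph::adjacent_vertices(network, members), function(x) x$name))),
        members)
      dens <- vapply(fringe, function(u) {
        nb <- c(u, igraph::neighbors(network, u)$name)
        sub <- igraph::induced_subgraph(network, nb)
        graph_density(igraph::vcount(sub), igraph::ecount(sub))
      }, numeric(1))
      members <- c(members, fringe[dens > fluff_density])
    }
    if (length(members) < 2L) next
    complexes[[length(complexes) + 1L]] <- list(
      seed = seed,
      members = sort(members),
      score = score_complex(network, members)
    )
  }
  if (length(complexes)) {
    ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
                 vapply(complexes, `[[`, character(1), "seed"))
    complexes <- complexes[ord]
  }
  complexes
}
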