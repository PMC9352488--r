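# Independent oracles used across test files. Each is a deliberately naive,
# brute-force computation kept separate from the package implementation.

# AUC by counting concordant pairs (half credit for ties).
oracle_auc <- function(values, labels, positive) {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# Exact two-sided rank-sum p by enumerating all rank assignments.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(n, length(x))
  w_all <- apply(combos, 2, function(idx) sum(idx) - length(x) * (length(x) + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
oracle_floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  d <- matrix(Inf, n, n, dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
  diag(d) <- 0
  el <- igraph::as_edgelist(g)
  for (i in seq_len(nrow(el))) d[el[i, 1], el[i, 2]] <- d[el[i, 2], el[i, 1]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# MCODE vertex weight by explicit minimum-degree peeling of the closed
# neighborhood (no igraph coreness).
oracle_vertex_weight <- function(g, v) {
  nb <- igraph::neighbors(g, v)$name
  if (!length(nb)) return(0)
  members <- c(v, nb)
  adj <- igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, members), sparse = FALSE)
  best_k <- 0
  best <- NULL
  k <- 1
  repeat {
    cur <- adj
    repeat {
      if (!nrow(cur)) break
      drop <- which(rowSums(cur) < k)
      if (!length(drop)) break
      cur <- cur[-drop, -drop, drop = FALSE]
    }
    if (!nrow(cur)) break
    best_k <- k
    best <- cur
    k <- k + 1
  }
  if (is.null(best) || nrow(best) < 2) return(0)
  n <- nrow(best)
  e <- sum(best) / 2
  best_k * (2 * e / (n * (n - 1)))
}

# Random simple graph with named vertices.
random_graph <- function(n, p = 0.4) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  g
}
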