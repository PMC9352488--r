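# Network-proximity drug screen: average weighted closest distance between a
# drug's target set T and the disease gene set S, standardized against a
# size-matched randomization null.
#
#   d(S, T) = (1 / |T|) * sum over t in T of [ min over s in S of d(s, t) + w_t ]
#   w_t = -ln(D_t + 1) when t is itself a disease gene (D_t = degree of t),
#         otherwise w_t = 0
#   z(S, T) = (d(S, T) - mu_{d(S, R)}) / sigma_{d(S, R)}
#
# with mu/sigma taken over random target-size-matched node sets R.

#' Configuration for the proximity screen
#'
#' @param n_random number of randomized reference sets (default 1000).
#' @param seed RNG seed for the reference draws.
#' @param weight_mode `"omega_degree"` applies the -ln(degree + 1) bonus to
#'   targets inside the disease set; `"omega_zero"` disables the weight
#'   (sensitivity analysis).
#' @param degree_matched_null match the degree distribution of the target
#'   set in the reference draws (log2-degree bins) instead of uniform
#'   sampling (default FALSE: size matching only).
#' @param restrict_lcc compute on the network's largest connected component
#'   (default TRUE), avoiding infinite-distance artifacts.
#' @return list of class `proximity_config`.
#' @export
proximity_config <- function(n_random = 1000L, seed = 1L,
                             weight_mode = c("omega_degree", "omega_zero"),
                             degree_matched_null = FALSE,
                             restrict_lcc = TRUE) {
  structure(list(
    n_random = assert_count(n_random, "n_random"),
    seed = assert_count(seed, "seed", min = 0L),
    weight_mode = match.arg(weight_mode),
    degree_matched_null = isTRUE(degree_matched_null),
    restrict_lcc = isTRUE(restrict_lcc)
  ), class = "proximity_config")
}

#' Largest connected component of a network
#'
#' @param network an `igraph`.
#' @return the induced subgraph on the largest component.
#' @export
largest_component <- function(network) {
  comp <- igraph::components(network)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(network, keep)
}

#' Hop distances from a gene set to every node
#'
#' Multi-source breadth-first distances on the unweighted, undirected graph:
#' for every node, the minimum shortest-path length to any source. Nodes
#' unreachable from every source are `Inf`.
#'
#' @param network an `igraph` with named vertices.
#' @param sources character vector of source node names (at least one must
#'   be in the network).
#' @return named numeric vector over all nodes.
#' @export
shortest_path_lengths <- function(network, sources) {
  src <- intersect(sources, igraph::V(network)$name)
  if (!length(src)) stop_ps("no source gene is in the network")
  d <- igraph::distances(network, v = src, to = igraph::V(network))
  out <- apply(d, 2, min)
  names(out) <- igraph::V(network)$name
  out
}

#' Weight term of the proximity distance for a single target
#'
#' `-ln(degree(t) + 1)` when the target is a member of the disease set
#' (rewarding drugs that hit disease genes directly, with hubs rewarded
#' more), 0 otherwise. `weight_mode = "omega_zero"` returns 0 always.
#'
#' @param network an `igraph`.
#' @param target a target node name.
#' @param disease_genes the disease gene set.
#' @param weight_mode `"omega_degree"` (default) or `"omega_zero"`.
#' @return the weight (<= 0).
#' @export
omega_weight <- function(network, target, disease_genes,
                         weight_mode = "omega_degree") {
  if (weight_mode == "omega_zero" || !(target %in% disease_genes)) return(0)
  unname(-log(igraph::degree(network, target) + 1))
}

# Per-node value vector d_min_to_S + omega, the workhorse of the screen: a
# drug's distance is then just the mean over its (reachable) target nodes.
proximity_value_vector <- function(network, disease_genes,
                                   weight_mode = "omega_degree") {
  d <- shortest_path_lengths(network, disease_genes)
  omega <- numeric(length(d))
  names(omega) <- names(d)
  if (weight_mode == "omega_degree") {
    members <- intersect(disease_genes, names(d))
    omega[members] <- -log(igraph::degree(network, members) + 1)
  }
  d + omega
}

#' Average weighted closest distance between disease genes and drug targets
#'
#' Implements `d(S, T) = (1/|T'|) sum_{t in T'} [min_{s in S} d(s, t) +
#' omega_t]` where `T'` is the set of targets mapped onto the network and
#' reachable from S (unmapped/unreachable targets are dropped with a
#' message). Duplicate targets count once (set semantics).
#'
#' @param network an `igraph` with named vertices.
#' @param disease_genes disease gene set S.
#' @param targets drug target set T.
#' @param weight_mode `"omega_degree"` (default) or `"omega_zero"`.
#' @return list with `d` (NA when no target is usable) and
#'   `n_targets_used`.
#' @export
weighted_closest_distance <- function(network, disease_genes, targets,
                                      weight_mode = "omega_degree") {
  targets <- unique(targets)
  mapped <- intersect(targets, igraph::V(network)$name)
  if (length(mapped) < length(targets)) {
    message(sprintf("weighted_closest_distance: %d target(s) not in network",
                    length(targets) - length(mapped)))
  }
  if (!length(mapped)) return(list(d = NA_real_, n_targets_used = 0L))
  val <- proximity_value_vector(network, disease_genes, weight_mode)[mapped]
  usable <- is.finite(val)
  if (!all(usable)) {
    message(sprintf("weighted_closest_distance: %d target(s) unreachable from S",
                    sum(!usable)))
  }
  if (!any(usable)) return(list(d = NA_real_, n_targets_used = 0L))
  list(d = mean(val[usable]), n_targets_used = sum(usable))
}

# Draw reference target sets. `value` is the precomputed per-node value
# vector restricted to eligible nodes. Returns the vector of null distances.
draw_null_distances <- function(value, t_size, n_random,
                                degrees = NULL, target_degrees = NULL) {
  eligible <- names(value)[is.finite(value)]
  if (t_size > length(eligible)) stop_ps("reference set size exceeds eligible nodes")
  if (is.null(target_degrees)) {
    vals <- value[eligible]
    vapply(seq_len(n_random), function(i) {
      mean(vals[sample.int(length(vals), t_size)])
    }, numeric(1))
  } else {
    # degree-binned matching: log2 bins, small bins merged upward
    bin_of <- function(d) pmin(floor(log2(pmax(d, 1))), 8)
    bins <- bin_of(degrees[eligible])
    by_bin <- split(eligible, bins)
    tbins <- as.character(bin_of(target_degrees))
    vapply(seq_len(n_random), function(i) {
      picks <- vapply(tbins, function(b) {
        pool <- by_bin[[b]] %||% eligible
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      mean(value[picks])
    }, numeric(1))
  }
}

#' Randomized reference distribution of the proximity distance
#'
#' Draws `n_random` node sets R of the given size (uniformly without
#' replacement by default; degree-binned when `degree_matched_null`),
#' computes the weighted closest distance d(S, R) for each, and returns the
#' sample mean and standard deviation (denominator n - 1). Fully reproducible
#' from the config seed.
#'
#' @param network an `igraph`.
#' @param disease_genes disease gene set S.
#' @param t_size number of nodes per reference set (matches the drug's
#'   target count).
#' @param config a [proximity_config()].
#' @param target_degrees degrees of the real target set, required when
#'   `degree_matched_null` is on.
#' @param keep_samples return the raw null distances too.
#' @return list with `mu`, `sigma`, `degenerate` (TRUE when sigma is 0 or
#'   undefined), and optionally `samples`.
#' @export
reference_distribution <- function(network, disease_genes, t_size,
                                   config = proximity_config(),
                                   target_degrees = NULL,
                                   keep_samples = FALSE) {
  value <- proximity_value_vector(network, disease_genes, config$weight_mode)
  degrees <- igraph::degree(network)
  samples <- with_seed(stage_seed(config$seed, 707), {
    draw_null_distances(value, t_size, config$n_random,
                        degrees = degrees,
                        target_degrees = if (config$degree_matched_null) target_degrees)
  })
  sigma <- if (length(samples) > 1L) stats::sd(samples) else NA_real_
  out <- list(mu = mean(samples), sigma = sigma,
              degenerate = !is.finite(sigma) || sigma == 0)
  if (keep_samples) out$samples <- samples
  out
}

#' Proximity z-score of one drug
#'
#' Standardizes the observed weighted closest distance against the
#' randomized reference distribution: `z = (d - mu) / sigma`, with a
#' one-sided lower-tail normal p-value (a drug significantly closer to the
#' disease genes than random gets small p). A degenerate null (sigma = 0)
#' gives z = 0 when d equals mu and +/-Inf otherwise, and is flagged.
#'
#' @param network an `igraph` (restricted to its largest component when the
#'   config says so).
#' @param disease_genes disease gene set S.
#' @param targets the drug's target set T.
#' @param config a [proximity_config()].
#' @return one-row data.frame: `d`, `mu`, `sigma`, `z`, `p`,
#'   `n_targets_used`, `degenerate`.
#' @export
proximity_zscore <- function(network, disease_genes, targets,
                             config = proximity_config()) {
  if (config$restrict_lcc) network <- largest_component(network)
  disease_genes <- intersect(disease_genes, igraph::V(network)$name)
  if (!length(disease_genes)) stop_ps("no disease gene is in the network")
  obs <- weighted_closest_distance(network, disease_genes, targets,
                                   config$weight_mode)
  if (!obs$n_targets_used) stop_ps("no drug target is reachable from the disease set")
  tdeg <- igraph::degree(network,
                         intersect(unique(targets), igraph::V(network)$name))
  ref <- reference_distribution(network, disease_genes, obs$n_targets_used,
                                config, target_degrees = tdeg)
  if (ref$degenerate) {
    z <- if (isTRUE(all.equal(obs$d, ref$mu))) 0 else sign(obs$d - ref$mu) * Inf
  } else {
    z <- (obs$d - ref$mu) / ref$sigma
  }
  data.frame(d = obs$d, mu = ref$mu, sigma = ref$sigma, z = z,
             p = stats::pnorm(z), n_targets_used = obs$n_targets_used,
             degenerate = ref$degenerate)
}

#' Screen a drug library by network proximity
#'
#' Computes the proximity z-score of every drug against the disease gene
#' set, adjusts the one-sided p-values across all screened drugs by
#' Benjamini-Hochberg ("global FDR"), flags candidates with `fdr < fdr_max`,
#' and ranks by ascending z (ties: ascending d, then drug id). Reference
#' distributions are shared between drugs with the same usable target count
#' (they are statistically identical), which keeps large screens fast.
#' Drugs with no mapped, reachable target are excluded with a message.
#'
#' @param network an `igraph`.
#' @param disease_genes disease gene set S.
#' @param drugs named list: drug id -> character vector of targets.
#' @param config a [proximity_config()].
#' @param fdr_max candidate threshold on the adjusted p (default 0.001).
#' @return data.frame ranked by z: `drug`, `d`, `mu`, `sigma`, `z`, `p`,
#'   `fdr`, `n_targets_used`, `candidate`, `rank`.
#' @export
screen_drugs <- function(network, disease_genes, drugs,
                         config = proximity_config(), fdr_max = 0.001) {
  if (!length(drugs) || is.null(names(drugs))) {
    stop_ps("'drugs' must be a non-empty named list of target sets")
  }
  if (config$restrict_lcc) network <- largest_component(network)
  disease_genes <- intersect(disease_genes, igraph::V(network)$name)
  if (!length(disease_genes)) stop_ps("no disease gene is in the network")
  value <- proximity_value_vector(network, disease_genes, config$weight_mode)
  nodes <- igraph::V(network)$name
  ref_cache <- new.env(parent = emptyenv())
  rows <- lapply(sort(names(drugs)), function(drug) {
    targets <- unique(drugs[[drug]])
    mapped <- intersect(targets, nodes)
    dropped <- length(targets) - length(mapped)
    if (dropped > 0) {
      message(sprintf("screen_drugs: %s: %d unmapped target(s) dropped",
                      drug, dropped))
    }
    val <- value[mapped]
    val <- val[is.finite(val)]
    if (!length(val)) {
      message(sprintf("screen_drugs: %s has no reachable target; excluded", drug))
      return(NULL)
    }
    size <- length(val)
    key <- as.character(size)
    if (config$degree_matched_null) {
      ref <- reference_distribution(network, disease_genes, size, config,
                                    target_degrees = igraph::degree(network, names(val)))
    } else if (!is.null(ref_cache[[key]])) {
      ref <- ref_cache[[key]]
    } else {
      ref <- reference_distribution(network, disease_genes, size, config)
      ref_cache[[key]] <- ref
    }
    d <- mean(val)
    z <- if (ref$degenerate) {
      if (isTRUE(all.equal(d, ref$mu))) 0 else sign(d - ref$mu) * Inf
    } else (d - ref$mu) / ref$sigma
    data.frame(drug = drug, d = d, mu = ref$mu, sigma = ref$sigma, z = z,
               p = stats::pnorm(z), n_targets_used = size,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop_ps("no drug could be screened")
  res$fdr <- benjamini_hochberg(res$p)
  res$candidate <- res$fdr < fdr_max
  res <- res[order(res$z, res$d, res$drug), ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}
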