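#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter of the synthetic study system: a scale-free
#' protein-interaction network with planted cliques (the dense modules MCODE
#' must recover), a bulk expression matrix with planted group-discriminative
#' genes and a factor-model co-expression module, per-cell tables with one
#' condition-enriched cluster, and drug-target maps with one drug planted
#' inside/near the disease module. Identical config + seed yields
#' byte-identical outputs from every generator.
#'
#' Defaults describe the emulated study system: 18 bulk samples (9 per group,
#' mirroring a small case/control islet cohort), an 11-cluster cell population
#' with one strongly T2DM-enriched cluster, a 300-node scale-free network with
#' two planted cliques, a 3-sd discriminative effect and a 0.99 factor loading
#' (expected pairwise module correlation = loading^2 = 0.98).
#'
#' @param seed base RNG seed; each generator derives a fixed per-stage offset
#'   from it so the stages are independent but jointly reproducible.
#' @param n_nodes number of network nodes (synthetic gene universe).
#' @param attachment edges added per node during preferential-attachment
#'   growth.
#' @param planted_clique_sizes integer vector of planted clique sizes
#'   (disjoint node sets made fully connected); may be empty.
#' @param n_genes number of genes measured in the bulk expression matrix
#'   (the first `n_genes` ids of the network gene universe).
#' @param n_samples_per_group bulk samples per condition.
#' @param effect_size standardized mean shift added in condition "T2DM" for
#'   planted discriminative genes.
#' @param module_size number of genes in the correlated module.
#' @param module_loading factor loading lambda in [0, 1): module gene
#'   x = lambda * f + sqrt(1 - lambda^2) * eps, so the expected pairwise
#'   Pearson correlation between module genes is lambda^2.
#' @param n_cells_per_condition cells simulated per condition.
#' @param cluster_proportions named probability vector of baseline cluster
#'   frequencies (names are cluster ids); must sum to 1.
#' @param enriched_cluster cluster id whose probability is multiplied by
#'   `enrichment_fc` in condition "T2DM" (then renormalized).
#' @param enrichment_fc enrichment ratio (> 0; 1 = null configuration).
#' @param n_drugs number of background drugs (one extra planted drug is
#'   always added).
#' @param targets_per_drug targets per drug.
#' @param planted_overlap number of the planted drug's targets drawn inside
#'   the disease gene set (the rest are drawn adjacent to it).
#' @param qc_fail_fraction fraction of simulated cells given a deliberately
#'   failing QC metric.
#' @param qc_ranges list of passing ranges for the QC metrics `n_genes`,
#'   `pct_mito`, `n_umi` (each `c(lo, hi)`).
#' @param markers_per_cluster genes planted as markers of each cell cluster
#'   in the per-cell count matrix.
#' @param marker_rate,baseline_rate Poisson rates for marker genes inside
#'   their cluster and for background counts.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_nodes = 300L,
                         attachment = 2L,
                         planted_clique_sizes = c(8L, 6L),
                         n_genes = 300L,
                         n_samples_per_group = 9L,
                         effect_size = 3,
                         module_size = 8L,
                         module_loading = 0.99,
                         n_cells_per_condition = 2000L,
                         cluster_proportions = c(
                           C0 = 0.30, C1 = 0.20, C2 = 0.10, C3 = 0.08,
                           C4 = 0.07, C5 = 0.06, C6 = 0.05, C7 = 0.05,
                           C8 = 0.04, C9 = 0.03, C10 = 0.02),
                         enriched_cluster = "C2",
                         enrichment_fc = 20,
                         n_drugs = 50L,
                         targets_per_drug = 5L,
                         planted_overlap = 3L,
                         qc_fail_fraction = 0.05,
                         qc_ranges = list(n_genes = c(500, 6000),
                                          pct_mito = c(0, 20),
                                          n_umi = c(2000, 20000)),
                         markers_per_cluster = 2L,
                         marker_rate = 5,
                         baseline_rate = 0.5) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    n_nodes = assert_count(n_nodes, "n_nodes"),
    attachment = assert_count(attachment, "attachment"),
    planted_clique_sizes = as.integer(planted_clique_sizes),
    n_genes = assert_count(n_genes, "n_genes"),
    n_samples_per_group = assert_count(n_samples_per_group, "n_samples_per_group"),
    effect_size = effect_size,
    module_size = assert_count(module_size, "module_size"),
    module_loading = module_loading,
    n_cells_per_condition = assert_count(n_cells_per_condition, "n_cells_per_condition"),
    cluster_proportions = cluster_proportions,
    enriched_cluster = as.character(enriched_cluster),
    enrichment_fc = enrichment_fc,
    n_drugs = assert_count(n_drugs, "n_drugs"),
    targets_per_drug = assert_count(targets_per_drug, "targets_per_drug"),
    planted_overlap = assert_count(planted_overlap, "planted_overlap", min = 0L),
    qc_fail_fraction = qc_fail_fraction,
    qc_ranges = qc_ranges,
    markers_per_cluster = assert_count(markers_per_cluster, "markers_per_cluster", min = 0L),
    marker_rate = marker_rate,
    baseline_rate = baseline_rate
  )
  if (length(cfg$planted_clique_sizes) &&
      (any(cfg$planted_clique_sizes < 2L) ||
       sum(cfg$planted_clique_sizes) > cfg$n_nodes)) {
    stop_ps("planted clique sizes must be >= 2 and fit disjointly in n_nodes")
  }
  if (cfg$module_loading < 0 || cfg$module_loading >= 1) {
    stop_ps("'module_loading' must lie in [0, 1)")
  }
  if (is.null(names(cfg$cluster_proportions))) {
    stop_ps("'cluster_proportions' must be named by cluster id")
  }
  assert_prob(cfg$cluster_proportions, "cluster_proportions")
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-9) {
    stop_ps("'cluster_proportions' must sum to 1 (within 1e-9)")
  }
  if (!cfg$enriched_cluster %in% names(cfg$cluster_proportions)) {
    stop_ps("'enriched_cluster' is not a cluster id in 'cluster_proportions'")
  }
  if (cfg$enrichment_fc <= 0) stop_ps("'enrichment_fc' must be > 0")
  assert_prob(cfg$qc_fail_fraction, "qc_fail_fraction")
  if (cfg$planted_overlap > cfg$targets_per_drug) {
    stop_ps("'planted_overlap' cannot exceed 'targets_per_drug'")
  }
  if (cfg$n_genes > cfg$n_nodes) {
    stop_ps("'n_genes' cannot exceed 'n_nodes' (expression measures network genes)")
  }
  structure(cfg, class = "synth_config")
}

synth_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free interaction network with planted cliques
#'
#' Grows an undirected preferential-attachment (Barabasi-Albert style)
#' background graph — PPI degree distributions are heavy-tailed — and plants
#' fully connected cliques on disjoint, randomly chosen node sets to give the
#' dense-module detector a known ground truth. Each edge carries a confidence
#' score drawn uniformly in (0, 1].
#'
#' Background edges carry confidence scores uniform in (0, 1]; edges inside a
#' planted clique are high-confidence, uniform in (0.7, 1], so that standard
#' confidence filtering (score > 0.4) thins the background without destroying
#' the planted modules — the situation a curated high-confidence interactome
#' presents.
#'
#' @param config a [synth_config()].
#' @return an `igraph` with vertex names (stable synthetic gene ids), edge
#'   attribute `score`, and graph attribute `planted_cliques` (list of
#'   character vectors of member ids).
#' @export
gen_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (length(config$planted_clique_sizes) &&
      max(config$planted_clique_sizes) >= config$n_nodes) {
    stop_ps("planted clique size must be smaller than n_nodes")
  }
  with_seed(stage_seed(config$seed, 101), {
    g <- igraph::sample_pa(config$n_nodes, m = config$attachment,
                           directed = FALSE)
    igraph::V(g)$name <- synth_gene_ids(config$n_nodes)
    cliques <- list()
    if (length(config$planted_clique_sizes)) {
      picked <- sample(igraph::V(g)$name, sum(config$planted_clique_sizes))
      idx <- rep(seq_along(config$planted_clique_sizes),
                 config$planted_clique_sizes)
      cliques <- split(picked, idx)
      names(cliques) <- paste0("clique", seq_along(cliques))
      for (members in cliques) {
        pairs <- utils::combn(members, 2L)
        g <- igraph::add_edges(g, as.vector(pairs))
      }
    }
    g <- igraph::simplify(g)
    score <- 1 - stats::runif(igraph::ecount(g))  # (0, 1]
    if (length(cliques)) {
      el <- igraph::as_edgelist(g)
      in_clique <- Reduce(`|`, lapply(cliques, function(members) {
        el[, 1] %in% members & el[, 2] %in% members
      }))
      score[in_clique] <- 0.7 + 0.3 * (1 - stats::runif(sum(in_clique)))
    }
    igraph::E(g)$score <- score
    g$planted_cliques <- cliques
    g
  })
}

#' Generate bulk expression with a planted effect and a correlated module
#'
#' Baseline values are iid standard normal. Genes in `module_genes` share a
#' per-sample latent factor f: x = lambda * f + sqrt(1 - lambda^2) * eps with
#' lambda = `module_loading`, so the expected pairwise Pearson correlation
#' within the module is lambda^2. Genes in `planted_genes` that lie outside
#' the module receive a direct +`effect_size` shift in condition "T2DM".
#' When a planted gene belongs to the module, the group shift is transmitted
#' through the shared factor instead (f gains mean `effect_size` in "T2DM"),
#' modelling a disease-activated co-expression module: a direct shift on one
#' member would destroy the within-module correlation it is meant to anchor.
#'
#' @param config a [synth_config()].
#' @param planted_genes character vector of group-discriminative gene ids.
#' @param module_genes character vector of correlated-module gene ids.
#' @return an [expression_set()] with groups "normal" / "T2DM" and attribute
#'   `truth` (list of the planted sets).
#' @export
gen_expression <- function(config,
                           planted_genes = character(),
                           module_genes = character()) {
  stopifnot(inherits(config, "synth_config"))
  genes <- synth_gene_ids(config$n_genes)
  if (!length(genes)) stop_ps("empty gene universe")
  bad <- setdiff(c(planted_genes, module_genes), genes)
  if (length(bad)) {
    stop_ps("planted/module genes outside the gene universe: ",
            paste(bad, collapse = ", "))
  }
  n <- config$n_samples_per_group
  samples <- c(sprintf("N%02d", seq_len(n)), sprintf("T%02d", seq_len(n)))
  group <- factor(rep(c("normal", "T2DM"), each = n), levels = c("normal", "T2DM"))
  lambda <- config$module_loading
  with_seed(stage_seed(config$seed, 202), {
    values <- matrix(stats::rnorm(length(genes) * 2 * n),
                     nrow = length(genes), ncol = 2 * n,
                     dimnames = list(genes, samples))
    shift_via_factor <- length(intersect(planted_genes, module_genes)) > 0
    if (length(module_genes)) {
      f <- stats::rnorm(2 * n)
      if (shift_via_factor) f <- f + config$effect_size * (group == "T2DM")
      values[module_genes, ] <- lambda * matrix(f, nrow = length(module_genes),
                                                ncol = 2 * n, byrow = TRUE) +
        sqrt(1 - lambda^2) * values[module_genes, , drop = FALSE]
    }
    direct <- setdiff(planted_genes, if (shift_via_factor) module_genes else character())
    if (length(direct)) {
      values[direct, group == "T2DM"] <-
        values[direct, group == "T2DM", drop = FALSE] + config$effect_size
    }
    out <- expression_set(values, group)
    attr(out, "truth") <- list(planted_genes = planted_genes,
                               module_genes = module_genes,
                               shift_via_factor = shift_via_factor)
    out
  })
}

#' Generate a per-cell table with a condition-enriched cluster
#'
#' Draws each cell's cluster label from the configured baseline proportions;
#' in condition "T2DM" the enriched cluster's probability is multiplied by
#' `enrichment_fc` and the vector renormalized. QC metric columns (gene
#' count, mitochondrial percentage, UMI count) are drawn uniformly from the
#' configured passing ranges; a `qc_fail_fraction` of cells instead get one
#' deliberately failing metric (flagged in the hidden `qc_fail` column so
#' filter behaviour can be checked).
#'
#' @param config a [synth_config()].
#' @return data.frame with columns `cell_id`, `cluster`, `condition`,
#'   `n_genes`, `pct_mito`, `n_umi`, `qc_fail`.
#' @export
gen_cell_table <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  base <- config$cluster_proportions
  enriched <- base
  enriched[config$enriched_cluster] <- enriched[config$enriched_cluster] * config$enrichment_fc
  enriched <- enriched / sum(enriched)
  n <- config$n_cells_per_condition
  rng <- config$qc_ranges
  with_seed(stage_seed(config$seed, 303), {
    draw_condition <- function(cond, probs) {
      cluster <- sample(names(probs), n, replace = TRUE, prob = probs)
      fail <- stats::runif(n) < config$qc_fail_fraction
      n_genes <- round(stats::runif(n, rng$n_genes[1], rng$n_genes[2]))
      pct_mito <- stats::runif(n, rng$pct_mito[1], rng$pct_mito[2])
      n_umi <- round(stats::runif(n, rng$n_umi[1], rng$n_umi[2]))
      # failing cells violate exactly one metric, chosen at random
      which_fail <- sample(3L, n, replace = TRUE)
      low_genes <- which(fail & which_fail == 1L)
      high_mito <- which(fail & which_fail == 2L)
      low_umi <- which(fail & which_fail == 3L)
      n_genes[low_genes] <- round(stats::runif(length(low_genes), 5, 99))
      pct_mito[high_mito] <- stats::runif(length(high_mito), 35, 90)
      n_umi[low_umi] <- round(stats::runif(length(low_umi), 50, 1000))
      data.frame(
        cell_id = sprintf("cell_%s_%05d", cond, seq_len(n)),
        cluster = cluster,
        condition = cond,
        n_genes = n_genes,
        pct_mito = pct_mito,
        n_umi = n_umi,
        qc_fail = fail,
        stringsAsFactors = FALSE
      )
    }
    rbind(draw_condition("normal", base), draw_condition("T2DM", enriched))
  })
}

#' Generate a per-cell count matrix with planted cluster markers
#'
#' Background counts are Poisson(`baseline_rate`); for every cluster,
#' `markers_per_cluster` genes are assigned as markers and drawn at
#' Poisson(`marker_rate`) inside that cluster. Used by the marker-detection
#' stage; marker assignments are recorded in the `truth` attribute.
#'
#' @param config a [synth_config()].
#' @param cells a cell table as from [gen_cell_table()].
#' @return an [expression_set()] (genes x cells, no group) with a `truth`
#'   attribute mapping cluster -> marker gene ids.
#' @export
gen_cell_expression <- function(config, cells) {
  stopifnot(inherits(config, "synth_config"))
  assert_cols(cells, c("cell_id", "cluster"), "cell table")
  genes <- synth_gene_ids(config$n_genes)
  clusters <- sort(unique(cells$cluster))
  need <- length(clusters) * config$markers_per_cluster
  if (need > length(genes)) stop_ps("not enough genes for the requested markers")
  with_seed(stage_seed(config$seed, 404), {
    counts <- matrix(stats::rpois(length(genes) * nrow(cells),
                                  config$baseline_rate),
                     nrow = length(genes),
                     dimnames = list(genes, cells$cell_id))
    truth <- list()
    if (config$markers_per_cluster > 0L) {
      marker_ids <- sample(genes, need)
      truth <- split(marker_ids,
                     rep(clusters, each = config$markers_per_cluster))
      for (cl in clusters) {
        in_cl <- cells$cell_id[cells$cluster == cl]
        counts[truth[[cl]], in_cl] <-
          stats::rpois(length(truth[[cl]]) * length(in_cl), config$marker_rate)
      }
    }
    out <- expression_set(counts)
    attr(out, "truth") <- truth
    out
  })
}

#' Generate drug-target sets with one planted proximal drug
#'
#' Background drugs draw `targets_per_drug` targets uniformly from the
#' network nodes. One designated planted drug ("DRUG_PLANTED") draws
#' `planted_overlap` targets inside the disease gene set and the remainder
#' from nodes adjacent to it, making it genuinely network-proximal to the
#' disease module.
#'
#' @param network an `igraph` interaction network.
#' @param disease_genes character vector of disease gene ids (subset of
#'   network nodes).
#' @param config a [synth_config()].
#' @return named list drug id -> character vector of target gene ids.
#' @export
gen_drug_targets <- function(network, disease_genes, config) {
  stopifnot(inherits(config, "synth_config"))
  nodes <- igraph::V(network)$name
  if (config$targets_per_drug > length(nodes)) {
    stop_ps("'targets_per_drug' exceeds the number of network nodes")
  }
  if (!all(disease_genes %in% nodes)) {
    stop_ps("disease genes must be network nodes")
  }
  with_seed(stage_seed(config$seed, 505), {
    drugs <- lapply(seq_len(config$n_drugs), function(i) {
      sample(nodes, config$targets_per_drug)
    })
    names(drugs) <- sprintf("DRUG%03d", seq_len(config$n_drugs))
    k_in <- min(config$planted_overlap, length(disease_genes))
    inside <- sample(disease_genes, k_in)
    neighbors <- setdiff(
      igraph::V(network)$name[unique(unlist(
        igraph::adjacent_vertices(network, disease_genes)))],
      disease_genes)
    k_out <- config$targets_per_drug - k_in
    if (k_out > 0 && length(neighbors) < k_out) {
      stop_ps("not enough neighbors of the disease set for the planted drug")
    }
    drugs[["DRUG_PLANTED"]] <- c(inside,
                                 if (k_out > 0) sample(neighbors, k_out))
    drugs
  })
}

#' Generate disease- and pathway-annotation gene lists
#'
#' Emulates two independently curated disease gene lists whose intersection
#' recovers the first planted clique: each list contains the clique members
#' plus its own random padding, so the Venn-style intersection downstream
#' isolates (approximately) the planted module.
#'
#' @param network an `igraph` from [gen_network()] (must carry planted
#'   cliques).
#' @param config a [synth_config()].
#' @param n_extra random padding genes per list.
#' @return named list of two character vectors (`disease_related`,
#'   `insulin_related`).
#' @export
gen_gene_lists <- function(network, config, n_extra = 30L) {
  stopifnot(inherits(config, "synth_config"))
  cliques <- network$planted_cliques
  if (is.null(cliques) || !length(cliques)) {
    stop_ps("network carries no planted cliques")
  }
  core <- cliques[[1L]]
  pool <- setdiff(igraph::V(network)$name, core)
  with_seed(stage_seed(config$seed, 606), {
    list(
      disease_related = sort(c(core, sample(pool, min(n_extra, length(pool))))),
      insulin_related = sort(c(core, sample(pool, min(n_extra, length(pool)))))
    )
  })
}
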