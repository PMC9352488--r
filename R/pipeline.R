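#' Configuration for an end-to-end pipeline run
#'
#' Bundles the synthetic-data configuration with every stage threshold.
#' Unknown arguments are rejected. All randomness in a run flows from
#' `synth$seed`.
#'
#' @param synth a [synth_config()] describing the simulated inputs.
#' @param qc a [qc_thresholds()].
#' @param fc_hi,fc_lo,alpha abundance selection thresholds.
#' @param min_log2fc,min_pct marker thresholds.
#' @param score_threshold PPI confidence threshold.
#' @param min_degree sparse-node pruning threshold.
#' @param vwp,haircut MCODE expansion/post-processing settings.
#' @param r_min,p_max correlation-expansion thresholds.
#' @param n_random,weight_mode,fdr_max proximity screen settings.
#' @param n_complexes_for_candidates top MCODE complexes whose members become
#'   diagnostic candidates.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            qc = qc_thresholds(),
                            fc_hi = 4, fc_lo = 0.25, alpha = 0.05,
                            min_log2fc = 0.5, min_pct = 0.35,
                            score_threshold = 0.4,
                            min_degree = 1L,
                            vwp = 0.2, haircut = TRUE,
                            r_min = 0.95, p_max = 0.001,
                            n_random = 1000L,
                            weight_mode = "omega_degree",
                            fdr_max = 0.001,
                            n_complexes_for_candidates = 2L) {
  stopifnot(inherits(synth, "synth_config"), inherits(qc, "qc_thresholds"))
  for (nm in c("fc_hi", "fc_lo", "alpha", "min_log2fc", "min_pct",
               "score_threshold", "vwp", "r_min", "p_max", "fdr_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_ps(sprintf("'%s' must be a single finite number", nm))
    }
  }
  if (alpha <= 0 || alpha >= 1) stop_ps("'alpha' must lie in (0, 1)")
  if (vwp < 0 || vwp >= 1) stop_ps("'vwp' must lie in [0, 1)")
  structure(list(synth = synth, qc = qc, fc_hi = fc_hi, fc_lo = fc_lo,
                 alpha = alpha, min_log2fc = min_log2fc, min_pct = min_pct,
                 score_threshold = score_threshold,
                 min_degree = assert_count(min_degree, "min_degree", 0L),
                 vwp = vwp, haircut = isTRUE(haircut),
                 r_min = r_min, p_max = p_max,
                 n_random = assert_count(n_random, "n_random"),
                 weight_mode = match.arg(weight_mode,
                                         c("omega_degree", "omega_zero")),
                 fdr_max = fdr_max,
                 n_complexes_for_candidates =
                   assert_count(n_complexes_for_candidates)),
            class = "pipeline_config")
}

stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  value <- tryCatch(expr, error = function(e) {
    stop_ps(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  rows <- if (is.data.frame(value)) nrow(value) else length(value)
  manifest$stages[[name]] <- list(status = "ok", rows = rows,
                                  seconds = round(proc.time()[["elapsed"]] - t0, 3))
  manifest$value <- value
  manifest
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Orchestrates every stage in order: simulate inputs, QC-filter cells,
#' cluster abundance testing, marker detection on the normalized per-cell
#' counts, gene-list intersection, network restriction and pruning, MCODE
#' complex detection, diagnostic candidate ranking and hub selection,
#' correlation expansion of the hub into the disease gene set, and the
#' network-proximity drug screen. All stage tables are written as TSV under
#' `outdir`, together with a JSON run manifest (tool version, config hash,
#' per-stage row counts and timings, seed). Reruns with the same config are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  m <- list(tool = "proxscreen",
            version = as.character(utils::packageVersion("proxscreen")),
            seed = config$synth$seed,
            config_hash = config_hash(config),
            stages = list())

  m <- stage(m, "simulate", write_simulation(config$synth, outdir))
  sim <- m$value

  # confidence-filtered interactome used by every network stage
  net <- igraph::delete_edges(
    sim$network,
    igraph::E(sim$network)[igraph::E(sim$network)$score <= config$score_threshold])

  m <- stage(m, "qc", qc_filter(sim$cells, config$qc))
  cells_qc <- m$value
  write_tsv(cells_qc, file.path(outdir, "cells_qc.tsv"))

  m <- stage(m, "abundance",
             abundance_test(cells_qc, config$alpha, config$fc_hi, config$fc_lo))
  abundance <- m$value
  write_tsv(abundance, file.path(outdir, "abundance.tsv"))

  m <- stage(m, "markers", {
    norm <- log_normalize(sim$cell_expr)
    keep <- sim$cell_expr$samples %in% cells_qc$cell_id
    norm$values <- norm$values[, keep, drop = FALSE]
    find_markers(norm$values, cells_qc, config$min_log2fc, config$min_pct,
                 config$alpha)
  })
  markers <- m$value
  write_tsv(markers, file.path(outdir, "markers.tsv"))
  write_tsv(top_markers(markers), file.path(outdir, "top_markers.tsv"))

  m <- stage(m, "intersect", intersect_sets(sim$gene_lists))
  shared_genes <- m$value

  m <- stage(m, "prune", {
    g <- prune_low_degree(net, shared_genes, config$min_degree)
    write_network(g, file.path(outdir, "pruned_network.tsv"))
    g
  })
  pruned <- m$value

  m <- stage(m, "mcode",
             mcode_find_complexes(pruned, vwp = config$vwp,
                                  haircut = config$haircut))
  complexes <- m$value
  write_tsv(data.frame(
    complex = seq_along(complexes),
    seed = vapply(complexes, `[[`, character(1), "seed"),
    score = vapply(complexes, `[[`, numeric(1), "score"),
    members = vapply(complexes, function(x) paste(x$members, collapse = ","),
                     character(1))), file.path(outdir, "complexes.tsv"))

  m <- stage(m, "diagnostics", {
    n_top <- min(config$n_complexes_for_candidates, length(complexes))
    candidates <- sort(unique(unlist(
      lapply(complexes[seq_len(n_top)], `[[`, "members"))))
    rank_candidates(sim$expr, candidates)
  })
  ranking <- m$value
  write_tsv(ranking, file.path(outdir, "diagnostics.tsv"))

  m <- stage(m, "hub", {
    hub <- select_hub(ranking)
    if (is.na(hub)) stop("no differentially expressed candidate")
    hub
  })
  hub <- m$value

  m <- stage(m, "expand",
             expand_correlated(sim$expr, hub, config$r_min, config$p_max))
  expansion <- m$value
  write_tsv(expansion, file.path(outdir, "expansion.tsv"))
  disease_set <- sort(c(hub, expansion$gene[expansion$selected]))
  writeLines(disease_set, file.path(outdir, "disease_genes.txt"))

  m <- stage(m, "proximity", {
    pconf <- proximity_config(n_random = config$n_random,
                              seed = config$synth$seed,
                              weight_mode = config$weight_mode)
    screen_drugs(net, disease_set, sim$drugs, pconf, config$fdr_max)
  })
  screen <- m$value
  write_tsv(screen, file.path(outdir, "proximity.tsv"))

  m$value <- NULL
  m$hub <- hub
  m$selected_clusters <- abundance$cluster[abundance$selected]
  m$top_drug <- screen$drug[1]
  jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(m)
}

# Stable hash of a pipeline configuration (md5 of its deparsed value).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}
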