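test_that("generators are pure functions of config and seed", {
  cfg1 <- synth_config(seed = 1, n_nodes = 100, n_genes = 100,
                       planted_clique_sizes = c(5L))
  cfg2 <- synth_config(seed = 2, n_nodes = 100, n_genes = 100,
                       planted_clique_sizes = c(5L))
  g1a <- gen_network(cfg1)
  g1b <- gen_network(cfg1)
  g2 <- gen_network(cfg2)
  expect_identical(igraph::as_edgelist(g1a), igraph::as_edgelist(g1b))
  expect_identical(igraph::E(g1a)$score, igraph::E(g1b)$score)
  expect_false(identical(igraph::as_edgelist(g1a), igraph::as_edgelist(g2)))

  e1a <- gen_expression(cfg1, "G0001", sprintf("G%04d", 1:5))
  e1b <- gen_expression(cfg1, "G0001", sprintf("G%04d", 1:5))
  expect_identical(e1a$values, e1b$values)
  expect_identical(gen_cell_table(cfg1), gen_cell_table(cfg1))
  expect_identical(gen_drug_targets(g1a, g1a$planted_cliques[[1]], cfg1),
                   gen_drug_targets(g1a, g1a$planted_cliques[[1]], cfg1))
})

test_that("network has the requested size and planted cliques are complete", {
  cfg <- synth_config(seed = 7, n_nodes = 100, n_genes = 100,
                      attachment = 2, planted_clique_sizes = integer())
  g <- gen_network(cfg)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::count_multiple(g), rep(1, igraph::ecount(g)))
  expect_false(any(igraph::which_loop(g)))
  expect_true(all(igraph::E(g)$score > 0 & igraph::E(g)$score <= 1))

  cfg5 <- synth_config(seed = 7, n_nodes = 100, n_genes = 100,
                       planted_clique_sizes = c(5L))
  g5 <- gen_network(cfg5)
  members <- g5$planted_cliques[[1]]
  expect_length(members, 5)
  sub <- igraph::induced_subgraph(g5, members)
  expect_equal(igraph::ecount(sub), 10)

  expect_error(synth_config(n_nodes = 4, planted_clique_sizes = c(5L)),
               "clique")
})

test_that("factor model delivers the analytic pairwise correlation", {
  module <- sprintf("G%04d", 1:5)
  rs <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_nodes = 60, n_genes = 60,
                        n_samples_per_group = 25, module_size = 5,
                        module_loading = 0.99, planted_clique_sizes = integer())
    e <- gen_expression(cfg, module_genes = module)
    cm <- cor(t(e$values[module, ]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  # loading 0.99 => expected pairwise r = 0.9801
  expect_true(all(rs > 0.9))
  expect_lt(abs(mean(rs) - 0.99^2), 0.02)
})

test_that("null configuration produces iid noise", {
  cfg <- synth_config(seed = 5, n_nodes = 50, n_genes = 50,
                      n_samples_per_group = 100, effect_size = 0,
                      module_loading = 0, planted_clique_sizes = integer())
  e <- gen_expression(cfg, planted_genes = "G0001",
                      module_genes = sprintf("G%04d", 2:6))
  gaps <- rowMeans(e$values[, e$group == "T2DM"]) -
    rowMeans(e$values[, e$group == "normal"])
  expect_lt(max(abs(gaps)), 0.5)
})

test_that("planted discriminative genes separate the groups", {
  hits <- vapply(1:50, function(s) {
    cfg <- synth_config(seed = s, n_nodes = 30, n_genes = 30,
                        n_samples_per_group = 10, effect_size = 3,
                        planted_clique_sizes = integer())
    e <- gen_expression(cfg, planted_genes = "G0001")
    auc_score(e$values["G0001", ], as.character(e$group))$auc > 0.9
  }, logical(1))
  expect_gte(sum(hits), 45)
})

test_that("cell table enrichment and QC failures are calibrated", {
  cfg <- synth_config(seed = 9, n_cells_per_condition = 1000,
                      qc_fail_fraction = 0.1)
  cells <- gen_cell_table(cfg)
  expect_equal(nrow(cells), 2000)
  n_fail <- sum(cells$qc_fail)
  # binomial expectation 200, +/- 3 sd
  expect_lt(abs(n_fail - 200), 3 * sqrt(2000 * 0.1 * 0.9) + 1)
  kept <- suppressMessages(qc_filter(cells))
  expect_equal(nrow(kept), sum(!cells$qc_fail))

  # fc = 1 is the null configuration: every cluster's expected fold change is 1
  cfg0 <- synth_config(seed = 9, n_cells_per_condition = 2000,
                       enrichment_fc = 1)
  ab <- abundance_test(gen_cell_table(cfg0))
  expect_false(any(ab$selected))
  expect_lt(max(abs(ab$fc - 1)), 0.5)
})

test_that("condition-enriched cluster is detected across seeds", {
  hits <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_cells_per_condition = 2000,
                        enrichment_fc = 20)
    ab <- abundance_test(gen_cell_table(cfg))
    row <- ab[ab$cluster == "C2", ]
    row$fc > 4 && row$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("drug-target generation plants one proximal drug", {
  cfg <- synth_config(seed = 4, n_nodes = 100, n_genes = 100,
                      planted_clique_sizes = c(6L), n_drugs = 50,
                      targets_per_drug = 4, planted_overlap = 4)
  g <- gen_network(cfg)
  disease <- g$planted_cliques[[1]]
  drugs <- gen_drug_targets(g, disease, cfg)
  expect_length(drugs, 51)
  expect_true(all(drugs$DRUG_PLANTED %in% disease))
  expect_error(
    gen_drug_targets(g, disease,
                     synth_config(n_nodes = 100, n_genes = 100,
                                  targets_per_drug = 101, planted_overlap = 3)),
    "targets_per_drug")
})

test_that("background drug targets are drawn uniformly", {
  counts <- integer(30)
  for (s in 1:200) {
    cfg <- synth_config(seed = s, n_nodes = 30, n_genes = 30,
                        planted_clique_sizes = c(5L), n_drugs = 1,
                        targets_per_drug = 3, planted_overlap = 1)
    g <- gen_network(cfg)
    tg <- gen_drug_targets(g, g$planted_cliques[[1]], cfg)$DRUG001
    idx <- as.integer(sub("G", "", tg))
    counts[idx] <- counts[idx] + 1L
  }
  # each node's inclusion frequency ~ Binom(200, 3/30); +/- 4 sd band
  expect_true(all(abs(counts - 20) < 4 * sqrt(200 * 0.1 * 0.9)))
})
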