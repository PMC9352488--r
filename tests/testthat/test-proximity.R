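path3 <- function() igraph::graph_from_literal(a - b - c)

test_that("multi-source BFS distances match hand-traced values", {
  g <- igraph::graph_from_literal(a - b - c, d)
  d <- shortest_path_lengths(g, "a")
  expect_equal(d[c("a", "b", "c")], c(a = 0, b = 1, c = 2))
  expect_true(is.infinite(d["d"]))
  expect_error(shortest_path_lengths(g, "zzz"), "no source")
})

test_that("weighted closest distance follows the omega-weighted formula", {
  g <- path3()
  expect_equal(weighted_closest_distance(g, "a", "c")$d, 2)
  # target inside S: omega = -ln(degree + 1); b-a-c gives degree(a) = ... use
  # the path's middle vertex so degree = 2 and d = 0 - ln(3)
  expect_equal(weighted_closest_distance(g, "b", "b")$d, -log(3),
               tolerance = 1e-15)
  expect_equal(weighted_closest_distance(g, "b", "b", "omega_zero")$d, 0)

  star <- igraph::graph_from_literal(h - l1, h - l2, h - l3, h - l4)
  expect_equal(weighted_closest_distance(star, c("l1", "l2"), c("l3", "l4"))$d, 2)
})

test_that("omega weight contract: zero outside S, -ln(D+1) inside", {
  g <- path3()
  expect_identical(omega_weight(g, "c", c("a", "b")), 0)
  expect_identical(omega_weight(g, "b", c("a", "b")), -log(3))
  expect_identical(omega_weight(g, "b", c("a", "b"), "omega_zero"), 0)
})

test_that("distance has set semantics and S-monotonicity", {
  set.seed(17)
  for (i in 1:20) {
    g <- random_graph(12, 0.3)
    g <- largest_component(g)
    nodes <- igraph::V(g)$name
    if (length(nodes) < 5) next
    S <- sample(nodes, 2)
    T_ <- sample(nodes, 2)
    base <- weighted_closest_distance(g, S, T_)
    expect_equal(weighted_closest_distance(g, S, c(T_, T_[1]))$d, base$d)
    # growing S never increases the unweighted distance
    S2 <- c(S, sample(setdiff(nodes, S), 1))
    expect_lte(weighted_closest_distance(g, S2, T_, "omega_zero")$d,
               weighted_closest_distance(g, S, T_, "omega_zero")$d + 1e-12)
  }
})

test_that("targets inside S give zero unweighted distance", {
  g <- largest_component(gen_network(synth_config(seed = 2, n_nodes = 50,
                                                  n_genes = 50,
                                                  planted_clique_sizes = c(5L))))
  S <- intersect(g$planted_cliques[[1]], igraph::V(g)$name)
  expect_equal(weighted_closest_distance(g, S, S[1:3], "omega_zero")$d, 0)
})

test_that("null distribution matches exhaustive enumeration on K10", {
  k10 <- igraph::make_full_graph(10)
  igraph::V(k10)$name <- sprintf("n%02d", 1:10)
  S <- c("n01", "n02", "n03")
  # omega disabled: d for a draw R of size 2 is mean of (0 if in S else 1)
  draws <- utils::combn(sprintf("n%02d", 1:10), 2)
  exact <- apply(draws, 2, function(r) mean(!(r %in% S)))
  cfg <- proximity_config(n_random = 4500, seed = 42,
                          weight_mode = "omega_zero")
  ref <- reference_distribution(k10, S, 2, cfg, keep_samples = TRUE)
  expect_equal(ref$mu, mean(exact), tolerance = 0.02)
  expect_equal(ref$sigma, sd(exact), tolerance = 0.05)
  expect_true(all(ref$samples %in% c(0, 0.5, 1)))

  ref2 <- reference_distribution(k10, S, 2, cfg)
  expect_identical(ref$mu, ref2$mu)
  expect_identical(ref$sigma, ref2$sigma)
})

test_that("degenerate nulls are flagged", {
  ref <- reference_distribution(path3(), "a", 1,
                                proximity_config(n_random = 1, seed = 1))
  expect_true(ref$degenerate)
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  # every size-5 draw is the whole vertex set: sigma = 0, d = mu, z = 0
  res <- proximity_zscore(k5, letters[1:5], letters[1:5],
                          proximity_config(n_random = 10, seed = 1,
                                           weight_mode = "omega_zero"))
  expect_true(res$degenerate)
  expect_equal(res$z, 0)
})

test_that("screening ranks a planted proximal drug first", {
  cfg <- synth_config(seed = 6, n_nodes = 200, n_genes = 200,
                      planted_clique_sizes = c(8L), n_drugs = 30,
                      targets_per_drug = 5, planted_overlap = 4)
  g <- gen_network(cfg)
  S <- g$planted_cliques[[1]]
  drugs <- gen_drug_targets(g, S, cfg)
  res <- suppressMessages(
    screen_drugs(g, S, drugs, proximity_config(n_random = 500, seed = 6)))
  expect_equal(res$drug[1], "DRUG_PLANTED")
  expect_lt(res$z[1], -2)
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("single-drug screens have fdr equal to p", {
  g <- largest_component(gen_network(synth_config(seed = 3, n_nodes = 80,
                                                  n_genes = 80)))
  nodes <- igraph::V(g)$name
  res <- screen_drugs(g, nodes[1:4], list(drg = nodes[5:7]),
                      proximity_config(n_random = 100, seed = 1))
  expect_equal(res$fdr, res$p)
})

test_that("unmapped and unreachable targets are dropped with a message", {
  g <- path3()
  expect_message(
    out <- weighted_closest_distance(g, "a", c("c", "zz")),
    "not in network")
  expect_equal(out$n_targets_used, 1)
  g2 <- igraph::graph_from_literal(a - b, x - y)
  expect_message(
    out2 <- weighted_closest_distance(g2, "a", c("b", "x")),
    "unreachable")
  expect_equal(out2$d, 1)
})

test_that("background-only screens make no discoveries at fdr < 0.001", {
  clean <- vapply(1:10, function(s) {
    cfg <- synth_config(seed = s, n_nodes = 150, n_genes = 150,
                        planted_clique_sizes = c(6L), n_drugs = 30,
                        targets_per_drug = 4, planted_overlap = 0)
    g <- gen_network(cfg)
    S <- g$planted_cliques[[1]]
    drugs <- gen_drug_targets(g, S, cfg)
    drugs$DRUG_PLANTED <- NULL
    res <- suppressMessages(screen_drugs(
      g, S, drugs, proximity_config(n_random = 500, seed = s)))
    !any(res$candidate)
  }, logical(1))
  expect_gte(sum(clean), 9)
})
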