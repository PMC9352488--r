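test_that("auc handles separation, ties and orientation", {
  expect_equal(auc_score(c(3, 4, 1, 2), c("T2DM", "T2DM", "normal", "normal"))$auc, 1)
  tied <- auc_score(rep(1, 6), rep(c("T2DM", "normal"), 3))
  expect_equal(tied$auc, 0.5)
  # positives {1,3} vs negatives {2,4}: 1 concordant of 4 pairs -> raw 0.25
  flip <- auc_score(c(1, 3, 2, 4), c("T2DM", "T2DM", "normal", "normal"))
  expect_equal(flip$raw_auc, 0.25)
  expect_equal(flip$auc, 0.75)
  expect_equal(flip$direction, "normal")
  expect_error(auc_score(1:3, rep("T2DM", 3)), "two groups")
})

test_that("auc equals brute-force pair counting and pROC", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    labels <- c("T2DM", "normal", sample(c("T2DM", "normal"), n - 2, TRUE))
    values <- sample(1:4, n, replace = TRUE)  # force ties
    got <- auc_score(values, labels)
    raw <- oracle_auc(values, labels, "T2DM")
    expect_equal(got$raw_auc, raw, tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(12)
  values <- rnorm(40)
  labels <- rep(c("T2DM", "normal"), 20)
  got <- auc_score(values, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, values, levels = c("normal", "T2DM"),
                                              direction = "<")))
  expect_equal(got$raw_auc, as.numeric(ref), tolerance = 1e-9)
})

test_that("rank-sum p: identical samples, exact enumeration, large shifts", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 0.05)
  # full enumeration over C(6,3)=20 assignments: the observed split is one of
  # the two most extreme -> p = 2/20
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1, tolerance = 1e-12)
  set.seed(3)
  expect_lt(wilcoxon_rank_sum(rnorm(50), rnorm(50) + 2), 1e-6)
})

test_that("pearson r and p match the hand-computed t transform", {
  expect_equal(pearson_with_p(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_with_p(1:10, 2 * (1:10) + 1)$p, 0)
  expect_equal(pearson_with_p(1:5, -(1:5))$r, -1)
  # x = 1:4, y = (1,2,4,3): r = 0.8; p from t = r sqrt(2 / (1 - r^2)), df 2
  got <- pearson_with_p(1:4, c(1, 2, 4, 3))
  expect_equal(got$r, 0.8, tolerance = 1e-12)
  t_ref <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(got$p, 2 * pt(-t_ref, 2), tolerance = 1e-12)
  ct <- cor.test(1:4, c(1, 2, 4, 3))
  expect_equal(got$p, ct$p.value, tolerance = 1e-9)
  expect_true(is.na(pearson_with_p(rep(1, 5), 1:5)$r))
})

make_expr <- function(values, group) {
  expression_set(values, group)
}

test_that("candidate ranking orders by AUC and flags differential genes", {
  set.seed(21)
  group <- rep(c("normal", "T2DM"), each = 10)
  v <- matrix(rnorm(3 * 20), nrow = 3,
              dimnames = list(c("null1", "perfect", "null2"),
                              sprintf("s%02d", 1:20)))
  v["perfect", group == "T2DM"] <- v["perfect", group == "T2DM"] + 100
  expr <- make_expr(v, group)
  res <- suppressMessages(rank_candidates(expr, c("perfect", "null1", "null2", "ghost")))
  expect_equal(res$gene[1], "perfect")
  expect_equal(res$auc[1], 1)
  expect_true(res$differential[1])
  expect_false("ghost" %in% res$gene)
  expect_error(rank_candidates(expr, "ghost"), "no candidate")
})

test_that("hub selection requires differential significance before AUC", {
  res <- data.frame(gene = c("hiAUC", "second"),
                    auc = c(0.95, 0.8),
                    direction = "T2DM",
                    wilcoxon_p = c(0.2, 0.01),
                    differential = c(FALSE, TRUE))
  # the top-AUC gene is not differential: the second gene becomes the hub
  expect_equal(select_hub(res), "second")
  res$differential <- c(TRUE, TRUE)
  expect_equal(select_hub(res), "hiAUC")
  res$differential <- c(FALSE, FALSE)
  expect_message(out <- select_hub(res), "no hub")
  expect_true(is.na(out))
})

test_that("correlation expansion honors the signed threshold", {
  set.seed(5)
  base <- rnorm(20)
  v <- rbind(hub = base, dup = base, anti = -base,
             noise = rnorm(20))
  colnames(v) <- sprintf("s%02d", 1:20)
  expr <- make_expr(v, rep(c("normal", "T2DM"), each = 10))
  res <- expand_correlated(expr, "hub")
  expect_true(res$selected[res$gene == "dup"])
  expect_equal(res$r[res$gene == "dup"], 1)
  expect_false(res$selected[res$gene == "anti"])   # r = -1, signed rule
  expect_false(res$selected[res$gene == "noise"])
  expect_false("hub" %in% res$gene)
  res_abs <- expand_correlated(expr, "hub", absolute = TRUE)
  expect_true(res_abs$selected[res_abs$gene == "anti"])
})

test_that("factor-model module is recovered by expansion", {
  hits <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, n_nodes = 60, n_genes = 60,
                        n_samples_per_group = 9, module_loading = 0.99,
                        planted_clique_sizes = integer())
    module <- sprintf("G%04d", 1:5)
    e <- gen_expression(cfg, module_genes = module)
    res <- expand_correlated(e, "G0001")
    sel <- res$gene[res$selected]
    all(module[-1] %in% sel) && !any(setdiff(res$gene, module) %in% sel)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("fraction correlations: identity, null level, constant rows", {
  set.seed(31)
  samples <- sprintf("s%02d", 1:20)
  v <- matrix(rnorm(20 * 20), nrow = 20,
              dimnames = list(sprintf("g%02d", 1:20), samples))
  expr <- make_expr(v, rep(c("normal", "T2DM"), each = 10))
  fr <- matrix(rnorm(22 * 20), nrow = 22,
               dimnames = list(sprintf("ct%02d", 1:22), samples))
  fr["ct01", ] <- v["g01", ]
  fr["ct02", ] <- 0.5
  res <- correlate_with_fractions(expr, rownames(v), fr)
  top <- res[res$gene == "g01" & res$cell_type == "ct01", ]
  expect_equal(top$r, 1)
  expect_equal(top$tier, "***")
  expect_true(all(is.na(res$r[res$cell_type == "ct02"])))
  # independent noise: ~5% of raw p below 0.05 (binomial +/- 3 sd)
  null_cells <- res[res$cell_type != "ct01" & res$cell_type != "ct02", ]
  frac <- mean(null_cells$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(null_cells)) + 0.01)
  expect_error(correlate_with_fractions(expr, "g01", fr[, 1:2, drop = FALSE]),
               "3 shared")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(0.04, 5)), rep(0.04, 5))
  set.seed(9)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-12))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})
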