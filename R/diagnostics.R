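#' ROC AUC via the rank-sum identity
#'
#' Computes the area under the ROC curve with the Mann-Whitney identity
#' (midranks handle ties): `AUC = (R_pos - n_pos (n_pos + 1) / 2) /
#' (n_pos n_neg)`. The returned AUC is auto-oriented — `max(AUC, 1 - AUC)` —
#' with the scoring direction recorded.
#'
#' @param values numeric scores, one per sample.
#' @param labels two-level factor/character of the same length.
#' @param positive label treated as positive (default "T2DM").
#' @return list with `auc` (oriented, in [0.5, 1]), `raw_auc` (positive
#'   scoring high), and `direction` (label whose samples score higher).
#' @export
auc_score <- function(values, labels, positive = "T2DM") {
  labels <- as.character(labels)
  lvls <- unique(labels)
  if (length(lvls) != 2L || !positive %in% lvls) {
    stop_ps("labels must contain exactly two groups including the positive one")
  }
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop_ps("both groups must be non-empty")
  r <- rank(values)
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  raw <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auc = max(raw, 1 - raw),
       raw_auc = raw,
       direction = if (raw >= 0.5) positive else setdiff(lvls, positive))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Uses the exact null distribution when the combined sample size is at most
#' `exact_max_n` and there are no ties; otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max_n combined-size cutoff for the exact branch (default 12).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12L) {
  if (!length(x) || !length(y)) stop_ps("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y)) <= exact_max_n && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

#' Rank candidate genes by diagnostic performance
#'
#' For each candidate gene present in the expression set, computes the
#' oriented ROC AUC for separating the two sample groups and a two-sided
#' Wilcoxon rank-sum p-value; `differential` flags `p < alpha`. Candidates
#' absent from the matrix are reported via `message()` and skipped. Results
#' are sorted by descending AUC.
#'
#' @param expr an [expression_set()] with a two-level group.
#' @param candidates character vector of gene ids.
#' @param positive group treated as positive for the AUC (default "T2DM").
#' @param alpha differential-expression level (default 0.05).
#' @return data.frame: `gene`, `auc`, `direction`, `wilcoxon_p`,
#'   `differential`.
#' @export
rank_candidates <- function(expr, candidates, positive = "T2DM",
                            alpha = 0.05) {
  stopifnot(inherits(expr, "expr_set"))
  if (is.null(expr$group)) stop_ps("expression set has no group factor")
  present <- intersect(candidates, expr$genes)
  absent <- setdiff(candidates, expr$genes)
  if (length(absent)) {
    message("rank_candidates: not detected in the expression set: ",
            paste(absent, collapse = ", "))
  }
  if (!length(present)) stop_ps("no candidate gene is present in the expression set")
  grp <- as.character(expr$group)
  res <- do.call(rbind, lapply(present, function(gene) {
    v <- expr$values[gene, ]
    a <- auc_score(v, grp, positive)
    p <- wilcoxon_rank_sum(v[grp == positive], v[grp != positive])
    data.frame(gene = gene, auc = a$auc, direction = a$direction,
               wilcoxon_p = p, differential = p < alpha,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$auc, res$gene), ]
  rownames(res) <- NULL
  res
}

#' Select the hub gene
#'
#' Among differentially expressed candidates, returns the gene with the
#' highest AUC (ties broken by gene id). Differential significance is
#' required first: a non-differential gene is never chosen regardless of its
#' AUC — mirroring a screen where only one candidate showed a group
#' difference. When no candidate is differential the explicit "no hub"
#' outcome `NA_character_` is returned (with a message), distinct from an
#' error.
#'
#' @param results data.frame from [rank_candidates()].
#' @return gene id, or `NA_character_` when no candidate is differential.
#' @export
select_hub <- function(results) {
  if (!nrow(results)) stop_ps("empty candidate ranking")
  diff <- results[results$differential, , drop = FALSE]
  if (!nrow(diff)) {
    message("select_hub: no differentially expressed candidate (no hub)")
    return(NA_character_)
  }
  diff <- diff[order(-diff$auc, diff$gene), ]
  diff$gene[1L]
}

#' Pearson correlation with a t-distribution p-value
#'
#' `r` is the sample Pearson coefficient; the two-sided p-value comes from
#' `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. Zero
#' variance in either vector yields an undefined (NA) result.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return list with `r` and `p` (both NA when undefined).
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n < 3L || length(y) != n) stop_ps("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

#' Expand a hub gene into its correlated gene set
#'
#' Correlates every other gene with the hub's expression across samples and
#' selects genes with `r > r_min` and `p < p_max` (signed rule; set
#' `absolute = TRUE` for `|r| > r_min`). Genes with zero variance are
#' reported with NA and never selected. The hub is excluded from its own
#' set.
#'
#' @param expr an [expression_set()].
#' @param hub hub gene id (must be present).
#' @param r_min,p_max selection thresholds (defaults 0.95 and 0.001).
#' @param absolute use `|r|` instead of signed `r` (default FALSE).
#' @return data.frame sorted by descending r: `gene`, `r`, `p`, `selected`.
#' @export
expand_correlated <- function(expr, hub, r_min = 0.95, p_max = 0.001,
                              absolute = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  if (!hub %in% expr$genes) stop_ps("hub gene not in the expression set")
  hub_v <- expr$values[hub, ]
  others <- setdiff(expr$genes, hub)
  res <- do.call(rbind, lapply(others, function(gene) {
    cp <- pearson_with_p(hub_v, expr$values[gene, ])
    data.frame(gene = gene, r = cp$r, p = cp$p, stringsAsFactors = FALSE)
  }))
  stat <- if (absolute) abs(res$r) else res$r
  res$selected <- !is.na(res$r) & stat > r_min & res$p < p_max
  res <- res[order(-res$r, res$gene, na.last = TRUE), ]
  rownames(res) <- NULL
  res
}

#' Correlate gene expression with cell-type fractions
#'
#' For every (gene, cell type) pair, computes the Pearson correlation of the
#' gene's expression with the cell type's fraction across the shared
#' samples, with significance tiers at p < 0.05 / 0.01 / 0.001 (one to three
#' stars). Constant fraction or expression rows yield NA (flagged, no tier).
#'
#' @param expr an [expression_set()].
#' @param genes gene ids to test (present genes only).
#' @param fractions numeric matrix, cell types x samples.
#' @return data.frame: `gene`, `cell_type`, `r`, `p`, `tier` ("", "*",
#'   "**", "***", or NA when undefined).
#' @export
correlate_with_fractions <- function(expr, genes, fractions) {
  stopifnot(inherits(expr, "expr_set"), is.matrix(fractions))
  shared <- intersect(expr$samples, colnames(fractions))
  if (length(shared) < 3L) stop_ps("need at least 3 shared samples")
  genes <- intersect(genes, expr$genes)
  if (!length(genes)) stop_ps("no requested gene is present")
  grid <- expand.grid(gene = genes, cell_type = rownames(fractions),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    cp <- pearson_with_p(expr$values[grid$gene[i], shared],
                         fractions[grid$cell_type[i], shared])
    tier <- if (is.na(cp$p)) NA_character_ else {
      c("", "*", "**", "***")[1 + (cp$p < 0.05) + (cp$p < 0.01) + (cp$p < 0.001)]
    }
    data.frame(gene = grid$gene[i], cell_type = grid$cell_type[i],
               r = cp$r, p = cp$p, tier = tier, stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; input order is
#' preserved. Inputs outside [0, 1] are an error.
#'
#' @param pvals numeric p-values.
#' @return adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_ps("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
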