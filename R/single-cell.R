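#' Quality-control thresholds for single-cell filtering
#'
#' Default thresholds follow common islet scRNA-seq practice: total detected
#' genes between 100 and 7500 (inclusive), mitochondrial content strictly
#' below 35 percent, and strictly more than 1000 UMIs per cell. The gene-count
#' bounds are inclusive; the mitochondrial and UMI thresholds are strict.
#'
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_pct_mito exclusive upper bound on mitochondrial percentage.
#' @param min_umi exclusive lower bound on UMI count.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 100L, max_genes = 7500L,
                          max_pct_mito = 35, min_umi = 1000L) {
  if (min_genes >= max_genes) stop_ps("'min_genes' must be < 'max_genes'")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_pct_mito = max_pct_mito, min_umi = min_umi),
            class = "qc_thresholds")
}

#' Filter cells on quality-control metrics
#'
#' Keeps cells with `min_genes <= n_genes <= max_genes`,
#' `pct_mito < max_pct_mito` and `n_umi > min_umi`; row order is preserved
#' and kept/removed counts are reported via `message()`.
#'
#' @param cells data.frame with columns `n_genes`, `pct_mito`, `n_umi`.
#' @param thresholds a [qc_thresholds()].
#' @return the filtered cell table.
#' @export
qc_filter <- function(cells, thresholds = qc_thresholds()) {
  assert_cols(cells, c("n_genes", "pct_mito", "n_umi"), "cell table")
  keep <- cells$n_genes >= thresholds$min_genes &
    cells$n_genes <= thresholds$max_genes &
    cells$pct_mito < thresholds$max_pct_mito &
    cells$n_umi > thresholds$min_umi
  message(sprintf("qc_filter: kept %d of %d cells (removed %d)",
                  sum(keep), length(keep), sum(!keep)))
  cells[keep, , drop = FALSE]
}

#' Log-normalize an expression matrix
#'
#' Scales every column (cell or sample) to a common library size and applies
#' a log transform: value v in a column with total C becomes
#' `ln(1 + v * scale_factor / C)`.
#'
#' @param values nonnegative numeric matrix (genes x cells), or an
#'   [expression_set()].
#' @param scale_factor target library size (default 10000).
#' @return object of the same class with normalized values.
#' @export
log_normalize <- function(values, scale_factor = 1e4) {
  if (inherits(values, "expr_set")) {
    out <- values
    out$values <- log_normalize(values$values, scale_factor)
    return(out)
  }
  if (any(values < 0)) stop_ps("expression values must be nonnegative")
  totals <- colSums(values)
  if (any(totals == 0)) {
    stop_ps("zero column total for: ",
            paste(colnames(values)[totals == 0], collapse = ", "))
  }
  log1p(sweep(values, 2, totals, "/") * scale_factor)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p-value for the table `[[a, b], [c, d]]` by summing
#' hypergeometric probabilities, over all tables with the same margins, of
#' every table whose probability does not exceed that of the observed table
#' (within relative tolerance `rel_tol`).
#'
#' @param a,b,c,d nonnegative integer cell counts (row-wise).
#' @param rel_tol relative tolerance used when comparing table probabilities.
#' @return the two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d, rel_tol = 1e-7) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != floor(counts))) {
    stop_ps("all four counts must be nonnegative integers")
  }
  m <- a + b
  n <- c + d
  k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
}

#' Selection rule for differentially abundant clusters
#'
#' A cluster is selected when its abundance fold change is extreme
#' (`fc > fc_hi` or `fc < fc_lo`) and its raw Fisher p-value is below
#' `alpha`.
#'
#' @param fc abundance fold changes.
#' @param p raw p-values.
#' @param fc_hi,fc_lo fold-change selection bounds (defaults 4 and 0.25).
#' @param alpha significance level (default 0.05).
#' @return logical vector.
#' @export
abundance_select <- function(fc, p, fc_hi = 4, fc_lo = 0.25, alpha = 0.05) {
  (fc > fc_hi | fc < fc_lo) & p < alpha
}

#' Cluster differential-abundance test
#'
#' For every cluster, compares its share of cells between the two conditions:
#' fold change is the ratio of condition-normalized proportions
#' `(n_cT / N_T) / (n_cN / N_N)` and significance is a two-sided Fisher exact
#' test on the cluster-vs-rest by condition 2x2 table. Benjamini-Hochberg
#' adjusted p-values are reported alongside; selection uses the raw p with
#' the fold-change rule of [abundance_select()]. A cluster with no control
#' cells gets `fc = Inf` (noted via `message()`) and is selected when its
#' p-value alone passes.
#'
#' @param cells data.frame with columns `cluster` and `condition`
#'   (two levels; `case`/`control` name them).
#' @param alpha,fc_hi,fc_lo selection thresholds.
#' @param case,control condition labels (defaults "T2DM" / "normal").
#' @return data.frame with one row per cluster: `cluster`, `n_t2dm`,
#'   `n_normal`, `fc`, `p`, `p_adj`, `selected`.
#' @export
abundance_test <- function(cells, alpha = 0.05, fc_hi = 4, fc_lo = 0.25,
                           case = "T2DM", control = "normal") {
  assert_cols(cells, c("cluster", "condition"), "cell table")
  if (!all(c(case, control) %in% cells$condition)) {
    stop_ps("both conditions must be present in the cell table")
  }
  clusters <- sort(unique(as.character(cells$cluster)))
  n_case <- sum(cells$condition == case)
  n_ctrl <- sum(cells$condition == control)
  res <- do.call(rbind, lapply(clusters, function(cl) {
    a <- sum(cells$cluster == cl & cells$condition == case)
    c_ <- sum(cells$cluster == cl & cells$condition == control)
    fc <- (a / n_case) / (c_ / n_ctrl)
    if (c_ == 0) message(sprintf(
      "abundance_test: cluster %s has no %s cells; fc = Inf", cl, control))
    data.frame(cluster = cl, n_t2dm = a, n_normal = c_, fc = fc,
               p = fisher_exact_2x2(a, n_case - a, c_, n_ctrl - c_),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- benjamini_hochberg(res$p)
  res$selected <- ifelse(is.infinite(res$fc), res$p < alpha,
                         abundance_select(res$fc, res$p, fc_hi, fc_lo, alpha))
  rownames(res) <- NULL
  res
}

#' Per-cluster marker gene detection
#'
#' For each cluster, tests every gene with a two-sided rank-sum test of the
#' cluster's cells against all other cells on normalized values. Reported
#' markers satisfy `log2fc >= min_log2fc` (with a 1e-9 pseudocount on the
#' group means), `max(pct_in, pct_out) >= min_pct` (fraction of cells with
#' value > 0) and `p < alpha`. Results are sorted by cluster then ascending
#' p-value. Clusters with fewer than two cells are skipped with a warning.
#'
#' @param expr normalized [expression_set()] or matrix (genes x cells) whose
#'   columns map 1:1 onto `cells$cell_id`.
#' @param cells data.frame with `cell_id` and `cluster`.
#' @param min_log2fc,min_pct,alpha marker thresholds (defaults 0.5, 0.35,
#'   0.05).
#' @return data.frame of markers: `cluster`, `gene`, `log2fc`, `pct_in`,
#'   `pct_out`, `p`, `p_adj` (BH within cluster).
#' @export
find_markers <- function(expr, cells, min_log2fc = 0.5, min_pct = 0.35,
                         alpha = 0.05) {
  values <- if (inherits(expr, "expr_set")) expr$values else expr
  assert_cols(cells, c("cell_id", "cluster"), "cell table")
  if (!setequal(colnames(values), cells$cell_id) ||
      ncol(values) != nrow(cells)) {
    stop_ps("expression columns must map 1:1 onto the cell table")
  }
  values <- values[, cells$cell_id, drop = FALSE]
  eps <- 1e-9
  out <- list()
  for (cl in sort(unique(as.character(cells$cluster)))) {
    in_cl <- cells$cluster == cl
    if (sum(in_cl) < 2L) {
      warning(sprintf("cluster %s has < 2 cells; skipped", cl), call. = FALSE)
      next
    }
    vin <- values[, in_cl, drop = FALSE]
    vout <- values[, !in_cl, drop = FALSE]
    mean_in <- rowMeans(vin)
    mean_out <- rowMeans(vout)
    log2fc <- log2((mean_in + eps) / (mean_out + eps))
    pct_in <- rowMeans(vin > 0)
    pct_out <- rowMeans(vout > 0)
    # only genes passing the cheap filters need a rank-sum p-value
    pass <- log2fc >= min_log2fc & pmax(pct_in, pct_out) >= min_pct
    if (!any(pass)) next
    p <- vapply(which(pass), function(i) {
      wilcoxon_rank_sum(vin[i, ], vout[i, ])
    }, numeric(1))
    keep <- p < alpha
    if (!any(keep)) next
    idx <- which(pass)[keep]
    df <- data.frame(cluster = cl, gene = rownames(values)[idx],
                     log2fc = log2fc[idx], pct_in = pct_in[idx],
                     pct_out = pct_out[idx], p = p[keep],
                     stringsAsFactors = FALSE)
    df$p_adj <- benjamini_hochberg(df$p)
    out[[cl]] <- df[order(df$p, df$gene), ]
  }
  if (!length(out)) {
    return(data.frame(cluster = character(), gene = character(),
                      log2fc = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p = numeric(), p_adj = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Top markers per cluster
#'
#' Slices the first `n` markers (by the [find_markers()] ordering: ascending
#' p within cluster) for each cluster.
#'
#' @param markers output of [find_markers()].
#' @param n markers to keep per cluster (default 5).
#' @return subset of `markers`.
#' @export
top_markers <- function(markers, n = 5L) {
  do.call(rbind, lapply(split(markers, markers$cluster), utils::head, n = n))
}
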