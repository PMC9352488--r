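#' Expression matrix with a two-level sample grouping
#'
#' Light container for a genes x samples expression matrix plus a two-level
#' condition factor per sample (e.g. T2DM vs normal). This is the substrate
#' for the diagnostics stage (AUC ranking, Wilcoxon testing, correlation
#' expansion) and for log-normalization of per-cell counts (where "samples"
#' are cells and `group` may be omitted).
#'
#' @param values numeric matrix, rows = genes, columns = samples; dimnames
#'   required and unique, no missing values.
#' @param group optional factor (or character) of length `ncol(values)` with
#'   exactly two levels, named by sample or in column order.
#' @return an object of class `expr_set`: a list with elements `values`
#'   (the matrix), `genes`, `samples`, and `group` (a named factor or NULL).
#' @export
expression_set <- function(values, group = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ps("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_ps("'values' must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop_ps("duplicate gene ids in 'values'")
  if (anyDuplicated(colnames(values))) stop_ps("duplicate sample ids in 'values'")
  if (anyNA(values)) stop_ps("'values' must not contain missing values")
  if (!is.null(group)) {
    if (!is.null(names(group))) {
      missing <- setdiff(colnames(values), names(group))
      if (length(missing)) {
        stop_ps("samples without a group label: ", paste(missing, collapse = ", "))
      }
      group <- group[colnames(values)]
    } else if (length(group) != ncol(values)) {
      stop_ps("'group' must have one entry per sample")
    }
    group <- factor(as.character(group))
    if (nlevels(group) != 2L) stop_ps("'group' must have exactly two levels")
    names(group) <- colnames(values)
  }
  structure(
    list(values = values, genes = rownames(values),
         samples = colnames(values), group = group),
    class = "expr_set"
  )
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

# group split helper: list(<level1> = matrix cols, <level2> = matrix cols)
split_by_group <- function(expr) {
  if (is.null(expr$group)) stop_ps("expression set has no group factor")
  lapply(split(expr$samples, expr$group), function(s) expr$values[, s, drop = FALSE])
}
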