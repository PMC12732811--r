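#' Labeled expression matrix
#'
#' Container for a genes x samples expression table with per-sample group
#' labels and a flag recording whether values are on the log2 scale. This is
#' the substrate of every bulk stage: differential expression, ranked-list
#' construction, cohort correlations and extreme-group selection.
#'
#' @param values Numeric matrix, genes in rows (unique uppercase symbols as
#'   rownames), samples in columns (unique sample ids as colnames). All values
#'   must be finite.
#' @param groups Character vector of group labels, one per sample, either in
#'   column order or named by sample id.
#' @param log2_scale Logical; `TRUE` if `values` are already log2-transformed.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `groups` (named by sample) and `log2`.
#' @export
expr_matrix <- function(values, groups, log2_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must have gene rownames and sample colnames")
  }
  if (any(!is.finite(values))) stopf("expression values must be finite")
  rownames(values) <- toupper(rownames(values))
  if (length(groups) != ncol(values)) {
    stopf("one group label per sample required (%d labels, %d samples)",
          length(groups), ncol(values))
  }
  groups <- as.character(groups)
  if (is.null(names(groups))) {
    names(groups) <- colnames(values)
  } else {
    if (!setequal(names(groups), colnames(values))) {
      stopf("group label names do not match sample ids")
    }
    groups <- groups[colnames(values)]
  }
  if (anyNA(groups)) stopf("every sample must have a group label")
  structure(list(values = values, groups = groups,
                 log2 = isTRUE(log2_scale)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), if (x$log2) "log2" else "raw"))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Collapse duplicate gene symbols
#'
#' When several rows share a gene symbol (e.g. multiple probes per gene) the
#' row with the highest variance across all samples is kept, mirroring common
#' best-probe collapse conventions.
#'
#' @param x An [expr_matrix].
#' @return An [expr_matrix] with unique gene symbols.
#' @export
collapse_duplicate_genes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  sym <- rownames(x$values)
  if (!anyDuplicated(sym)) return(x)
  v <- row_vars(x$values)
  keep <- unlist(lapply(split(seq_along(sym), sym), function(idx) {
    idx[which.max(v[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  expr_matrix(x$values[keep, , drop = FALSE], x$groups, x$log2)
}

#' Log-normalize a raw expression matrix
#'
#' Applies `log2(x + 1)` to a raw-scale matrix. A matrix already flagged as
#' log2 is returned unchanged, so the operation is idempotent.
#'
#' @param x An [expr_matrix].
#' @return An [expr_matrix] on the log2 scale.
#' @export
log_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$log2) return(x)
  if (any(x$values < 0)) stopf("raw expression values must be non-negative")
  expr_matrix(log2(x$values + 1), x$groups, log2_scale = TRUE)
}
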