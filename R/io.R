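# Plain-text readers and writers for every artifact the pipeline consumes or
# produces: expression TSV (+ group map), STRING-dialect edge TSV, survival
# TSV, MTX count bundles, DE / centrality / consensus tables and truth JSON.

#' Write / read an expression TSV
#'
#' First column `gene`, remaining columns sample ids. The group map is a
#' two-column TSV (`sample`, `group`).
#'
#' @param x An [expr_matrix].
#' @param path Output path for the expression table.
#' @param group_path Optional path for the group map.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, group_path = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(group_path)) {
    utils::write.table(
      data.frame(sample = names(x$groups), group = unname(x$groups)),
      group_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param group_map Path to a group-map TSV, or a named character vector;
#'   `NULL` labels every sample `"all"`.
#' @param log2_scale Whether the stored values are log2 (default TRUE).
#' @export
read_expression_tsv <- function(path, group_map = NULL, log2_scale = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  if (names(df)[1] != "gene") stopf("%s: first column must be 'gene'", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(apply(df[, -1, drop = FALSE], 1,
                       function(r) anyNA(suppressWarnings(as.numeric(r)))))
    stopf("%s: non-numeric expression values at data line(s) %s", path,
          paste(utils::head(bad, 5), collapse = ", "))
  }
  rownames(vals) <- df$gene
  if (is.null(group_map)) {
    group_map <- stats::setNames(rep("all", ncol(vals)), colnames(vals))
  }
  if (is.character(group_map) && length(group_map) == 1 &&
      file.exists(group_map)) {
    gm <- utils::read.table(group_map, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    group_map <- stats::setNames(gm$group, gm$sample)
  }
  expr_matrix(vals, group_map[colnames(vals)], log2_scale = log2_scale)
}

#' Write / read a STRING-dialect edge TSV
#'
#' Columns `node1`, `node2`, `combined_score`.
#'
#' @param edges Data frame of edges (e.g. from [as_edge_list]).
#' @param path File path.
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "")
}

#' Write / read a survival TSV (sample, time, event)
#'
#' @param survival_table Data frame with columns `sample`, `time`, `event`.
#' @param path File path.
#' @export
write_survival_tsv <- function(survival_table, path) {
  utils::write.table(survival_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_tsv
#' @export
read_survival_tsv <- function(path) {
  st <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "time", "event") %in% names(st))) {
    stopf("%s: survival TSV needs columns sample/time/event", path)
  }
  if (!all(st$event %in% c(0, 1))) stopf("%s: event must be 0/1", path)
  st
}

#' Write / read a single-cell MTX bundle
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and `metadata.tsv` into a
#' directory.
#'
#' @param x An [sc_dataset].
#' @param dir Directory (created if needed).
#' @export
write_mtx_bundle <- function(x, dir) {
  stopifnot(inherits(x, "sc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(rownames(x$counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(x$counts), file.path(dir, "barcodes.tsv"))
  utils::write.table(x$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_mtx_bundle
#' @export
read_mtx_bundle <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- utils::read.table(file.path(dir, "metadata.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  sc_dataset(counts, timepoint = meta$timepoint, state = meta$state)
}

#' Write ground truth (or any plain list) as JSON
#'
#' @param truth A list.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  truth <- unclass(truth)
  truth$params <- NULL
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a hub-discovery consensus table
#'
#' One row per candidate gene: membership count, consensus flag, direction,
#' and the per-network rank columns for all 12 metrics.
#'
#' @param hd A [run_hub_discovery] result.
#' @param path File path.
#' @export
write_consensus_tsv <- function(hd, path) {
  stopifnot(inherits(hd, "hub_discovery"))
  out <- summary(hd)
  for (dn in names(hd$centralities)) {
    ct <- hd$centralities[[dn]]
    for (mname in CENTRALITY_METRICS) {
      out[[paste(dn, "rank", mname, sep = ".")]] <-
        ct[[paste0("rank_", mname)]][match(out$gene, ct$node)]
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
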