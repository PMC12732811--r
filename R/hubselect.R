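# Consensus hub calling: per-network top-fraction candidates across the 12
# centrality metrics, cross-network membership counting, and direction
# labelling from the per-dataset differential expression results.

#' Top-fraction hub candidates from a centrality table
#'
#' Per metric, `k = ceiling(fraction * n_nodes)` nodes are taken by
#' descending score, plus any node tied with the k-th score; the returned
#' candidate set is the union over all twelve metrics ("top 15% by at least
#' one metric").
#'
#' @param table A [compute_all_centralities] result.
#' @param fraction Top fraction per metric, in (0, 1].
#' @return Sorted character vector of candidate genes.
#' @export
top_fraction_candidates <- function(table, fraction = 0.15) {
  stopifnot(inherits(table, "centrality_table"))
  check_number(fraction, "fraction", lower = 0, upper = 1, open_lower = TRUE)
  n <- nrow(table)
  if (n == 0) stopf("empty centrality table")
  k <- ceiling(fraction * n)
  cand <- character(0)
  for (mname in CENTRALITY_METRICS) {
    sc <- table[[mname]]
    kth <- sort(sc, decreasing = TRUE)[k]
    cand <- c(cand, table$node[sc >= kth])
  }
  sort(unique(cand))
}

#' Cross-network consensus of hub candidates
#'
#' Counts each gene's membership across the per-network candidate sets;
#' consensus genes appear in at least `min_networks` sets.
#'
#' @param candidate_sets List (one candidate gene set per network).
#' @param min_networks Minimum membership count (default 3, as in a
#'   3-of-4-network consensus).
#' @return An object of class `hub_consensus` with elements
#'   `candidates` (the input sets), `counts` (named membership counts),
#'   `consensus` (genes with count >= `min_networks`) and `min_networks`.
#' @export
consensus_hubs <- function(candidate_sets, min_networks = 3) {
  if (!is.list(candidate_sets) || length(candidate_sets) < 1) {
    stopf("candidate_sets must be a non-empty list")
  }
  min_networks <- check_count(min_networks, "min_networks")
  if (min_networks > length(candidate_sets)) {
    stopf("min_networks (%d) exceeds the number of candidate sets (%d)",
          min_networks, length(candidate_sets))
  }
  sets <- lapply(candidate_sets, function(s) unique(as.character(s)))
  tab <- table(unlist(sets))
  counts <- stats::setNames(as.integer(tab), names(tab))
  if (length(counts)) counts <- counts[order(-counts, names(counts))]
  structure(list(candidates = sets, counts = counts,
                 consensus = sort(names(counts)[counts >= min_networks]),
                 min_networks = min_networks),
            class = "hub_consensus")
}

#' @export
print.hub_consensus <- function(x, ...) {
  cat(sprintf("<hub_consensus> %d candidate sets, %d consensus genes (>= %d networks)\n",
              length(x$candidates), length(x$consensus), x$min_networks))
  if (length(x$consensus)) {
    cat(strwrap(paste(x$consensus, collapse = ", "), width = 70), sep = "\n")
  }
  invisible(x)
}

#' Direction labels for consensus genes
#'
#' Collects each gene's significant signed calls (per [select_degs]) across
#' the datasets: all positive gives `"up"`, all negative `"down"`, mixed
#' signs `"variable"`. Genes with no significant call in any dataset are
#' labelled `"variable"` and flagged rather than dropped.
#'
#' @param genes Character vector of consensus genes.
#' @param de_results List of [differential_expression] results (one per
#'   dataset).
#' @param thresholds A [de_thresholds] object for significance.
#' @return Data frame with columns `gene`, `direction`, `n_significant`,
#'   `no_significant_call`.
#' @export
annotate_direction <- function(genes, de_results, thresholds = de_thresholds()) {
  stopifnot(is.list(de_results), length(de_results) >= 1)
  missing <- genes[!vapply(genes, function(g) {
    any(vapply(de_results, function(d) g %in% d$gene, logical(1)))
  }, logical(1))]
  if (length(missing)) {
    stopf("genes absent from every DE result: %s",
          paste(missing, collapse = ", "))
  }
  rows <- lapply(genes, function(g) {
    signs <- unlist(lapply(de_results, function(d) {
      i <- match(g, d$gene)
      if (is.na(i)) return(NULL)
      if (abs(d$log2FC[i]) >= thresholds$min_abs_lfc &&
          d$q[i] < thresholds$max_q) sign(d$log2FC[i]) else NULL
    }))
    ns <- length(signs)
    dir <- if (ns == 0) "variable"
    else if (all(signs > 0)) "up"
    else if (all(signs < 0)) "down"
    else "variable"
    data.frame(gene = g, direction = dir, n_significant = ns,
               no_significant_call = ns == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Configuration for hub discovery
#'
#' @param de_thresholds A [de_thresholds] object (discovery defaults 1.5 /
#'   0.05).
#' @param confidence_cutoff Edge-confidence cutoff (strict `>`).
#' @param fraction Top fraction per centrality metric.
#' @param min_networks Consensus membership threshold.
#' @param group_a,group_b Group labels compared in every dataset.
#' @param moderated Use moderated t statistics.
#' @param centrality_options A [centrality_options] object.
#' @return A list of class `hub_discovery_config`.
#' @export
hub_discovery_config <- function(de_thresholds = emtnet::de_thresholds(),
                                 confidence_cutoff = 0.7, fraction = 0.15,
                                 min_networks = 3, group_a = "treated",
                                 group_b = "control", moderated = TRUE,
                                 centrality_options = emtnet::centrality_options()) {
  structure(list(de_thresholds = de_thresholds,
                 confidence_cutoff = check_number(confidence_cutoff,
                                                  "confidence_cutoff",
                                                  lower = 0, upper = 1,
                                                  open_upper = TRUE),
                 fraction = check_number(fraction, "fraction", lower = 0,
                                         upper = 1, open_lower = TRUE),
                 min_networks = check_count(min_networks, "min_networks"),
                 group_a = group_a, group_b = group_b, moderated = moderated,
                 centrality_options = centrality_options),
            class = "hub_discovery_config")
}

#' Run the full consensus hub-discovery procedure
#'
#' For each dataset: differential expression, DEG selection, construction of
#' the DEG-restricted confidence-filtered network, the twelve centrality
#' metrics, and top-fraction candidate calling; then cross-network consensus
#' and direction labelling. Per-stage record counts are kept as provenance.
#'
#' @param datasets Named list (>= 2) of [expr_matrix] objects.
#' @param edges A single edge data.frame shared by all datasets, or a list of
#'   edge data.frames (one per dataset).
#' @param config A [hub_discovery_config] object.
#' @return An object of class `hub_discovery`: `consensus` (a
#'   [consensus_hubs] object), `directions`, `candidates`, `centralities`
#'   (per-network tables), `de` (per-dataset results) and `report`.
#' @export
run_hub_discovery <- function(datasets, edges,
                              config = hub_discovery_config()) {
  if (!is.list(datasets) || length(datasets) < 2) {
    stopf("at least 2 datasets required")
  }
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  if (is.data.frame(edges)) {
    edges <- rep(list(edges), length(datasets))
  }
  if (length(edges) != length(datasets)) {
    stopf("need one edge table, or one per dataset")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  de <- list(); degs <- list(); cents <- list(); cands <- list()
  report <- list()
  for (i in seq_along(datasets)) {
    dn <- names(datasets)[i]
    de[[dn]] <- stage(paste0("de:", dn), differential_expression(
      datasets[[i]], config$group_a, config$group_b,
      moderated = config$moderated))
    degs[[dn]] <- stage(paste0("degs:", dn),
                        select_degs(de[[dn]], config$de_thresholds))
    if (nrow(degs[[dn]]) == 0) {
      warnf("dataset '%s' has zero DEGs; its network is empty", dn)
    }
    net <- stage(paste0("network:", dn), build_network(
      edges[[i]], cutoff = config$confidence_cutoff,
      node_universe = degs[[dn]]$gene))
    cents[[dn]] <- stage(paste0("centrality:", dn),
                         compute_all_centralities(net, config$centrality_options))
    cands[[dn]] <- if (nrow(cents[[dn]]) == 0) character(0) else
      stage(paste0("candidates:", dn),
            top_fraction_candidates(cents[[dn]], config$fraction))
    report[[dn]] <- list(n_genes = nrow(datasets[[i]]$values),
                         n_degs = nrow(degs[[dn]]),
                         n_nodes = nrow(cents[[dn]]),
                         n_edges = igraph::ecount(net),
                         n_candidates = length(cands[[dn]]))
  }
  cons <- stage("consensus", consensus_hubs(cands, config$min_networks))
  dirs <- if (length(cons$consensus)) {
    stage("direction", annotate_direction(cons$consensus, de,
                                          config$de_thresholds))
  } else {
    data.frame(gene = character(0), direction = character(0),
               n_significant = integer(0), no_significant_call = logical(0))
  }
  if (length(cons$consensus) == 0) warnf("consensus hub set is empty")
  structure(list(consensus = cons, directions = dirs, candidates = cands,
                 centralities = cents, de = de, degs = degs,
                 report = report, config = config),
            class = "hub_discovery")
}

#' @export
print.hub_discovery <- function(x, ...) {
  cat(sprintf("<hub_discovery> %d datasets\n", length(x$candidates)))
  for (dn in names(x$report)) {
    r <- x$report[[dn]]
    cat(sprintf("  %s: %d genes -> %d DEGs -> %d nodes / %d edges -> %d candidates\n",
                dn, r$n_genes, r$n_degs, r$n_nodes, r$n_edges, r$n_candidates))
  }
  print(x$consensus)
  if (nrow(x$directions)) print(table(x$directions$direction))
  invisible(x)
}

#' @export
summary.hub_discovery <- function(object, ...) {
  out <- merge(
    data.frame(gene = names(object$consensus$counts),
               networks = unname(object$consensus$counts)),
    object$directions, by = "gene", all.x = TRUE)
  out$consensus <- out$networks >= object$consensus$min_networks
  out[order(-out$networks, out$gene), ]
}
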