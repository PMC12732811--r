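# Interaction-network construction and the twelve node-centrality metrics
# used for hub calling: Degree, MCC, DMNC, MNC, EPC, BottleNeck,
# EcCentricity, Closeness, Radiality, Betweenness, Stress and the local
# clustering coefficient. All metrics are computed on the simple unweighted
# graph; confidence scores act only as an edge filter. Networks are never
# reduced to a largest component: every metric has a per-component (or
# isolated-node) convention so fragmented DEG networks stay fully scoreable.

CENTRALITY_METRICS <- c("Degree", "MCC", "DMNC", "MNC", "EPC", "BottleNeck",
                        "EcCentricity", "Closeness", "Radiality",
                        "Betweenness", "Stress", "ClusteringCoefficient")

as_interaction_network <- function(g) {
  class(g) <- unique(c("interaction_network", class(g)))
  g
}

#' Options for centrality computation
#'
#' @param dmnc_epsilon Exponent of the DMNC denominator (default 1.7).
#' @param epc_replicates Monte-Carlo replicates for edge-percolation
#'   centrality.
#' @param epc_retention Edge retention probability per replicate.
#' @param epc_seed Seed for the percolation replicates.
#' @param bottleneck_fraction Subtree-size fraction above which a node counts
#'   as a bottleneck in a rooted shortest-path tree (default 1/4).
#' @param clique_budget Abort maximal-clique enumeration above this count.
#' @return An object of class `centrality_options`.
#' @export
centrality_options <- function(dmnc_epsilon = 1.7, epc_replicates = 1000,
                               epc_retention = 0.5, epc_seed = 1,
                               bottleneck_fraction = 0.25,
                               clique_budget = 1e6) {
  structure(list(
    dmnc_epsilon = check_number(dmnc_epsilon, "dmnc_epsilon",
                                lower = 0, open_lower = TRUE),
    epc_replicates = check_count(epc_replicates, "epc_replicates"),
    epc_retention = check_number(epc_retention, "epc_retention",
                                 lower = 0, upper = 1, open_lower = TRUE),
    epc_seed = check_count(epc_seed, "epc_seed", min = 0),
    bottleneck_fraction = check_number(bottleneck_fraction,
                                       "bottleneck_fraction", lower = 0,
                                       upper = 1, open_lower = TRUE,
                                       open_upper = TRUE),
    clique_budget = check_number(clique_budget, "clique_budget", lower = 1)
  ), class = "centrality_options")
}

#' Build a confidence-filtered interaction network
#'
#' Retains edges whose confidence is strictly greater than `cutoff`. Scores on
#' the STRING 0-1000 integer scale are auto-detected (any score > 1) and
#' divided by 1000. If a node universe (e.g. a DEG list) is supplied, both
#' endpoints must be members ("no additional interactions") and the network's
#' node set is the universe itself, so genes without retained interactions
#' appear as zero-degree vertices. Self loops are dropped and parallel edges
#' collapsed to their maximum confidence.
#'
#' @param edges Data frame with columns `node1`/`node2`/`score` (aliases
#'   `protein1`/`protein2`/`combined_score` accepted).
#' @param cutoff Confidence cutoff on the 0-1 scale (strict `>`).
#' @param node_universe Optional character vector restricting the node set.
#' @param score_scale `"auto"`, `"unit"` (scores already in (0,1]) or
#'   `"string"` (0-1000).
#' @return An `interaction_network` (an igraph graph with a `confidence` edge
#'   attribute).
#' @export
build_network <- function(edges, cutoff = 0.7, node_universe = NULL,
                          score_scale = c("auto", "unit", "string")) {
  score_scale <- match.arg(score_scale)
  edges <- as.data.frame(edges)
  nm <- tolower(names(edges))
  col <- function(alts) {
    i <- which(nm %in% alts)[1]
    if (is.na(i)) stopf("edge table must have columns node1/node2/score (or protein1/protein2/combined_score)")
    edges[[i]]
  }
  n1 <- toupper(as.character(col(c("node1", "protein1", "from"))))
  n2 <- toupper(as.character(col(c("node2", "protein2", "to"))))
  sc <- suppressWarnings(as.numeric(col(c("score", "combined_score", "confidence"))))
  bad <- which(is.na(n1) | is.na(n2) | n1 == "" | n2 == "" | is.na(sc))
  if (length(bad)) {
    stopf("malformed edge rows at lines: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  if (score_scale == "string" || (score_scale == "auto" && any(sc > 1))) {
    sc <- sc / 1000
  }
  all_nodes <- unique(c(n1, n2))
  keep <- sc > cutoff
  if (!is.null(node_universe)) {
    node_universe <- unique(toupper(as.character(node_universe)))
    keep <- keep & n1 %in% node_universe & n2 %in% node_universe
    nodes <- node_universe
  } else {
    nodes <- all_nodes
  }
  n1 <- n1[keep]; n2 <- n2[keep]; sc <- sc[keep]
  loop <- n1 == n2
  n1 <- n1[!loop]; n2 <- n2[!loop]; sc <- sc[!loop]
  if (length(n1) == 0) warnf("no edges pass the confidence cutoff")
  g <- igraph::graph_from_data_frame(
    data.frame(from = n1, to = n2, confidence = sc),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  g <- igraph::simplify(g, edge.attr.comb = list(confidence = "max"))
  as_interaction_network(g)
}

# Brandes-style single pass computing both betweenness and stress on the
# unweighted simple graph; sums are over unordered pairs excluding the node.
brandes_betweenness_stress <- function(g) {
  n <- igraph::vcount(g)
  betw <- numeric(n); strs <- numeric(n)
  if (n == 0) return(list(betweenness = betw, stress = strs))
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_v <- integer(0)
    queue <- c(s); qi <- 1
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1
      order_v <- c(order_v, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)  # betweenness dependency
    gcnt <- numeric(n)   # shortest-path DAG descendants-with-multiplicity
    for (w in rev(order_v)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        gcnt[v] <- gcnt[v] + (1 + gcnt[w])
      }
    }
    nz <- order_v[order_v != s]
    betw[nz] <- betw[nz] + delta[nz]
    strs[nz] <- strs[nz] + sigma[nz] * gcnt[nz]
  }
  list(betweenness = betw / 2, stress = strs / 2)
}

#' Shortest-path centralities
#'
#' Closeness (sum of reciprocal geodesic distances, with 1/Inf = 0),
#' Betweenness and Stress (over unordered pairs), EcCentricity (reciprocal
#' eccentricity; 0 for an isolated node) and Radiality (per-component, using
#' the component's diameter; 0 for a singleton component), all on the
#' unweighted graph.
#'
#' @param network An `interaction_network` or igraph graph.
#' @return A data.frame with columns `node`, `Closeness`, `Betweenness`,
#'   `Stress`, `EcCentricity`, `Radiality`.
#' @export
shortest_path_metrics <- function(network) {
  g <- network
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) {
    return(data.frame(node = character(0), Closeness = numeric(0),
                      Betweenness = numeric(0), Stress = numeric(0),
                      EcCentricity = numeric(0), Radiality = numeric(0)))
  }
  D <- igraph::distances(g, algorithm = "unweighted")
  R <- 1 / D
  diag(R) <- 0
  R[is.infinite(D)] <- 0
  closeness <- rowSums(R)
  ecc <- apply(D, 1, function(row) {
    fin <- row[is.finite(row) & row > 0]
    if (length(fin) == 0) 0 else 1 / max(fin)
  })
  comp <- igraph::components(g)
  radial <- numeric(n)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    if (nc < 2) next
    Dc <- D[idx, idx, drop = FALSE]
    delta <- max(Dc)
    radial[idx] <- (rowSums(delta + 1 - Dc) - (delta + 1)) / (nc - 1)
  }
  bs <- brandes_betweenness_stress(g)
  data.frame(node = nodes, Closeness = unname(closeness),
             Betweenness = bs$betweenness, Stress = bs$stress,
             EcCentricity = unname(ecc), Radiality = radial,
             stringsAsFactors = FALSE)
}

#' Neighborhood centralities
#'
#' Degree; MNC (order of the largest connected component of the open
#' neighborhood); DMNC (edges of that component divided by its order to the
#' power `dmnc_epsilon`; 0 when it has fewer than 2 nodes); local clustering
#' coefficient (0 for degree < 2).
#'
#' @param network An `interaction_network` or igraph graph.
#' @param options A [centrality_options] object.
#' @return A data.frame with columns `node`, `Degree`, `MNC`, `DMNC`,
#'   `ClusteringCoefficient`.
#' @export
neighborhood_metrics <- function(network, options = centrality_options()) {
  g <- network
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  deg <- if (n) unname(igraph::degree(g)) else numeric(0)
  mnc <- numeric(n); dmnc <- numeric(n); cc <- numeric(n)
  if (n > 0) {
    adj <- igraph::as_adj_list(g)
    for (v in seq_len(n)) {
      nb <- as.integer(adj[[v]])
      if (length(nb) == 0) next
      sub <- igraph::induced_subgraph(g, nb)
      cm <- igraph::components(sub)
      big <- which.max(cm$csize)
      size <- cm$csize[big]
      mnc[v] <- size
      if (size >= 2) {
        comp_sub <- igraph::induced_subgraph(sub, which(cm$membership == big))
        dmnc[v] <- igraph::ecount(comp_sub) / size^options$dmnc_epsilon
      }
      k <- length(nb)
      if (k >= 2) cc[v] <- 2 * igraph::ecount(sub) / (k * (k - 1))
    }
  }
  data.frame(node = nodes, Degree = deg, MNC = mnc, DMNC = dmnc,
             ClusteringCoefficient = cc, stringsAsFactors = FALSE)
}

#' Maximal clique centrality (MCC)
#'
#' For each node, the sum over the maximal cliques containing it of
#' `(clique size - 1)!`. Maximal cliques are enumerated exactly
#' (Bron-Kerbosch with pivoting); a degree-0 node scores 0.
#'
#' @param network An `interaction_network` or igraph graph.
#' @param clique_budget Abort with an error if the graph has more maximal
#'   cliques than this.
#' @return Named numeric vector of MCC scores.
#' @export
mcc <- function(network, clique_budget = 1e6) {
  g <- network
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  out <- stats::setNames(numeric(n), nodes)
  if (n == 0 || igraph::ecount(g) == 0) return(out)
  n_cl <- igraph::count_max_cliques(g, min = 2)
  if (n_cl > clique_budget) {
    stopf("graph has %s maximal cliques, above the budget of %s; raise clique_budget to proceed",
          format(n_cl), format(clique_budget))
  }
  cliques <- igraph::max_cliques(g, min = 2)
  for (cl in cliques) {
    idx <- as.integer(cl)
    out[idx] <- out[idx] + factorial(length(idx) - 1)
  }
  out
}

#' Edge-percolation centrality (EPC)
#'
#' Monte-Carlo estimate of the expected number of nodes co-connected with
#' each node when every edge is retained independently with probability
#' `epc_retention` (a node always counts itself, so an isolated node scores
#' 1). Deterministic under a fixed `epc_seed`.
#'
#' @param network An `interaction_network` or igraph graph.
#' @param options A [centrality_options] object.
#' @return Named numeric vector of EPC scores.
#' @export
epc <- function(network, options = centrality_options()) {
  g <- network
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) return(stats::setNames(numeric(0), nodes))
  m <- igraph::ecount(g)
  K <- options$epc_replicates
  acc <- numeric(n)
  with_seed(options$epc_seed, {
    for (k in seq_len(K)) {
      keep <- which(stats::runif(m) < options$epc_retention)
      sg <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
      cs <- igraph::components(sg)
      acc <- acc + cs$csize[cs$membership]
    }
  })
  stats::setNames(acc / K, nodes)
}

#' BottleNeck centrality
#'
#' For every root in a node's connected component, a breadth-first
#' shortest-path tree is built with deterministic parent tie-breaking
#' (lexicographically smallest parent name). A node scores one point per root
#' whose tree gives it a subtree (itself included) larger than
#' `bottleneck_fraction` times the tree size; the root itself never scores.
#'
#' @param network An `interaction_network` or igraph graph.
#' @param options A [centrality_options] object.
#' @return Named numeric vector of BottleNeck scores.
#' @export
bottleneck <- function(network, options = centrality_options()) {
  g <- network
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  out <- stats::setNames(numeric(n), nodes)
  if (n == 0) return(out)
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  comp <- igraph::components(g)
  name_rank <- rank(nodes, ties.method = "first")
  for (s in seq_len(n)) {
    idx <- which(comp$membership == comp$membership[s])
    n_tree <- length(idx)
    if (n_tree < 2) next
    # BFS distances from s restricted to the component
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- c(s); qi <- 1
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1
      for (w in adj[[v]]) {
        if (dist[w] < 0) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    parent <- rep(NA_integer_, n)
    for (v in idx) {
      if (v == s) next
      cand <- adj[[v]][dist[adj[[v]]] == dist[v] - 1L]
      parent[v] <- cand[which.min(name_rank[cand])]
    }
    size <- rep(1, n)
    for (v in idx[order(dist[idx], decreasing = TRUE)]) {
      if (v == s) next
      size[parent[v]] <- size[parent[v]] + size[v]
    }
    qual <- idx[idx != s & size[idx] > options$bottleneck_fraction * n_tree]
    out[qual] <- out[qual] + 1
  }
  out
}

#' Compute all twelve centrality metrics
#'
#' Assembles Degree, MCC, DMNC, MNC, EPC, BottleNeck, EcCentricity,
#' Closeness, Radiality, Betweenness, Stress and ClusteringCoefficient into
#' one table, with a descending rank per metric (ties share the minimum
#' rank).
#'
#' @param network An `interaction_network` or igraph graph.
#' @param options A [centrality_options] object.
#' @return A data.frame of class `centrality_table`: one row per node, the 12
#'   scores, and `rank_<metric>` columns.
#' @export
compute_all_centralities <- function(network, options = centrality_options()) {
  g <- network
  nbm <- neighborhood_metrics(g, options)
  spm <- shortest_path_metrics(g)
  tab <- data.frame(
    node = nbm$node,
    Degree = nbm$Degree,
    MCC = unname(mcc(g, options$clique_budget)),
    DMNC = nbm$DMNC,
    MNC = nbm$MNC,
    EPC = unname(epc(g, options)),
    BottleNeck = unname(bottleneck(g, options)),
    EcCentricity = spm$EcCentricity,
    Closeness = spm$Closeness,
    Radiality = spm$Radiality,
    Betweenness = spm$Betweenness,
    Stress = spm$Stress,
    ClusteringCoefficient = nbm$ClusteringCoefficient,
    stringsAsFactors = FALSE
  )
  for (mname in CENTRALITY_METRICS) {
    tab[[paste0("rank_", mname)]] <- if (nrow(tab)) rank_desc(tab[[mname]]) else integer(0)
  }
  structure(tab, class = c("centrality_table", "data.frame"))
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("<centrality_table> %d nodes x 12 metrics\n", nrow(x)))
  print.data.frame(utils::head(x[order(x$rank_Degree),
                                 c("node", CENTRALITY_METRICS)], 6),
                   digits = 4)
  invisible(x)
}

#' Edge list of an interaction network
#'
#' @param network An `interaction_network`.
#' @return Data frame with columns `node1`, `node2`, `combined_score`
#'   (confidence on the 0-1 scale).
#' @export
as_edge_list <- function(network) {
  el <- igraph::as_edgelist(network)
  data.frame(node1 = el[, 1], node2 = el[, 2],
             combined_score = igraph::E(network)$confidence,
             stringsAsFactors = FALSE)
}
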