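# Network construction and the twelve centrality metrics.

named_graph <- function(...) {
  g <- igraph::make_graph(c(...), directed = FALSE)
  igraph::E(g)$confidence <- rep(1, igraph::ecount(g))
  g
}

test_that("build_network filters strictly, rescales STRING scores and keeps the universe", {
  edges <- data.frame(node1 = c("A", "B", "C", "D", "E"),
                      node2 = c("B", "C", "D", "E", "A"),
                      combined_score = c(700, 701, 900, 200, 950))
  net <- build_network(edges, cutoff = 0.7)
  # score 700 on the 0-1000 scale is exactly 0.7 and is excluded (strict >)
  el <- as_edge_list(net)
  expect_false(any(el$node1 == "A" & el$node2 == "B"))
  expect_equal(igraph::ecount(net), 3)
  expect_true(all(igraph::E(net)$confidence > 0.7))
  # universe restriction drops edges with an outside endpoint but keeps
  # universe genes as isolated vertices
  net2 <- build_network(edges, cutoff = 0.7, node_universe = c("B", "C", "Z"))
  expect_setequal(igraph::V(net2)$name, c("B", "C", "Z"))
  expect_equal(igraph::ecount(net2), 1)
  expect_equal(unname(igraph::degree(net2)["Z"]), 0)
  # unit-scale scores pass through; all retained above the cutoff
  edges3 <- data.frame(node1 = "A", node2 = "B", score = 0.9)
  expect_equal(igraph::ecount(build_network(edges3, 0.7)), 1)
  expect_warning(build_network(edges3, 0.95), "no edges")
})

test_that("build_network reports malformed rows and collapses duplicates", {
  edges <- data.frame(node1 = c("A", NA, "C"), node2 = c("B", "C", "D"),
                      score = c(0.9, 0.8, NA))
  expect_error(build_network(edges), "lines: 2, 3")
  dup <- data.frame(node1 = c("A", "B", "A"), node2 = c("B", "A", "A"),
                    score = c(0.8, 0.9, 0.99))
  net <- build_network(dup, cutoff = 0.5)
  expect_equal(igraph::ecount(net), 1) # parallel collapsed, self loop dropped
  expect_equal(igraph::E(net)$confidence, 0.9)
})

test_that("path metrics match hand-derived values on the named fixtures", {
  p3 <- named_graph("a", "b", "b", "c")
  spm <- shortest_path_metrics(p3)
  expect_equal(spm$Betweenness[spm$node == "b"], 1)
  expect_equal(spm$Stress[spm$node == "b"], 1)
  expect_equal(spm$Closeness[spm$node == "b"], 2)
  expect_equal(spm$Closeness[spm$node == "a"], 1.5)
  expect_equal(spm$EcCentricity[spm$node == "a"], 0.5)
  expect_equal(spm$Radiality[spm$node == "a"], 1.5)
  expect_equal(spm$Radiality[spm$node == "b"], 2)

  tri <- named_graph("a", "b", "b", "c", "a", "c")
  expect_equal(shortest_path_metrics(tri)$Betweenness, rep(0, 3))
  expect_equal(unname(mcc(tri)), rep(2, 3))

  c4 <- named_graph("a", "b", "b", "c", "c", "d", "d", "a")
  expect_equal(unname(mcc(c4)), rep(2, 4))
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(unname(mcc(k5)), rep(24, 5))
})

test_that("neighborhood metrics match hand-derived values", {
  star <- named_graph("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  nbm <- neighborhood_metrics(star)
  ctr <- nbm[nbm$node == "c", ]
  expect_equal(ctr$Degree, 4)
  expect_equal(ctr$MNC, 1)
  expect_equal(ctr$DMNC, 0)
  expect_equal(ctr$ClusteringCoefficient, 0)

  g <- named_graph("v", "a", "v", "b", "v", "c", "a", "b", "b", "c")
  vm <- neighborhood_metrics(g)
  expect_equal(vm$MNC[vm$node == "v"], 3)
  expect_equal(vm$DMNC[vm$node == "v"], 2 / 3^1.7, tolerance = 1e-12)
  tri <- named_graph("a", "b", "b", "c", "a", "c")
  expect_equal(neighborhood_metrics(tri)$ClusteringCoefficient, rep(1, 3))
})

test_that("BottleNeck follows the rooted-tree subtree rule", {
  star <- named_graph("c", "l1", "c", "l2", "c", "l3", "c", "l4")
  bn <- bottleneck(star)
  expect_equal(unname(bn["c"]), 4)
  expect_equal(unname(bn[c("l1", "l2", "l3", "l4")]), rep(0, 4))
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(bottleneck(k4)), rep(0, 4))
  two <- named_graph("a", "b")
  expect_equal(unname(bottleneck(two)), c(1, 1))
})

test_that("EPC is exact at retention 1, unbiased on a single edge, and seeded", {
  g <- igraph::make_ring(6)
  igraph::V(g)$name <- letters[1:6]
  expect_equal(unname(epc(g, centrality_options(epc_retention = 1,
                                                epc_replicates = 3))),
               rep(6, 6))
  two <- named_graph("a", "b")
  e <- epc(two, centrality_options(epc_retention = 0.5,
                                   epc_replicates = 1000, epc_seed = 5))
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(e[["a"]] - 1.5), 3 * se)
  e2 <- epc(two, centrality_options(epc_retention = 0.5,
                                    epc_replicates = 1000, epc_seed = 5))
  expect_identical(e, e2)
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b")
  expect_equal(unname(epc(iso, centrality_options(epc_replicates = 10))),
               c(1, 1))
})

test_that("deterministic metrics equal the brute-force oracle on random small graphs", {
  set.seed(42)
  for (rep in 1:60) {
    A <- random_small_graph()
    g <- graph_from_adj(A)
    oracle <- brute_centralities(A)
    tab <- compute_all_centralities(g, centrality_options(epc_replicates = 2))
    tab <- tab[match(oracle$node, tab$node), ]
    det_metrics <- c("Degree", "MCC", "DMNC", "MNC", "BottleNeck",
                     "EcCentricity", "Closeness", "Radiality", "Betweenness",
                     "Stress", "ClusteringCoefficient")
    for (m in det_metrics) {
      expect_equal(tab[[m]], oracle[[m]], tolerance = 1e-10,
                   info = paste("metric", m, "rep", rep))
    }
  }
})

test_that("betweenness agrees with the igraph reference implementation", {
  set.seed(7)
  for (rep in 1:20) {
    A <- random_small_graph(n_max = 12)
    g <- graph_from_adj(A)
    spm <- shortest_path_metrics(g)
    expect_equal(spm$Betweenness, unname(igraph::betweenness(g)),
                 tolerance = 1e-10)
    cc <- neighborhood_metrics(g)$ClusteringCoefficient
    ref <- igraph::transitivity(g, type = "local", isolates = "zero")
    ref[is.nan(ref)] <- 0
    expect_equal(cc, unname(ref), tolerance = 1e-10)
  }
})

test_that("scores are isomorphism invariant and monotone under edge addition", {
  set.seed(11)
  A <- random_small_graph(7, p = 0.5)
  g <- graph_from_adj(A)
  perm <- sample(nrow(A))
  B <- A[perm, perm]
  t1 <- compute_all_centralities(g, centrality_options(epc_replicates = 2))
  t2 <- compute_all_centralities(graph_from_adj(B),
                                 centrality_options(epc_replicates = 2))
  t2 <- t2[match(t1$node, t2$node), ]
  for (m in c("Degree", "MCC", "DMNC", "MNC", "BottleNeck", "EcCentricity",
              "Closeness", "Radiality", "Betweenness", "Stress",
              "ClusteringCoefficient")) {
    expect_equal(t1[[m]], t2[[m]], tolerance = 1e-10, info = m)
  }
  # adding an edge never decreases Degree or MNC of its endpoints
  miss <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
  if (nrow(miss)) {
    ij <- miss[1, ]
    A2 <- A; A2[ij[1], ij[2]] <- A2[ij[2], ij[1]] <- 1L
    n1 <- neighborhood_metrics(graph_from_adj(A))
    n2 <- neighborhood_metrics(graph_from_adj(A2))
    expect_true(all(n2$Degree[ij] >= n1$Degree[ij]))
    expect_true(all(n2$MNC[ij] >= n1$MNC[ij]))
  }
})

test_that("degenerate graphs follow the stated conventions", {
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(compute_all_centralities(empty)), 0)
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "a"
  tab <- compute_all_centralities(one, centrality_options(epc_replicates = 5))
  expect_equal(tab$EPC, 1) # a node is always co-connected with itself
  for (m in c("Degree", "MCC", "DMNC", "MNC", "BottleNeck", "EcCentricity",
              "Closeness", "Radiality", "Betweenness", "Stress",
              "ClusteringCoefficient")) {
    expect_equal(tab[[m]], 0, info = m)
  }
})
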