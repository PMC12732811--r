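# Synthetic-data generators: determinism, planted effect sizes, truth
# bookkeeping and error contracts.

test_that("bulk generator is deterministic and plants the stated effect", {
  p <- bulk_sim_params(n_genes = 1000, n_de = 100, lfc_magnitude = 2,
                       noise_sd = 0.5, seed = 7)
  a <- make_bulk_expression(p)
  b <- make_bulk_expression(p)
  expect_identical(a, b)
  x <- a$expression
  expect_s3_class(x, "expr_matrix")
  expect_true(x$log2)
  # empirical |lfc| over planted DEGs within 3 standard errors of 2.0
  trt <- x$values[, x$groups == "treated"]
  ctl <- x$values[, x$groups == "control"]
  emp <- rowMeans(trt) - rowMeans(ctl)
  de <- a$truth$de_genes
  mean_abs <- mean(abs(emp[de$gene]))
  se <- 0.5 * sqrt(2 / 5) / sqrt(nrow(de)) # noise_sd, n_per_group, n_de
  expect_lt(abs(mean_abs - 2), 3 * se)
  # non-DE genes centred at zero
  expect_lt(abs(mean(emp[setdiff(rownames(x$values), de$gene)])), 3 * se)
  # marker panel planted with stated signs
  panel <- emt_marker_panel()
  expect_true(all(panel$gene %in% de$gene))
  got <- de$sign[match(panel$gene, de$gene)]
  expect_equal(got, ifelse(panel$direction == "up", 1, -1))
})

test_that("bulk generator null case and validation", {
  p0 <- bulk_sim_params(n_genes = 200, n_de = 0, seed = 3)
  out <- make_bulk_expression(p0)
  expect_equal(nrow(out$truth$de_genes), 0)
  expect_error(bulk_sim_params(n_genes = 10, n_de = 50), "n_de")
  expect_error(bulk_sim_params(n_genes = 0), "n_genes")
  expect_error(bulk_sim_params(noise_sd = 0), "noise_sd")
  expect_error(bulk_sim_params(n_de = 5), "marker panel")
})

test_that("network generator plants recoverable hubs with dense modules", {
  p <- network_sim_params(n_nodes = 300, n_hubs = 5, hub_module_size = 15,
                          background_attachment = 2, seed = 21)
  a <- make_network(p)
  b <- make_network(p)
  expect_identical(igraph::as_edgelist(a$network),
                   igraph::as_edgelist(b$network))
  expect_identical(igraph::E(a$network)$confidence,
                   igraph::E(b$network)$confidence)
  g <- a$network
  conf <- igraph::E(g)$confidence
  expect_true(all(conf > 0 & conf <= 1))
  deg <- igraph::degree(g)
  hubs <- a$truth$hub_nodes
  q95 <- quantile(deg[setdiff(names(deg), hubs)], 0.95)
  expect_true(all(deg[hubs] > q95))
  # module density >= 0.8 (hub edges included)
  for (h in hubs) {
    mem <- a$truth$modules[[h]]
    sub <- igraph::induced_subgraph(g, c(h, mem))
    nn <- length(mem) + 1
    dens <- igraph::ecount(sub) / (nn * (nn - 1) / 2)
    expect_gte(dens, 0.8)
    expect_equal(unname(igraph::degree(g, h) >= length(mem)), TRUE)
  }
  # modules are disjoint
  expect_false(anyDuplicated(unlist(a$truth$modules)) > 0)
})

test_that("network generator null and degenerate-confidence cases", {
  p0 <- network_sim_params(n_nodes = 150, n_hubs = 0, seed = 5)
  g0 <- make_network(p0)$network
  expect_lt(max(igraph::degree(g0)), 40) # no planted outliers
  # near-1 confidences survive any practical cutoff
  p1 <- network_sim_params(n_nodes = 60, n_hubs = 2, hub_module_size = 5,
                           confidence_params = c(5000, 1), seed = 5)
  net <- make_network(p1)$network
  el <- as_edge_list(net)
  kept <- build_network(el, cutoff = 0.7)
  expect_equal(igraph::ecount(kept), nrow(el))
  expect_error(network_sim_params(n_nodes = 10, n_hubs = 3,
                                  hub_module_size = 5), "overlap")
})

test_that("single-cell generator plants QC failures at the stated rate", {
  p <- sc_sim_params(n_cells = 2000, frac_low_quality = 0.1, seed = 9)
  a <- make_scrna(p)
  b <- make_scrna(p)
  expect_identical(a$dataset$counts, b$dataset$counts)
  filtered <- qc_filter(a$dataset)
  removed <- ncol(a$dataset$counts) - ncol(filtered$counts)
  expect_lt(abs(removed / 2000 - 0.10), 0.02)
  # the planted failures are exactly the removed cells (within 1% stragglers)
  planted <- names(a$truth$qc_fail)[!is.na(a$truth$qc_fail)]
  qlog <- attr(filtered, "qc_log")
  expect_lt(length(setdiff(qlog$barcode, planted)) / 2000, 0.01)
  expect_lt(length(setdiff(planted, qlog$barcode)) / 2000, 0.01)
})

test_that("single-cell generator honours degenerate mixtures and null QC", {
  p0 <- sc_sim_params(n_cells = 400, n_genes = 600, frac_low_quality = 0,
                      seed = 2)
  a <- make_scrna(p0)
  filtered <- qc_filter(a$dataset)
  expect_lt(1 - ncol(filtered$counts) / 400, 0.01)
  p1 <- sc_sim_params(n_cells = 200, n_genes = 600,
                      epithelial_fraction = rep(1, 4), seed = 2)
  one <- make_scrna(p1)
  expect_equal(unique(unname(one$truth$cell_state)), "epithelial")
  expect_error(sc_sim_params(n_genes = 80,
                             signature_sizes = c(epithelial = 50,
                                                 mesenchymal = 50)),
               "exceed")
})

test_that("cohort generator hits the requested Spearman and censoring", {
  p <- cohort_sim_params(n_patients = 500, marker_correlations = c(VIM = 0.9),
                         seed = 13)
  a <- make_cohort(p)
  b <- make_cohort(p)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$survival, b$survival)
  ct <- marker_correlations(a$expression, "ADAMTS6", "VIM")
  expect_lt(abs(ct$rho - 0.9), 0.05)
  # censoring
  expect_lt(abs(mean(a$survival$event == 0) - 0.3), 0.1)
  nocens <- make_cohort(cohort_sim_params(censor_rate = 0, seed = 13))
  expect_true(all(nocens$survival$event == 1))
  expect_error(cohort_sim_params(marker_correlations = c(VIM = 1.2)),
               "non-positive-semidefinite")
})

test_that("null cohorts give uniform median-split log-rank rejections", {
  reps <- 200
  pvals <- vapply(seq_len(reps), function(i) {
    co <- make_cohort(cohort_sim_params(n_patients = 120,
                                        hazard_log_ratio = 0,
                                        n_background_genes = 0,
                                        seed = 4000 + i))
    grp <- median_split(co$expression, "ADAMTS6")
    st <- co$survival
    st$group <- unname(grp[st$sample])
    km_logrank(st)$p
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 1.96 * sqrt(0.05 * 0.95 / reps) + 0.01)
})
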