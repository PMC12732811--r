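# Single-cell stage: QC, normalization/HVG, clustering, classification and
# pseudobulk differential expression.

small_sc <- function(n_cells = 400, n_genes = 600, frac_low_quality = 0,
                     seed = 1, ...) {
  make_scrna(sc_sim_params(n_cells = n_cells, n_genes = n_genes,
                           frac_low_quality = frac_low_quality, seed = seed,
                           ...))
}

test_that("qc_filter applies the four strict bounds", {
  counts <- Matrix::Matrix(0, 600, 4, sparse = TRUE,
                           dimnames = list(c(sprintf("MT-G%02d", 1:10),
                                             sprintf("G%04d", 1:590)),
                                           paste0("c", 1:4)))
  set.seed(1)
  # c1: 150 detected genes -> removed; c2: high mito -> removed;
  # c3: healthy -> kept; c4: low UMI -> removed
  counts[sample(11:600, 150), 1] <- 10
  counts[11:400, 2] <- 5; counts[1:10, 2] <- 13 # ~6.25% mito
  counts[11:510, 3] <- 10; counts[1:10, 3] <- 2 # 1000 genes? 510 genes, 2% mito
  counts[sample(11:600, 300), 4] <- 2           # 600 UMI
  ds <- sc_dataset(counts)
  kept <- qc_filter(ds)
  expect_equal(colnames(kept$counts), "c3")
  qlog <- attr(kept, "qc_log")
  expect_match(qlog$reason[qlog$barcode == "c1"], "low_genes")
  expect_match(qlog$reason[qlog$barcode == "c2"], "high_mito")
  expect_match(qlog$reason[qlog$barcode == "c4"], "low_umi")
  # idempotence: filtering a filtered dataset removes nothing
  again <- qc_filter(kept)
  expect_equal(ncol(again$counts), ncol(kept$counts))
  expect_error(qc_filter(sc_dataset(counts[, 1, drop = FALSE])), "no cell")
})

test_that("boundary cells are excluded by the strict inequalities", {
  n_g <- 1300
  counts <- Matrix::Matrix(0, n_g, 2, sparse = TRUE,
                           dimnames = list(c("MT-G01",
                                             sprintf("G%04d", 1:(n_g - 1))),
                                           c("b1", "b2")))
  counts[2:201, 1] <- 10   # exactly 200 detected genes -> removed
  counts[2:1001, 2] <- 1; counts[1, 2] <- 1 # 1001 genes, 1002 UMI, mito ~0.1%
  ds <- sc_dataset(counts)
  kept <- qc_filter(ds)
  expect_equal(colnames(kept$counts), "b2")
})

test_that("normalization is library-size invariant and HVGs catch signatures", {
  sim <- small_sc(seed = 3)
  ds <- qc_filter(sim$dataset)
  ds <- suppressWarnings(normalize_and_hvg(ds, cluster_options(n_hvg = 300,
                                                               n_pcs = 30)))
  # proportional count vectors normalize identically
  c1 <- ds$counts[, 1]
  dbl <- cbind(c1, 2 * c1)
  colnames(dbl) <- c("x", "y")
  d2 <- normalize_and_hvg(sc_dataset(Matrix::Matrix(dbl, sparse = TRUE)),
                          cluster_options(n_hvg = 10, n_pcs = 5))
  expect_equal(as.numeric(d2$normalized[, 1]), as.numeric(d2$normalized[, 2]),
               tolerance = 1e-12)
  # planted signature genes are highly variable
  sig <- unlist(sim$truth$signatures)
  expect_gte(mean(sig %in% ds$hvg), 0.9)
  # constant genes are never HVGs while alternatives exist
  zero_gene <- rownames(ds$counts)[Matrix::rowSums(ds$counts) == 0]
  if (length(zero_gene)) expect_false(any(zero_gene %in% ds$hvg))
  # capping warns
  expect_warning(normalize_and_hvg(ds, cluster_options(n_hvg = 10000,
                                                       n_pcs = 10)),
                 "capped")
})

test_that("clustering is deterministic and recovers planted states", {
  sim <- small_sc(n_cells = 500, seed = 5)
  ds <- qc_filter(sim$dataset)
  ds <- suppressWarnings(normalize_and_hvg(ds))
  ds <- embed_and_cluster(ds, cluster_options(n_hvg = 600, n_pcs = 30,
                                              seed = 2))
  ds2 <- embed_and_cluster(ds, cluster_options(n_hvg = 600, n_pcs = 30,
                                               seed = 2))
  expect_identical(ds$meta$cluster, ds2$meta$cluster)
  truth <- sim$truth$cell_state[ds$meta$barcode]
  expect_gte(adjusted_rand_index(ds$meta$cluster, truth), 0.8)
  # labels are contiguous integers ordered by decreasing size
  sizes <- table(ds$meta$cluster)
  expect_equal(sort(unique(ds$meta$cluster)), seq_along(sizes))
  expect_true(all(diff(as.numeric(sizes)) <= 0))
})

test_that("classification follows signature dominance and majority truth", {
  sim <- small_sc(n_cells = 500, seed = 8)
  ds <- qc_filter(sim$dataset)
  ds <- suppressWarnings(normalize_and_hvg(ds))
  ds <- embed_and_cluster(ds, cluster_options(n_hvg = 600, n_pcs = 30,
                                              seed = 3))
  sig <- sim$truth$signatures
  cls <- classify_clusters(ds, sig$epithelial, sig$mesenchymal,
                           unique(c(sig$mesenchymal, sig$epithelial)))
  truth <- sim$truth$cell_state[ds$meta$barcode]
  for (k in cls$cluster_states$cluster) {
    maj <- names(which.max(table(truth[ds$meta$cluster == k])))
    expect_equal(cls$cluster_states$state[cls$cluster_states$cluster == k],
                 paste0(maj, "-like"))
  }
  # classification is invariant to cluster relabelling
  ds_swap <- ds
  ds_swap$meta$cluster <- max(ds$meta$cluster) + 1 - ds$meta$cluster
  cls2 <- classify_clusters(ds_swap, sig$epithelial, sig$mesenchymal,
                            unique(c(sig$mesenchymal, sig$epithelial)))
  m <- match(cls$cluster_states$cluster,
             max(ds$meta$cluster) + 1 - cls2$cluster_states$cluster)
  expect_equal(cls$cluster_states$state, cls2$cluster_states$state[m])
  expect_error(classify_clusters(ds, "NOTAGENE", sig$mesenchymal,
                                 sig$mesenchymal), "no overlap")
})

test_that("a single-state simulation yields one shared label", {
  sim <- make_scrna(sc_sim_params(n_cells = 220, n_genes = 600,
                                  epithelial_fraction = rep(1, 4),
                                  frac_low_quality = 0, seed = 4))
  ds <- qc_filter(sim$dataset)
  ds <- suppressWarnings(normalize_and_hvg(ds))
  ds <- embed_and_cluster(ds, cluster_options(n_hvg = 500, n_pcs = 20,
                                              seed = 5))
  sig <- sim$truth$signatures
  cls <- classify_clusters(ds, sig$epithelial, sig$mesenchymal,
                           unique(c(sig$mesenchymal, sig$epithelial)))
  expect_equal(unique(cls$cluster_states$state), "epithelial-like")
})

test_that("pseudobulk DE recovers planted signature genes", {
  sim <- small_sc(n_cells = 500, seed = 10)
  ds <- qc_filter(sim$dataset)
  pb <- pseudobulk_de(ds, states = paste0(ds$meta$state, "-like"), seed = 2)
  sig <- sim$truth$signatures
  up <- pb$selected$gene[pb$selected$direction == "up"]
  dn <- pb$selected$gene[pb$selected$direction == "down"]
  expect_gte(mean(sig$mesenchymal %in% up), 0.9)
  expect_gte(mean(sig$epithelial %in% dn), 0.9)
  # determinism
  pb2 <- pseudobulk_de(ds, states = paste0(ds$meta$state, "-like"), seed = 2)
  expect_identical(pb$de, pb2$de)
  # identical pooled profiles in both states -> no selections: state b is an
  # exact copy of state a cells, so the pooled profiles coincide while the
  # random pseudo-replicate partitions still vary
  cells <- as.matrix(ds$counts[, 1:30])
  twin <- cbind(cells, cells)
  colnames(twin) <- paste0("c", seq_len(60))
  pbf <- pseudobulk_de(sc_dataset(Matrix::Matrix(twin, sparse = TRUE),
                                  state = rep(c("a", "b"), each = 30)),
                       seed = 3)
  expect_equal(nrow(pbf$selected), 0)
  expect_error(pseudobulk_de(ds, states = c(rep("a", 2),
                                            rep("b", ncol(ds$counts) - 2))),
               "fewer than")
})
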