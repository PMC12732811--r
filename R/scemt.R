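# Single-cell EMT stage: quality control, library-size normalization and
# highly-variable-gene selection, PCA + graph clustering, ssGSEA-based
# epithelial/mesenchymal cluster classification, and pseudobulk differential
# expression.

#' Single-cell dataset
#'
#' Sparse genes x cells counts with per-cell metadata. Detected-gene counts,
#' UMI totals and mitochondrial fractions (genes prefixed `MT-`) are computed
#' from the counts.
#'
#' @param counts A sparse (or dense) genes x cells matrix of non-negative
#'   integer counts with gene rownames and cell colnames.
#' @param timepoint Optional per-cell timepoint labels.
#' @param state Optional per-cell true state labels (simulation bookkeeping).
#' @return An object of class `sc_dataset`: list with `counts`, `meta`
#'   (data.frame: `barcode`, `n_genes`, `n_umi`, `mito_frac`, plus
#'   `timepoint`/`state` when supplied), and later layers added by
#'   [normalize_and_hvg] / [embed_and_cluster].
#' @export
sc_dataset <- function(counts, timepoint = NULL, state = NULL) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("counts must have gene rownames and cell colnames")
  }
  if (any(counts < 0) || any(counts@x != floor(counts@x))) {
    stopf("counts must be non-negative integers")
  }
  mito <- grepl("^MT-", rownames(counts))
  umi <- Matrix::colSums(counts)
  meta <- data.frame(
    barcode = colnames(counts),
    n_genes = Matrix::colSums(counts > 0),
    n_umi = umi,
    mito_frac = ifelse(umi > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / umi, 0),
    stringsAsFactors = FALSE
  )
  if (!is.null(timepoint)) meta$timepoint <- timepoint
  if (!is.null(state)) meta$state <- state
  rownames(meta) <- meta$barcode
  structure(list(counts = counts, meta = meta), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("<sc_dataset> %d genes x %d cells\n", nrow(x$counts),
              ncol(x$counts)))
  if (!is.null(x$hvg)) cat(length(x$hvg), "highly variable genes\n")
  if (!is.null(x$meta$cluster)) {
    cat("clusters:", paste(sort(unique(x$meta$cluster)), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

#' Quality-control thresholds
#'
#' All four bounds are strict: cells are kept with detected genes in
#' (min_genes, max_genes), UMI total above `min_umi` and mitochondrial
#' fraction below `max_mito`.
#'
#' @param min_genes,max_genes Exclusive bounds on detected genes (defaults
#'   200 and 5000).
#' @param min_umi Exclusive lower bound on UMI total (default 1000).
#' @param max_mito Exclusive upper bound on mitochondrial fraction (default
#'   0.05).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 5000, min_umi = 1000,
                          max_mito = 0.05) {
  if (min_genes >= max_genes) stopf("min_genes must be below max_genes")
  structure(list(min_genes = check_count(min_genes, "min_genes"),
                 max_genes = check_count(max_genes, "max_genes"),
                 min_umi = check_count(min_umi, "min_umi"),
                 max_mito = check_number(max_mito, "max_mito", lower = 0,
                                         upper = 1, open_lower = TRUE)),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Keeps cells strictly inside all four QC bounds; genes are unchanged.
#' Removal reasons are recorded per cell in the `qc_log` attribute.
#'
#' @param x An [sc_dataset].
#' @param thresholds A [qc_thresholds] object.
#' @return The filtered [sc_dataset].
#' @export
qc_filter <- function(x, thresholds = qc_thresholds()) {
  stopifnot(inherits(x, "sc_dataset"), inherits(thresholds, "qc_thresholds"))
  m <- x$meta
  reasons <- character(nrow(m))
  reasons[m$n_genes <= thresholds$min_genes] <- "low_genes"
  reasons[m$n_genes >= thresholds$max_genes] <- "high_genes"
  reasons[m$n_umi <= thresholds$min_umi] <-
    paste0(reasons[m$n_umi <= thresholds$min_umi], "+low_umi")
  reasons[m$mito_frac >= thresholds$max_mito] <-
    paste0(reasons[m$mito_frac >= thresholds$max_mito], "+high_mito")
  reasons <- sub("^\\+", "", reasons)
  keep <- reasons == ""
  if (!any(keep)) stopf("no cell passes quality control")
  out <- sc_dataset(x$counts[, keep, drop = FALSE],
                    timepoint = x$meta$timepoint[keep],
                    state = x$meta$state[keep])
  attr(out, "qc_log") <- data.frame(barcode = m$barcode[!keep],
                                    reason = reasons[!keep],
                                    stringsAsFactors = FALSE)
  out
}

#' Clustering options
#'
#' @param n_hvg Number of highly variable genes (default 2000; capped at the
#'   gene count with a warning).
#' @param n_pcs Number of principal components (default 50).
#' @param neighbors_k Neighbors for the kNN graph (default 20).
#' @param resolution Community-detection resolution (default 1).
#' @param seed Seed for community detection and any stochastic step.
#' @return An object of class `cluster_options`.
#' @export
cluster_options <- function(n_hvg = 2000, n_pcs = 50, neighbors_k = 20,
                            resolution = 1, seed = 1) {
  if (n_pcs > n_hvg) stopf("n_pcs must not exceed n_hvg")
  structure(list(n_hvg = check_count(n_hvg, "n_hvg"),
                 n_pcs = check_count(n_pcs, "n_pcs"),
                 neighbors_k = check_count(neighbors_k, "neighbors_k"),
                 resolution = check_number(resolution, "resolution",
                                           lower = 0, open_lower = TRUE),
                 seed = check_count(seed, "seed", min = 0)),
            class = "cluster_options")
}

#' Normalize counts and select highly variable genes
#'
#' Library-size normalization to 10,000 counts per cell followed by log1p;
#' the HVG set is the top `n_hvg` genes by variance of the normalized values.
#' A per-gene z-scaled layer over the HVGs is stored for the embedding.
#'
#' @param x A QC-filtered [sc_dataset].
#' @param options A [cluster_options] object.
#' @return The [sc_dataset] with `normalized`, `hvg` and `scaled` layers.
#' @export
normalize_and_hvg <- function(x, options = cluster_options()) {
  stopifnot(inherits(x, "sc_dataset"))
  libs <- Matrix::colSums(x$counts)
  if (any(libs == 0)) stopf("cells with zero counts cannot be normalized")
  norm <- x$counts %*% Matrix::Diagonal(x = 1e4 / libs)
  norm@x <- log1p(norm@x)
  colnames(norm) <- colnames(x$counts)
  nc <- ncol(norm)
  mu <- Matrix::rowMeans(norm)
  v <- (Matrix::rowSums(norm^2) / nc - mu^2) * nc / (nc - 1)
  n_hvg <- options$n_hvg
  if (n_hvg > nrow(norm)) {
    warnf("n_hvg capped at the gene count (%d)", nrow(norm))
    n_hvg <- nrow(norm)
  }
  hvg <- rownames(norm)[order(-v, rownames(norm))][seq_len(n_hvg)]
  scl <- as.matrix(norm[hvg, , drop = FALSE])
  mu_h <- rowMeans(scl)
  sd_h <- sqrt(row_vars(scl))
  scl <- (scl - mu_h) / ifelse(sd_h > 0, sd_h, 1)
  x$normalized <- norm
  x$hvg <- hvg
  x$scaled <- scl
  x
}

#' PCA embedding and graph clustering
#'
#' PCA on the scaled HVG layer (deterministic sign convention: the
#' largest-magnitude loading of each component is positive), a k-nearest-
#' neighbor graph in PC space (Euclidean), and seeded multilevel modularity
#' community detection at the stated resolution. Cluster labels are
#' contiguous integers ordered by decreasing cluster size.
#'
#' @param x An [sc_dataset] with `scaled` layer (see [normalize_and_hvg]).
#' @param options A [cluster_options] object.
#' @return The [sc_dataset] with `pca` (cells x PCs) and `meta$cluster`.
#' @export
embed_and_cluster <- function(x, options = cluster_options()) {
  stopifnot(inherits(x, "sc_dataset"))
  if (is.null(x$scaled)) stopf("run normalize_and_hvg() first")
  X <- t(x$scaled)
  n <- nrow(X)
  npc <- min(options$n_pcs, ncol(X), n - 1)
  cx <- crossprod(X) / (n - 1)
  ev <- eigen(cx, symmetric = TRUE)
  V <- ev$vectors[, seq_len(npc), drop = FALSE]
  for (j in seq_len(npc)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- X %*% V
  colnames(scores) <- paste0("PC", seq_len(npc))
  k <- options$neighbors_k
  if (k >= n) {
    warnf("neighbors_k reduced to %d (only %d cells)", n - 1, n)
    k <- n - 1
  }
  D <- as.matrix(stats::dist(scores))
  diag(D) <- Inf
  nn <- apply(D, 1, function(row) order(row)[seq_len(k)])
  from <- rep(seq_len(n), each = k)
  g <- igraph::simplify(igraph::graph_from_edgelist(
    cbind(from, as.vector(nn)), directed = FALSE))
  memb <- with_seed(options$seed, {
    igraph::membership(igraph::cluster_louvain(g,
                                               resolution = options$resolution))
  })
  sizes <- table(memb)
  relabel <- stats::setNames(seq_along(sizes),
                             names(sort(sizes, decreasing = TRUE)))
  x$pca <- scores
  x$meta$cluster <- as.integer(relabel[as.character(memb)])
  x
}

#' Classify clusters as epithelial-like or mesenchymal-like
#'
#' Per-cell ssGSEA scores are computed for the epithelial, mesenchymal and
#' hallmark-EMT sets. A cluster is mesenchymal-like iff its mean per-cell
#' score difference (mesenchymal minus epithelial, on the common ssGSEA
#' scale) is positive; this absolute rule keeps a pure single-state dataset
#' on one label. Per-set z-scores across cells (the relative enrichment
#' usually plotted per cluster) and the hallmark-EMT mean are reported as
#' supporting evidence.
#'
#' @param x A clustered [sc_dataset].
#' @param epithelial,mesenchymal,hallmark Character vectors of gene symbols.
#' @param alpha ssGSEA rank-weight exponent.
#' @return An object of class `emt_classification`: `cluster_states`
#'   (data.frame: cluster, n_cells, mean z per set, state) and `cell_states`
#'   (named per-cell state labels).
#' @export
classify_clusters <- function(x, epithelial, mesenchymal, hallmark,
                              alpha = 0.25) {
  stopifnot(inherits(x, "sc_dataset"))
  if (is.null(x$meta$cluster)) stopf("run embed_and_cluster() first")
  if (is.null(x$normalized)) stopf("run normalize_and_hvg() first")
  sets <- list(epithelial = epithelial, mesenchymal = mesenchymal,
               hallmark_emt = hallmark)
  present <- rownames(x$normalized)
  for (nm in names(sets)) {
    if (!any(toupper(sets[[nm]]) %in% toupper(present))) {
      stopf("the %s set has no overlap with the dataset genes", nm)
    }
  }
  sc <- ssgsea_scores(as.matrix(x$normalized), sets, alpha = alpha)
  z <- t(scale(t(sc)))
  z[!is.finite(z)] <- 0 # constant scores (degenerate data) carry no evidence
  diff_mes <- sc["mesenchymal", ] - sc["epithelial", ]
  cl <- x$meta$cluster
  rows <- lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    mz <- rowMeans(z[, idx, drop = FALSE])
    data.frame(cluster = k, n_cells = length(idx),
               mean_z_epithelial = mz[["epithelial"]],
               mean_z_mesenchymal = mz[["mesenchymal"]],
               mean_z_hallmark = mz[["hallmark_emt"]],
               state = if (mean(diff_mes[idx]) > 0)
                 "mesenchymal-like" else "epithelial-like",
               stringsAsFactors = FALSE)
  })
  cluster_states <- do.call(rbind, rows)
  cell_states <- stats::setNames(
    cluster_states$state[match(cl, cluster_states$cluster)],
    x$meta$barcode)
  structure(list(cluster_states = cluster_states, cell_states = cell_states,
                 scores = sc),
            class = "emt_classification")
}

#' @export
print.emt_classification <- function(x, ...) {
  cat("<emt_classification>\n")
  print.data.frame(x$cluster_states, digits = 3)
  invisible(x)
}

#' Pseudobulk differential expression between two cell states
#'
#' Cells of each state are partitioned uniformly at random (seeded) into
#' `n_replicates` pseudo-replicates; counts are summed per replicate,
#' converted to log2 counts-per-million with a +1 pseudocount, and tested
#' with the moderated two-group test. Selection uses the stated thresholds
#' (default |log2FC| >= 0.5, FDR < 0.05).
#'
#' @param x An [sc_dataset].
#' @param states Per-cell state labels (defaults to `x$meta$state_call`, then
#'   `x$meta$state`).
#' @param group_a,group_b The two state labels compared (`log2FC = A - B`);
#'   default mesenchymal-like vs epithelial-like (falling back to the sorted
#'   unique labels).
#' @param thresholds A [de_thresholds] object.
#' @param n_replicates Pseudo-replicates per state (default 3).
#' @param seed Seed for the random partition.
#' @return List with `de` (a `de_result`) and `selected` (the DEG table).
#' @export
pseudobulk_de <- function(x, states = NULL, group_a = NULL, group_b = NULL,
                          thresholds = de_thresholds(0.5, 0.05),
                          n_replicates = 3, seed = 1) {
  stopifnot(inherits(x, "sc_dataset"))
  if (is.null(states)) states <- x$meta$state_call
  if (is.null(states)) states <- x$meta$state
  if (is.null(states)) stopf("no state labels available")
  states <- as.character(states)
  lv <- sort(unique(states))
  if (length(lv) != 2) stopf("exactly two states required, got: %s",
                             paste(lv, collapse = ", "))
  if (is.null(group_a)) {
    group_a <- if ("mesenchymal-like" %in% lv) "mesenchymal-like" else lv[2]
  }
  if (is.null(group_b)) group_b <- setdiff(lv, group_a)
  for (s in lv) {
    if (sum(states == s) < n_replicates) {
      stopf("state '%s' has fewer than %d cells", s, n_replicates)
    }
  }
  pb <- with_seed(seed, {
    cols <- list()
    for (s in lv) {
      idx <- which(states == s)
      part <- sample(rep(seq_len(n_replicates), length.out = length(idx)))
      for (r in seq_len(n_replicates)) {
        cols[[paste0(s, "_rep", r)]] <-
          Matrix::rowSums(x$counts[, idx[part == r], drop = FALSE])
      }
    }
    do.call(cbind, cols)
  })
  cpm <- log2(t(t(pb) / colSums(pb)) * 1e6 + 1)
  rownames(cpm) <- rownames(x$counts)
  groups <- sub("_rep[0-9]+$", "", colnames(cpm))
  em <- expr_matrix(cpm, groups, log2_scale = TRUE)
  de <- differential_expression(em, group_a, group_b, moderated = TRUE)
  list(de = de, selected = select_degs(de, thresholds))
}
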