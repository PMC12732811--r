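# Multi-dataset hub-study scenario: the synthetic counterpart of re-analyzing
# several TGF-beta1 induction experiments against one interactome. Four (by
# default) expression datasets share the planted hub genes and the EMT marker
# panel as DEGs; each dataset has its own independently wired network in which
# the same hubs carry dense modules drawn from that dataset's DEGs.

#' Simulate a multi-dataset hub-discovery study
#'
#' Generates `n_datasets` two-group expression matrices over a common gene
#' universe plus one interaction network per dataset. The planted hub genes
#' are differentially expressed (up) in every dataset and sit at the centre
#' of a dense module in every network; module membership is re-randomized per
#' network and each network's module members are planted as DEGs of the
#' matching dataset, so the hubs - and only the hubs - are recurrently
#' central. The EMT marker panel is differentially expressed in every dataset
#' (a shared program) but carries no planted wiring.
#'
#' @param n_datasets Number of datasets/networks.
#' @param n_genes Gene universe size.
#' @param n_per_group Samples per group in each dataset.
#' @param n_de Planted DEGs per dataset (must cover hubs, module members and
#'   the marker panel).
#' @param lfc_magnitude Planted effect size, log2 units.
#' @param noise_sd Expression noise, log2 units.
#' @param n_nodes,n_hubs,hub_module_size,background_attachment,confidence_params
#'   Network parameters, see [network_sim_params].
#' @param marker_panel Marker panel data frame (see [emt_marker_panel]).
#' @param seed Integer master seed; per-dataset seeds are derived from it.
#' @return A list with `datasets` (named list of [expr_matrix]), `edges`
#'   (list of edge data.frames), and `truth` (hub ids, per-dataset DEG truth,
#'   per-network modules).
#' @export
simulate_hub_study <- function(n_datasets = 4, n_genes = 1000, n_per_group = 5,
                               n_de = 100, lfc_magnitude = 3, noise_sd = 0.5,
                               n_nodes = 300, n_hubs = 5, hub_module_size = 15,
                               background_attachment = 2,
                               confidence_params = c(6, 2),
                               marker_panel = emt_marker_panel(), seed = 1) {
  n_datasets <- check_count(n_datasets, "n_datasets", min = 2)
  hubs <- sprintf("HUB%02d", seq_len(n_hubs))
  markers <- if (is.null(marker_panel)) character(0) else toupper(marker_panel$gene)
  n_named <- n_hubs + length(markers)
  universe <- c(hubs, markers,
                sprintf("G%04d", seq_len(n_genes - n_named)))
  need <- n_hubs + n_hubs * hub_module_size + length(markers)
  if (n_de < need) {
    stopf("n_de (%d) must cover hubs, module members and markers (%d)",
          n_de, need)
  }
  datasets <- list(); edge_lists <- list(); net_truth <- list(); ds_truth <- list()
  for (i in seq_len(n_datasets)) {
    net_seed <- seed * 1000L + i
    node_names <- with_seed(net_seed, {
      c(hubs, sample(setdiff(universe, hubs), n_nodes - n_hubs))
    })
    net <- make_network(network_sim_params(
      n_nodes = n_nodes, n_hubs = n_hubs, hub_module_size = hub_module_size,
      background_attachment = background_attachment,
      confidence_params = confidence_params,
      node_names = node_names, hub_nodes = hubs, seed = net_seed + 1L))
    members <- setdiff(unique(unlist(net$truth$modules)), markers)
    pinned <- c(stats::setNames(rep("up", n_hubs), hubs),
                stats::setNames(rep("up", length(members)), members))
    bulk <- make_bulk_expression(bulk_sim_params(
      n_genes = n_genes, n_per_group = n_per_group, n_de = n_de,
      lfc_magnitude = lfc_magnitude, noise_sd = noise_sd,
      marker_panel = marker_panel, de_genes = pinned,
      seed = net_seed + 2L))
    # rebuild on the shared universe: pinned + marker symbols already among
    # the generated names; replace the generator's filler names with the
    # study universe so datasets and networks share symbols
    v <- bulk$expression$values
    planted <- unique(c(names(pinned), markers))
    filler <- setdiff(universe, planted)
    rn <- rownames(v)
    rn[!rn %in% planted] <- filler[seq_len(sum(!rn %in% planted))]
    rownames(v) <- rn
    bulk$truth$de_genes$gene <- rn[match(bulk$truth$de_genes$gene,
                                         rownames(bulk$expression$values))]
    dn <- sprintf("dataset%d", i)
    datasets[[dn]] <- expr_matrix(v, bulk$expression$groups, log2_scale = TRUE)
    edge_lists[[dn]] <- as_edge_list(net$network)
    net_truth[[dn]] <- net$truth
    ds_truth[[dn]] <- bulk$truth
  }
  truth <- structure(list(hub_genes = hubs, markers = markers,
                          datasets = ds_truth, networks = net_truth),
                     class = "ground_truth")
  list(datasets = datasets, edges = edge_lists, truth = truth)
}
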