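# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with planted, recoverable ground truth, so all downstream
# stages are testable without external downloads.

#' EMT marker panel
#'
#' The default epithelial/mesenchymal marker panel used by the generators:
#' mesenchymal markers and EMT transcription factors (up during EMT) and
#' epithelial markers (down during EMT). Real symbols are used so that GMT
#' fixtures built on synthetic data remain meaningful.
#'
#' @return A data.frame with columns `gene` and `direction` (`"up"`/`"down"`).
#' @export
emt_marker_panel <- function() {
  data.frame(
    gene = c("CDH2", "VIM", "FN1", "SNAI1", "SNAI2", "ZEB1", "ZEB2",
             "TWIST1", "ADAMTS6",
             "CDH1", "EPCAM", "KRT19", "OCLN"),
    direction = c(rep("up", 9), rep("down", 4)),
    stringsAsFactors = FALSE
  )
}

#' Parameters for the bulk two-group expression generator
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (two groups: treated vs control).
#' @param n_de Number of planted differentially expressed genes (must be at
#'   least the size of the marker panel, which is always planted).
#' @param lfc_magnitude Mean planted effect, in log2 units (> 0).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale (> 0).
#' @param marker_panel Data frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`), or `NULL` for no marker panel. Marker genes are always
#'   planted DEGs with the stated sign.
#' @param de_genes Optional named character vector of directions
#'   (`"up"`/`"down"`) explicitly pinning which genes are planted DEGs;
#'   remaining slots up to `n_de` are filled at random.
#' @param seed Integer seed.
#' @return An object of class `bulk_sim_params`.
#' @export
bulk_sim_params <- function(n_genes = 1000, n_per_group = 5, n_de = 100,
                            lfc_magnitude = 2, noise_sd = 0.5,
                            marker_panel = emt_marker_panel(),
                            de_genes = NULL, seed = 1) {
  p <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_per_group = check_count(n_per_group, "n_per_group", min = 2),
    n_de = check_count(n_de, "n_de", min = 0),
    lfc_magnitude = check_number(lfc_magnitude, "lfc_magnitude",
                                 lower = 0, open_lower = TRUE),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0, open_lower = TRUE),
    marker_panel = marker_panel,
    de_genes = de_genes,
    seed = check_count(seed, "seed", min = 0)
  )
  if (p$n_de > p$n_genes) stopf("n_de must not exceed n_genes")
  n_pinned <- length(de_genes)
  if (!is.null(marker_panel)) {
    stopifnot(all(c("gene", "direction") %in% names(marker_panel)))
    if (p$n_de > 0 && p$n_de < nrow(marker_panel) + n_pinned) {
      stopf("n_de (%d) is too small for the marker panel plus pinned DEGs",
            p$n_de)
    }
    if (p$n_de == 0) p$marker_panel <- NULL # null case: nothing is planted
  }
  structure(p, class = "bulk_sim_params")
}

#' Simulate a two-group bulk expression matrix with planted DEGs
#'
#' Generates a microarray-like log2-scale matrix: per-gene baseline means,
#' Gaussian noise, and a planted group-mean shift of exactly
#' `+/- lfc_magnitude` for the chosen DE genes (treated minus control).
#' The EMT marker panel is always among the planted DEGs with its stated
#' directions (epithelial down, mesenchymal up).
#'
#' @param params A [bulk_sim_params] object.
#' @return A list with `expression` (an [expr_matrix] with groups `"treated"`
#'   and `"control"`) and `truth` (planted DEG table and parameter echo).
#' @export
make_bulk_expression <- function(params = bulk_sim_params()) {
  stopifnot(inherits(params, "bulk_sim_params"))
  p <- params
  with_seed(p$seed, {
    markers <- p$marker_panel
    fixed <- character(0)
    fixed_dir <- character(0)
    if (!is.null(markers)) {
      fixed <- toupper(markers$gene)
      fixed_dir <- markers$direction
    }
    if (!is.null(p$de_genes)) {
      extra <- setdiff(toupper(names(p$de_genes)), fixed)
      fixed_dir <- c(fixed_dir, unname(p$de_genes[match(extra, toupper(names(p$de_genes)))]))
      fixed <- c(fixed, extra)
    }
    if (length(fixed) > p$n_de) stopf("more pinned DEGs than n_de allows")
    n_bg <- p$n_genes - length(fixed)
    genes <- c(fixed, sprintf("G%04d", seq_len(n_bg)))
    genes <- make.unique(genes) # pinned symbols may collide with G#### names
    de_idx <- integer(0)
    if (p$n_de > 0) {
      free <- setdiff(seq_len(p$n_genes), seq_along(fixed))
      de_idx <- c(seq_along(fixed), sample(free, p$n_de - length(fixed)))
    }
    signs <- numeric(p$n_genes)
    if (length(de_idx)) {
      signs[de_idx] <- sample(c(-1, 1), length(de_idx), replace = TRUE)
      if (length(fixed)) {
        signs[seq_along(fixed)] <- ifelse(fixed_dir == "up", 1, -1)
      }
    }
    base <- runif(p$n_genes, 4, 10)
    n <- p$n_per_group
    samples <- c(sprintf("TRT%02d", seq_len(n)), sprintf("CTL%02d", seq_len(n)))
    groups <- c(rep("treated", n), rep("control", n))
    mu <- matrix(base, p$n_genes, 2 * n)
    mu[, seq_len(n)] <- mu[, seq_len(n)] + signs * p$lfc_magnitude
    vals <- mu + matrix(rnorm(p$n_genes * 2 * n, sd = p$noise_sd),
                        p$n_genes, 2 * n)
    dimnames(vals) <- list(genes, samples)
    truth <- list(
      de_genes = data.frame(
        gene = genes[de_idx],
        sign = signs[de_idx],
        lfc = signs[de_idx] * p$lfc_magnitude,
        stringsAsFactors = FALSE
      ),
      params = unclass(p)
    )
    list(expression = expr_matrix(vals, groups, log2_scale = TRUE),
         truth = structure(truth, class = "ground_truth"))
  })
}

#' Parameters for the interaction-network generator
#'
#' @param n_nodes Number of nodes.
#' @param n_hubs Number of planted hub nodes.
#' @param hub_module_size Members per hub module (disjoint across hubs).
#' @param background_attachment Edges added per node by the preferential
#'   attachment background process.
#' @param confidence_params Two positive Beta shape parameters for edge
#'   confidence scores in (0, 1].
#' @param module_density Fraction of member pairs wired within each module
#'   (>= 0.8 so modules are dense).
#' @param node_names Optional character vector of node names (length
#'   `n_nodes`); defaults to synthetic symbols.
#' @param hub_nodes Optional character vector pinning which named nodes are
#'   the planted hubs (must be among `node_names`).
#' @param seed Integer seed.
#' @return An object of class `network_sim_params`.
#' @export
network_sim_params <- function(n_nodes = 300, n_hubs = 5, hub_module_size = 15,
                               background_attachment = 2,
                               confidence_params = c(6, 2),
                               module_density = 0.9,
                               node_names = NULL, hub_nodes = NULL, seed = 1) {
  p <- list(
    n_nodes = check_count(n_nodes, "n_nodes", min = 1),
    n_hubs = check_count(n_hubs, "n_hubs", min = 0),
    hub_module_size = check_count(hub_module_size, "hub_module_size", min = 1),
    background_attachment = check_count(background_attachment,
                                        "background_attachment", min = 1),
    confidence_params = confidence_params,
    module_density = check_number(module_density, "module_density",
                                  lower = 0.8, upper = 1),
    node_names = node_names,
    hub_nodes = hub_nodes,
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(confidence_params) != 2 || any(confidence_params <= 0)) {
    stopf("confidence_params must be two positive shape values")
  }
  if (p$n_hubs * (1 + p$hub_module_size) > p$n_nodes) {
    stopf("hub modules would overlap: n_hubs * (1 + hub_module_size) > n_nodes")
  }
  if (!is.null(node_names)) {
    if (length(node_names) != p$n_nodes || anyDuplicated(node_names)) {
      stopf("node_names must be %d unique names", p$n_nodes)
    }
    p$node_names <- toupper(node_names)
  }
  if (!is.null(hub_nodes)) {
    p$hub_nodes <- toupper(hub_nodes)
    if (length(p$hub_nodes) != p$n_hubs) {
      stopf("hub_nodes must name exactly n_hubs nodes")
    }
    if (is.null(p$node_names)) stopf("hub_nodes requires node_names")
    if (!all(p$hub_nodes %in% p$node_names)) {
      stopf("hub_nodes must be among node_names")
    }
  }
  structure(p, class = "network_sim_params")
}

#' Simulate a scale-free-ish network with planted hub modules
#'
#' A background graph is grown by preferential attachment; each planted hub is
#' wired to all members of its own dense module (disjoint modules, pairwise
#' member edges at `module_density`) and to at least twice the median
#' background degree of random extra nodes. Every edge carries a
#' Beta-distributed confidence score in (0, 1].
#'
#' @param params A [network_sim_params] object.
#' @return A list with `network` (an `interaction_network`, see
#'   [build_network]) and `truth` (hub ids and module membership).
#' @export
make_network <- function(params = network_sim_params()) {
  stopifnot(inherits(params, "network_sim_params"))
  p <- params
  with_seed(p$seed, {
    nm <- p$node_names
    if (is.null(nm)) nm <- sprintf("N%04d", seq_len(p$n_nodes))
    g <- igraph::sample_pa(p$n_nodes, m = p$background_attachment,
                           directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- nm
    med_deg <- stats::median(igraph::degree(g))
    hubs <- character(0)
    modules <- list()
    if (p$n_hubs > 0) {
      hubs <- p$hub_nodes
      if (is.null(hubs)) hubs <- sample(nm, p$n_hubs)
      pool <- setdiff(nm, hubs)
      members <- sample(pool, p$n_hubs * p$hub_module_size)
      modules <- split(members, rep(seq_len(p$n_hubs), each = p$hub_module_size))
      names(modules) <- hubs
      new_edges <- character(0)
      for (h in hubs) {
        mem <- modules[[h]]
        new_edges <- c(new_edges, rbind(h, mem))
        pairs <- utils::combn(mem, 2)
        n_keep <- ceiling(p$module_density * ncol(pairs))
        keep <- sample(ncol(pairs), n_keep)
        new_edges <- c(new_edges, pairs[, keep])
        n_extra <- ceiling(2 * med_deg)
        extra <- sample(setdiff(nm, c(h, mem)), min(n_extra, p$n_nodes - 1 - length(mem)))
        new_edges <- c(new_edges, rbind(h, extra))
      }
      g <- igraph::add_edges(g, match(new_edges, nm))
      g <- igraph::simplify(g)
    }
    conf <- stats::rbeta(igraph::ecount(g), p$confidence_params[1],
                         p$confidence_params[2])
    conf[conf <= 0] <- .Machine$double.eps
    conf[conf > 1] <- 1
    igraph::E(g)$confidence <- conf
    truth <- list(hub_nodes = hubs, modules = modules,
                  median_background_degree = med_deg, params = unclass(p))
    list(network = as_interaction_network(g),
         truth = structure(truth, class = "ground_truth"))
  })
}

#' Parameters for the single-cell count generator
#'
#' @param n_cells Number of cells.
#' @param n_genes Number of genes (including mitochondrial and signature
#'   genes).
#' @param timepoints Labels of the induction timepoints.
#' @param epithelial_fraction Proportion of epithelial cells per timepoint
#'   (mesenchymal fraction is the complement, so state fractions sum to 1).
#' @param signature_sizes Named counts of epithelial and mesenchymal
#'   signature genes.
#' @param signature_lfc Log2 up-shift of a state's signature genes in cells of
#'   that state.
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (variance = mu + dispersion * mu^2).
#' @param mean_umi Mean library size of healthy cells.
#' @param frac_low_quality Proportion of planted QC-failing cells in [0, 1).
#' @param mito_gene_count Number of mitochondrial (`MT-`) genes.
#' @param seed Integer seed.
#' @return An object of class `sc_sim_params`.
#' @export
sc_sim_params <- function(n_cells = 2000, n_genes = 1500,
                          timepoints = c("d0", "d1", "d3", "d7"),
                          epithelial_fraction = c(0.9, 0.6, 0.3, 0.1),
                          signature_sizes = c(epithelial = 50, mesenchymal = 50),
                          signature_lfc = 2, nb_dispersion = 0.5,
                          mean_umi = 2500, frac_low_quality = 0.05,
                          mito_gene_count = 30, seed = 1) {
  p <- list(
    n_cells = check_count(n_cells, "n_cells", min = 10),
    n_genes = check_count(n_genes, "n_genes", min = 50),
    timepoints = as.character(timepoints),
    epithelial_fraction = as.numeric(epithelial_fraction),
    signature_sizes = signature_sizes,
    signature_lfc = check_number(signature_lfc, "signature_lfc", lower = 0),
    nb_dispersion = check_number(nb_dispersion, "nb_dispersion",
                                 lower = 0, open_lower = TRUE),
    mean_umi = check_count(mean_umi, "mean_umi", min = 100),
    frac_low_quality = check_number(frac_low_quality, "frac_low_quality",
                                    lower = 0, upper = 1, open_upper = TRUE),
    mito_gene_count = check_count(mito_gene_count, "mito_gene_count", min = 1),
    seed = check_count(seed, "seed", min = 0)
  )
  if (length(p$epithelial_fraction) != length(p$timepoints)) {
    stopf("one epithelial fraction per timepoint required")
  }
  if (any(p$epithelial_fraction < 0 | p$epithelial_fraction > 1)) {
    stopf("state fractions must lie in [0, 1]")
  }
  if (sum(p$signature_sizes) + p$mito_gene_count > p$n_genes) {
    stopf("signature sizes plus mitochondrial genes exceed n_genes")
  }
  structure(p, class = "sc_sim_params")
}

#' Simulate single-cell RNA counts from two latent EMT states
#'
#' Negative-binomial counts from two latent states (epithelial/mesenchymal)
#' whose mixture changes over an induction time course. Each state's signature
#' genes are up-shifted in cells of that state. A planted fraction of
#' low-quality cells violates at least one quality-control bound (low library
#' size or high mitochondrial content).
#'
#' The marker panel symbols head the signatures (epithelial markers in the
#' epithelial signature, mesenchymal markers in the mesenchymal signature) so
#' GMT fixtures built from the truth are meaningful.
#'
#' @param params An [sc_sim_params] object.
#' @return A list with `dataset` (an [sc_dataset]) and `truth` (per-cell state
#'   labels, planted QC failures, signature gene lists).
#' @export
make_scrna <- function(params = sc_sim_params()) {
  stopifnot(inherits(params, "sc_sim_params"))
  p <- params
  with_seed(p$seed, {
    panel <- emt_marker_panel()
    epi_n <- p$signature_sizes[["epithelial"]]
    mes_n <- p$signature_sizes[["mesenchymal"]]
    epi_head <- panel$gene[panel$direction == "down"]
    mes_head <- panel$gene[panel$direction == "up"]
    epi_sig <- c(epi_head, sprintf("EPI%03d", seq_len(max(0, epi_n - length(epi_head)))))[seq_len(epi_n)]
    mes_sig <- c(mes_head, sprintf("MES%03d", seq_len(max(0, mes_n - length(mes_head)))))[seq_len(mes_n)]
    mito <- sprintf("MT-G%02d", seq_len(p$mito_gene_count))
    n_bg <- p$n_genes - epi_n - mes_n - p$mito_gene_count
    genes <- c(mito, epi_sig, mes_sig, sprintf("G%04d", seq_len(n_bg)))

    w <- exp(stats::rnorm(p$n_genes, 0, 1))
    # mitochondrial content of a healthy cell averages ~1.5% of the library
    mito_idx <- seq_len(p$mito_gene_count)
    w[mito_idx] <- w[mito_idx] / sum(w[mito_idx]) *
      0.015 / 0.985 * sum(w[-mito_idx])
    shift <- 2^p$signature_lfc
    w_epi <- w; w_epi[match(epi_sig, genes)] <- w_epi[match(epi_sig, genes)] * shift
    w_mes <- w; w_mes[match(mes_sig, genes)] <- w_mes[match(mes_sig, genes)] * shift
    prof <- cbind(epithelial = w_epi / sum(w_epi),
                  mesenchymal = w_mes / sum(w_mes))

    tp <- rep(p$timepoints, length.out = p$n_cells)
    epi_frac <- p$epithelial_fraction[match(tp, p$timepoints)]
    state <- ifelse(stats::runif(p$n_cells) < epi_frac,
                    "epithelial", "mesenchymal")
    lib <- stats::rlnorm(p$n_cells, log(p$mean_umi), 0.25)
    n_bad <- floor(p$frac_low_quality * p$n_cells)
    bad <- sample(p$n_cells, n_bad)
    bad_mode <- rep(c("low_umi", "high_mito"), length.out = n_bad)
    lib[bad[bad_mode == "low_umi"]] <- stats::runif(sum(bad_mode == "low_umi"),
                                                    200, 600)
    counts <- matrix(0L, p$n_genes, p$n_cells)
    size <- 1 / p$nb_dispersion
    for (j in seq_len(p$n_cells)) {
      pj <- prof[, state[j]]
      if (j %in% bad[bad_mode == "high_mito"]) {
        pj[mito_idx] <- pj[mito_idx] / sum(pj[mito_idx]) * 0.15
        pj[-mito_idx] <- pj[-mito_idx] / sum(pj[-mito_idx]) * 0.85
      }
      counts[, j] <- stats::rnbinom(p$n_genes, mu = lib[j] * pj, size = size)
    }
    dimnames(counts) <- list(genes, sprintf("CELL%05d", seq_len(p$n_cells)))
    ds <- sc_dataset(Matrix::Matrix(counts, sparse = TRUE),
                     timepoint = tp, state = state)
    truth <- list(
      cell_state = stats::setNames(state, colnames(counts)),
      qc_fail = stats::setNames(rep(NA_character_, p$n_cells), colnames(counts)),
      signatures = list(epithelial = epi_sig, mesenchymal = mes_sig),
      params = unclass(p)
    )
    truth$qc_fail[bad] <- bad_mode
    list(dataset = ds, truth = structure(truth, class = "ground_truth"))
  })
}

#' Parameters for the patient-cohort generator
#'
#' @param n_patients Number of patients.
#' @param target_gene Symbol of the prognostic target gene.
#' @param hazard_log_ratio Log hazard ratio per standard deviation of target
#'   expression (0 = no prognostic effect).
#' @param censor_rate Expected proportion of censored records in [0, 1).
#' @param marker_correlations Named vector of signed Spearman correlation
#'   targets between each marker and the target gene (|rho| <= 1).
#' @param n_background_genes Uncorrelated filler genes added to the matrix.
#' @param baseline_hazard Baseline exponential event rate.
#' @param seed Integer seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_patients = 300, target_gene = "ADAMTS6",
                              hazard_log_ratio = 1, censor_rate = 0.3,
                              marker_correlations = c(
                                CDH2 = 0.6, VIM = 0.6, FN1 = 0.5,
                                SNAI1 = 0.4, SNAI2 = 0.4, ZEB1 = 0.4,
                                ZEB2 = 0.4, TWIST1 = 0.4,
                                CDH1 = -0.5, EPCAM = -0.5,
                                OCLN = -0.4, KRT19 = -0.4),
                              n_background_genes = 50,
                              baseline_hazard = log(2) / 5, seed = 1) {
  p <- list(
    n_patients = check_count(n_patients, "n_patients", min = 4),
    target_gene = toupper(target_gene),
    hazard_log_ratio = check_number(hazard_log_ratio, "hazard_log_ratio"),
    censor_rate = check_number(censor_rate, "censor_rate",
                               lower = 0, upper = 1, open_upper = TRUE),
    marker_correlations = marker_correlations,
    n_background_genes = check_count(n_background_genes,
                                     "n_background_genes", min = 0),
    baseline_hazard = check_number(baseline_hazard, "baseline_hazard",
                                   lower = 0, open_lower = TRUE),
    seed = check_count(seed, "seed", min = 0)
  )
  if (is.null(names(marker_correlations)) ||
      anyNA(names(marker_correlations))) {
    stopf("marker_correlations must be a named vector")
  }
  if (any(abs(marker_correlations) > 1)) {
    stopf("correlation targets outside [-1, 1] give a non-positive-semidefinite copula")
  }
  names(p$marker_correlations) <- toupper(names(p$marker_correlations))
  structure(p, class = "cohort_sim_params")
}

#' Simulate a patient cohort with a prognostic target gene
#'
#' Expression of the target gene modulates an exponential hazard
#' (log-linear, per standard deviation of expression); censoring is
#' independent, with its rate solved so the expected censored fraction matches
#' `censor_rate`. Marker genes are generated through a single-factor Gaussian
#' copula so their Spearman correlation with the target matches the requested
#' signed values.
#'
#' @param params A [cohort_sim_params] object.
#' @return A list with `expression` (an [expr_matrix], group label
#'   `"tumor"`), `survival` (data.frame: `sample`, `time`, `event`) and
#'   `truth`.
#' @export
make_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  with_seed(p$seed, {
    n <- p$n_patients
    z <- stats::rnorm(n)
    # Pearson rho that yields the requested Spearman under a Gaussian copula
    rho_s <- p$marker_correlations
    rho_p <- 2 * sin(pi * rho_s / 6)
    markers <- vapply(rho_p, function(r) {
      r * z + sqrt(1 - r^2) * stats::rnorm(n)
    }, numeric(n))
    bg <- matrix(stats::rnorm(n * p$n_background_genes), p$n_background_genes, n)
    vals <- rbind(8 + 2 * z, 8 + 2 * t(markers), 8 + 2 * bg)
    rownames(vals) <- c(p$target_gene, names(rho_s),
                        if (p$n_background_genes > 0)
                          sprintf("BG%04d", seq_len(p$n_background_genes)))
    colnames(vals) <- sprintf("P%04d", seq_len(n))
    hz <- p$baseline_hazard * exp(p$hazard_log_ratio * z)
    t_event <- stats::rexp(n, hz)
    if (p$censor_rate > 0) {
      f <- function(log_hc) mean(exp(log_hc) / (exp(log_hc) + hz)) - p$censor_rate
      log_hc <- stats::uniroot(f, c(-20, 20))$root
      t_cens <- stats::rexp(n, exp(log_hc))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    surv <- data.frame(sample = colnames(vals), time = time, event = event,
                       stringsAsFactors = FALSE)
    truth <- list(latent_target = stats::setNames(z, colnames(vals)),
                  hazard_log_ratio = p$hazard_log_ratio,
                  marker_correlations = rho_s, params = unclass(p))
    list(expression = expr_matrix(vals, rep("tumor", n), log2_scale = TRUE),
         survival = surv,
         truth = structure(truth, class = "ground_truth"))
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>", paste(setdiff(names(x), "params"), collapse = ", "),
      "\n")
  invisible(x)
}
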