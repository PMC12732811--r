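# Pipeline orchestration: a single structured configuration (validated
# against documented defaults carrying the study's printed parameter values)
# and an end-to-end driver that runs simulate -> de -> hubs -> gsea -> sc ->
# cohort and writes every artifact plus a machine-readable run report.

pipeline_defaults <- function() {
  list(
    stages = list(simulate = TRUE, de = TRUE, hubs = TRUE, gsea = TRUE,
                  sc = TRUE, cohort = TRUE),
    de = list(min_abs_lfc = 1.5, max_q = 0.05, moderated = TRUE),
    verification = list(min_abs_lfc = 1.0, max_q = 0.05),
    pseudobulk = list(min_abs_lfc = 0.5, max_q = 0.05, n_replicates = 3),
    network = list(confidence_cutoff = 0.7),
    hubs = list(fraction = 0.15, min_networks = 3),
    gsea = list(min_size = 25, max_size = 500, n_perm = 1000, weight = 1,
                p_cutoff = 0.05),
    ssgsea = list(alpha = 0.25),
    qc = list(min_genes = 200, max_genes = 5000, min_umi = 1000,
              max_mito = 0.05),
    cluster = list(n_hvg = 2000, n_pcs = 50, neighbors_k = 20, resolution = 1),
    cohort = list(extreme_k = 20, target_gene = "ADAMTS6"),
    sim = list(n_datasets = 4, n_genes = 600, n_per_group = 5, n_de = 100,
               lfc_magnitude = 3, noise_sd = 0.5, n_nodes = 250, n_hubs = 5,
               hub_module_size = 15, background_attachment = 2,
               sc_n_cells = 600, sc_n_genes = 800, sc_frac_low_quality = 0.05,
               cohort_n_patients = 200, cohort_hazard_log_ratio = 1,
               cohort_censor_rate = 0.3),
    seeds = list(simulate = 11, epc = 12, gsea = 13, cluster = 14,
                 pseudobulk = 15)
  )
}

# Deterministic gene sets over the bulk universe, built from the study's
# planted truth: an EMT-like up-program, an epithelial program padded with
# unperturbed genes, and a null set of unperturbed genes.
bulk_truth_sets <- function(study) {
  panel <- emt_marker_panel()
  de1 <- study$truth$datasets[[1]]$de_genes
  up1 <- sort(de1$gene[de1$sign > 0])
  universe <- rownames(study$datasets[[1]]$values)
  non_de <- sort(setdiff(universe, de1$gene))
  mes <- panel$gene[panel$direction == "up"]
  epi <- panel$gene[panel$direction == "down"]
  list(
    EMT_UP_PROGRAM = utils::head(unique(c(mes, up1)), 60),
    EPITHELIAL_PROGRAM = utils::head(unique(c(epi, non_de)), 30),
    UNPERTURBED_SET = utils::head(non_de[-seq_len(30)], 30)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s",
          paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]])) {
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Fills defaults (the study's printed parameter values: DE thresholds
#' 1.5/0.05 discovery, 1.0 verification, 0.5 pseudobulk; confidence cutoff
#' 0.7; top fraction 0.15; 3-of-n network consensus; GSEA sizes 25-500 at
#' p < 0.05; the four QC bounds; 2000 HVGs / 50 PCs / resolution 1), rejects
#' unknown keys, and range-checks every field.
#'
#' @param source `NULL` (all defaults), a named list, or the path of a YAML
#'   file.
#' @return A normalized configuration of class `pipeline_config`.
#' @export
validate_config <- function(source = NULL) {
  user <- if (is.null(source)) {
    NULL
  } else if (is.character(source) && length(source) == 1) {
    yaml::read_yaml(source)
  } else if (is.list(source)) {
    source
  } else {
    stopf("config source must be NULL, a list, or a YAML file path")
  }
  cfg <- merge_config(pipeline_defaults(), user)
  check_number(cfg$de$min_abs_lfc, "de.min_abs_lfc", lower = 0)
  check_number(cfg$de$max_q, "de.max_q", lower = 0, upper = 1,
               open_lower = TRUE, open_upper = TRUE)
  check_number(cfg$network$confidence_cutoff, "network.confidence_cutoff",
               lower = 0, upper = 1, open_upper = TRUE)
  check_number(cfg$hubs$fraction, "hubs.fraction", lower = 0, upper = 1,
               open_lower = TRUE)
  check_count(cfg$hubs$min_networks, "hubs.min_networks")
  check_count(cfg$gsea$min_size, "gsea.min_size")
  check_count(cfg$gsea$max_size, "gsea.max_size")
  check_count(cfg$gsea$n_perm, "gsea.n_perm")
  check_number(cfg$gsea$p_cutoff, "gsea.p_cutoff", lower = 0, upper = 1,
               open_lower = TRUE)
  check_number(cfg$ssgsea$alpha, "ssgsea.alpha", lower = 0)
  qc_thresholds(cfg$qc$min_genes, cfg$qc$max_genes, cfg$qc$min_umi,
                cfg$qc$max_mito)
  cluster_options(cfg$cluster$n_hvg, cfg$cluster$n_pcs,
                  cfg$cluster$neighbors_k, cfg$cluster$resolution)
  for (s in names(cfg$seeds)) check_count(cfg$seeds[[s]], paste0("seeds.", s),
                                          min = 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the toggled stages on synthetic inputs generated from the
#' configuration: the multi-dataset hub study (simulate, de, hubs, gsea), the
#' single-cell stage (QC, clustering, classification, pseudobulk DE) and the
#' patient-cohort stage (correlations, extreme groups, median-split
#' survival). All artifacts are written under `out_dir`; rerunning with the
#' same configuration and seeds reproduces every artifact byte for byte
#' (wall-clock timings are returned but not serialized).
#'
#' @param config A [validate_config] result (or anything it accepts).
#' @param out_dir Output directory.
#' @return An object of class `run_report`.
#' @export
run_all <- function(config = NULL, out_dir = tempfile("emtnet_run_")) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  timings <- list()
  warnings <- list()
  note_stage <- function(name, counts, t0) {
    report[[name]] <<- counts
    timings[[name]] <<- as.numeric(proc.time()["elapsed"]) - t0
  }
  run_stage <- function(name, expr) {
    t0 <- as.numeric(proc.time()["elapsed"])
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stopf("stage '%s' failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        warnings[[name]] <<- c(warnings[[name]], conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(res = res, t0 = t0)
  }
  study <- NULL; sc <- NULL; cohort <- NULL; gene_sets <- NULL

  if (any(vapply(cfg$stages, isTRUE, logical(1)))) {
    st <- run_stage("simulate", {
      s <- cfg$sim
      study <- simulate_hub_study(
        n_datasets = s$n_datasets, n_genes = s$n_genes,
        n_per_group = s$n_per_group, n_de = s$n_de,
        lfc_magnitude = s$lfc_magnitude, noise_sd = s$noise_sd,
        n_nodes = s$n_nodes, n_hubs = s$n_hubs,
        hub_module_size = s$hub_module_size,
        background_attachment = s$background_attachment,
        seed = cfg$seeds$simulate)
      scr <- make_scrna(sc_sim_params(n_cells = s$sc_n_cells,
                                      n_genes = s$sc_n_genes,
                                      frac_low_quality = s$sc_frac_low_quality,
                                      seed = cfg$seeds$simulate + 1L))
      coh <- make_cohort(cohort_sim_params(
        n_patients = s$cohort_n_patients,
        hazard_log_ratio = s$cohort_hazard_log_ratio,
        censor_rate = s$cohort_censor_rate,
        target_gene = cfg$cohort$target_gene,
        seed = cfg$seeds$simulate + 2L))
      list(study = study, scr = scr, coh = coh)
    })
    study <- st$res$study; sc <- st$res$scr; cohort <- st$res$coh
    if (isTRUE(cfg$stages$simulate)) {
      sim_dir <- file.path(out_dir, "simulate")
      dir.create(sim_dir, showWarnings = FALSE)
      for (dn in names(study$datasets)) {
        write_expression_tsv(study$datasets[[dn]],
                             file.path(sim_dir, paste0(dn, "_expr.tsv")),
                             file.path(sim_dir, paste0(dn, "_groups.tsv")))
        write_edge_tsv(study$edges[[dn]],
                       file.path(sim_dir, paste0(dn, "_edges.tsv")))
      }
      sig <- sc$truth$signatures
      write_gmt(list(EPITHELIAL = sig$epithelial,
                     MESENCHYMAL = sig$mesenchymal,
                     HALLMARK_EMT = unique(c(sig$mesenchymal,
                                             sig$epithelial))),
                file.path(sim_dir, "gene_sets.gmt"))
      gene_sets <- bulk_truth_sets(study)
      write_gmt(gene_sets, file.path(sim_dir, "bulk_gene_sets.gmt"))
      write_mtx_bundle(sc$dataset, file.path(sim_dir, "scrna"))
      write_expression_tsv(cohort$expression,
                           file.path(sim_dir, "cohort_expr.tsv"))
      write_survival_tsv(cohort$survival,
                         file.path(sim_dir, "cohort_survival.tsv"))
      write_truth_json(study$truth, file.path(sim_dir, "truth_study.json"))
      write_truth_json(sc$truth, file.path(sim_dir, "truth_scrna.json"))
      note_stage("simulate",
                 list(datasets = length(study$datasets),
                      sc_cells = ncol(sc$dataset$counts),
                      cohort_patients = nrow(cohort$survival)), st$t0)
    }
  }

  de_results <- NULL
  if (isTRUE(cfg$stages$de)) {
    st <- run_stage("de", {
      thr <- de_thresholds(cfg$de$min_abs_lfc, cfg$de$max_q)
      de_results <- lapply(study$datasets, differential_expression,
                           moderated = isTRUE(cfg$de$moderated))
      degs <- lapply(de_results, select_degs, thresholds = thr)
      de_dir <- file.path(out_dir, "de")
      dir.create(de_dir, showWarnings = FALSE)
      for (dn in names(de_results)) {
        utils::write.table(format(de_results[[dn]], digits = 8),
                           file.path(de_dir, paste0(dn, "_de.tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      venn <- intersect_deg_sets(lapply(degs, `[[`, "gene"))
      jsonlite::write_json(venn$counts, file.path(de_dir, "venn.json"),
                           auto_unbox = TRUE)
      list(de = de_results, degs = degs)
    })
    de_results <- st$res$de
    note_stage("de", lapply(st$res$degs, nrow), st$t0)
  }

  hd <- NULL
  if (isTRUE(cfg$stages$hubs)) {
    st <- run_stage("hubs", {
      hcfg <- hub_discovery_config(
        de_thresholds = de_thresholds(cfg$de$min_abs_lfc, cfg$de$max_q),
        confidence_cutoff = cfg$network$confidence_cutoff,
        fraction = cfg$hubs$fraction, min_networks = cfg$hubs$min_networks,
        moderated = isTRUE(cfg$de$moderated),
        centrality_options = centrality_options(epc_seed = cfg$seeds$epc))
      hd <- run_hub_discovery(study$datasets, study$edges, hcfg)
      hub_dir <- file.path(out_dir, "hubs")
      dir.create(hub_dir, showWarnings = FALSE)
      write_consensus_tsv(hd, file.path(hub_dir, "consensus.tsv"))
      jsonlite::write_json(hd$report, file.path(hub_dir, "provenance.json"),
                           auto_unbox = TRUE)
      hd
    })
    hd <- st$res
    note_stage("hubs", list(consensus = length(hd$consensus$consensus)), st$t0)
  }

  if (isTRUE(cfg$stages$gsea)) {
    st <- run_stage("gsea", {
      if (is.null(de_results)) {
        de_results <- lapply(study$datasets, differential_expression,
                             moderated = isTRUE(cfg$de$moderated))
      }
      d1 <- de_results[[1]]
      rl <- ranked_list(d1$gene, d1$log2FC)
      if (is.null(gene_sets)) gene_sets <- bulk_truth_sets(study)
      er <- gsea_collection(rl, gene_sets, min_size = cfg$gsea$min_size,
                            max_size = cfg$gsea$max_size,
                            weight = cfg$gsea$weight,
                            n_perm = cfg$gsea$n_perm, seed = cfg$seeds$gsea,
                            p_cutoff = cfg$gsea$p_cutoff)
      gsea_dir <- file.path(out_dir, "gsea")
      dir.create(gsea_dir, showWarnings = FALSE)
      utils::write.table(format(as.data.frame(er), digits = 8),
                         file.path(gsea_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      er
    })
    note_stage("gsea", list(sets_tested = nrow(st$res)), st$t0)
  }

  if (isTRUE(cfg$stages$sc)) {
    st <- run_stage("sc", {
      if (is.null(sc)) stopf("single-cell stage requires the simulate stage")
      thr <- qc_thresholds(cfg$qc$min_genes, cfg$qc$max_genes,
                           cfg$qc$min_umi, cfg$qc$max_mito)
      copt <- cluster_options(cfg$cluster$n_hvg, cfg$cluster$n_pcs,
                              cfg$cluster$neighbors_k, cfg$cluster$resolution,
                              seed = cfg$seeds$cluster)
      ds <- qc_filter(sc$dataset, thr)
      ds <- normalize_and_hvg(ds, copt)
      ds <- embed_and_cluster(ds, copt)
      sig <- sc$truth$signatures
      cls <- classify_clusters(ds, sig$epithelial, sig$mesenchymal,
                               unique(c(sig$mesenchymal, sig$epithelial)),
                               alpha = cfg$ssgsea$alpha)
      ds$meta$state_call <- unname(cls$cell_states[ds$meta$barcode])
      pb <- pseudobulk_de(ds, thresholds = de_thresholds(
        cfg$pseudobulk$min_abs_lfc, cfg$pseudobulk$max_q),
        n_replicates = cfg$pseudobulk$n_replicates,
        seed = cfg$seeds$pseudobulk)
      sc_dir <- file.path(out_dir, "sc")
      dir.create(sc_dir, showWarnings = FALSE)
      utils::write.table(
        data.frame(barcode = ds$meta$barcode, cluster = ds$meta$cluster,
                   state = ds$meta$state_call),
        file.path(sc_dir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(format(cls$cluster_states, digits = 8),
                         file.path(sc_dir, "cluster_states.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(format(pb$de, digits = 8),
                         file.path(sc_dir, "pseudobulk_de.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(ds = ds, cls = cls, pb = pb)
    })
    note_stage("sc", list(cells_kept = ncol(st$res$ds$counts),
                          clusters = length(unique(st$res$ds$meta$cluster)),
                          pseudobulk_degs = nrow(st$res$pb$selected)), st$t0)
  }

  if (isTRUE(cfg$stages$cohort)) {
    st <- run_stage("cohort", {
      if (is.null(cohort)) stopf("cohort stage requires the simulate stage")
      target <- cfg$cohort$target_gene
      markers <- names(cohort$truth$marker_correlations)
      ct <- marker_correlations(cohort$expression, target, markers)
      grp <- median_split(cohort$expression, target)
      stab <- cohort$survival
      stab$group <- unname(grp[stab$sample])
      km <- km_logrank(stab)
      ext <- extreme_groups(cohort$expression, target,
                            k = cfg$cohort$extreme_k)
      co_dir <- file.path(out_dir, "cohort")
      dir.create(co_dir, showWarnings = FALSE)
      utils::write.table(format(as.data.frame(ct), digits = 8),
                         file.path(co_dir, "correlations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(format(km$curves, digits = 8),
                         file.path(co_dir, "km_curves.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(logrank_chisq = km$chisq, logrank_p = km$p,
             n_high = sum(grp == "high"), n_low = sum(grp == "low"),
             extreme_high = ext$high, extreme_low = ext$low),
        file.path(co_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
      km
    })
    note_stage("cohort", list(logrank_p = st$res$p), st$t0)
  }

  out <- structure(list(stages = report, warnings = warnings,
                        timings = timings, config = unclass(cfg),
                        out_dir = out_dir),
                   class = "run_report")
  # the serialized report omits timings so reruns are byte-identical
  jsonlite::write_json(list(stages = report, warnings = warnings,
                            config = unclass(cfg)),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>", x$out_dir, "\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-9s %5.1fs  %s\n", s, x$timings[[s]],
                paste(names(x$stages[[s]]),
                      vapply(x$stages[[s]], function(v) paste(format(v), collapse = "/"),
                             character(1)),
                      sep = "=", collapse = ", ")))
  }
  if (length(x$warnings)) {
    cat("warnings in stages:", paste(names(x$warnings), collapse = ", "), "\n")
  }
  invisible(x)
}
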