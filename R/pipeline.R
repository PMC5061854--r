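#' Run the full analysis pipeline
#'
#' Executes the six stages in order — contamination classification, SAD
#' core/satellite partitioning, association filtering, C-score null-model
#' validation, network assembly/module detection/topology, and module
#' eigengene/environment correlation plus PERMANOVA — writing per-stage
#' TSV/GraphML outputs and a machine-readable JSON run manifest (seed,
#' thresholds, completed stages) to `out_dir`. Any stage failure aborts with
#' the stage name and cause.
#'
#' @param table an [abundance_table()].
#' @param metadata sample metadata data.frame.
#' @param taxonomy optional taxonomy data.frame.
#' @param config a [benthonet_config()].
#' @param out_dir output directory (created if needed).
#' @param permanova_terms predictors for the PERMANOVA stage.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(table, metadata, taxonomy = NULL,
                         config = benthonet_config(), out_dir,
                         permanova_terms = c("salinity", "fluoranthene")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  res <- list()
  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    stages <<- c(stages, name)
    out
  }

  res$contamination <- run_stage("contamination", {
    call <- classify_sites_hac(metadata, config)
    write.table(call$calls, file.path(out_dir, "contamination_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    call
  })

  res$sad <- run_stage("sad_partition", {
    part <- partition_sad(table, config)
    write.table(part$records, file.path(out_dir, "sad_partition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    part
  })

  core_tab <- abundance_table(
    unclass(table)[core_otus(res$sad), , drop = FALSE])

  res$edges <- run_stage("association", {
    ed <- edge_table(core_tab, config)
    write.table(as.data.frame(ed), file.path(out_dir, "edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    ed
  })

  res$nullmodel <- run_stage("nullmodels", {
    otus <- attr(res$edges, "tested_otus")
    sub <- if (!is.null(otus) && length(otus) >= 2)
      unclass(core_tab)[otus, , drop = FALSE] else unclass(core_tab)
    rep <- ses_cscore(sub, n_null = config$n_null_matrices,
                      algorithm = config$null_algorithm,
                      seed = config$random_seed)
    jsonlite::write_json(unclass(rep), file.path(out_dir, "nullmodel.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })

  res$network <- run_stage("network", {
    net <- build_network(res$edges, taxonomy)
    if (nrow(net$edges) > 0) {
      net <- detect_modules(net, seed = config$random_seed)
      write_network(net, file.path(out_dir, "network.graphml"), "graphml")
      write_network(net, file.path(out_dir, "edges_export.tsv"),
                    "edge_list_tsv")
    }
    topo <- network_topology(net)
    jsonlite::write_json(unclass(topo), file.path(out_dir, "topology.json"),
                         auto_unbox = TRUE, digits = NA)
    list(net = net, topology = topo)
  })

  res$module_env <- run_stage("module_env", {
    out <- list()
    net <- res$network$net
    if (!is.null(net$modules)) {
      eg <- module_eigengenes(core_tab, net)
      out$eigengenes <- eg
      if (length(eg) > 0) {
        ec <- correlate_env(eg, metadata, transforms = config$transforms)
        write.table(ec, file.path(out_dir, "env_corr.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        out$env_corr <- ec
      }
    }
    d <- community_distance(core_tab)
    pm <- permanova(as.matrix(d), metadata, permanova_terms,
                    n_perm = config$permutations,
                    seed = config$random_seed,
                    transforms = config$transforms)
    write.table(as.data.frame(pm), file.path(out_dir, "permanova.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$permanova <- pm
    out
  })

  manifest <- list(
    package = "benthonet",
    version = as.character(utils::packageVersion("benthonet")),
    seed = config$random_seed,
    thresholds = list(rho = config$rho_edge_threshold,
                      p = config$p_edge_threshold,
                      prevalence = config$prevalence_min_fraction,
                      n_null = config$n_null_matrices,
                      null_algorithm = config$null_algorithm,
                      chi2 = c(config$chi2_lower, config$chi2_upper),
                      df_convention = config$df_convention,
                      collinearity = config$collinearity_threshold,
                      permutations = config$permutations,
                      hac_linkage = config$hac_linkage,
                      hac_transform = config$hac_transform),
    stages_completed = stages,
    n_otus = nrow(table), n_samples = ncol(table))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
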