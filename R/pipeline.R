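# Pipeline orchestration: a validated configuration object, a staged runner
# writing every intermediate table under one run directory, and a JSON
# manifest capturing seeds, thresholds and per-stage record counts.

#' Default pipeline configuration
#'
#' Builds a full configuration list with the pipeline's default thresholds
#' (fold change 1.2, DE alpha 0.05 on the adjusted p, deconvolution gate
#' 0.05, correlation gates 0.3/0.05, hypergeometric gate 0.01, co-expression
#' gates 0.3/0.01), all stages enabled, and a synthetic demo cohort as the
#' input source. Any field can be overridden via `...` (nested lists are
#' merged shallowly per top-level field).
#'
#' @param output_dir Run directory (created on demand).
#' @param seed Master seed; all stage seeds derive from it.
#' @param ... Top-level overrides, e.g. `stages = list(cerna = FALSE)` or
#'   `inputs = list(expression = "expr.tsv", metadata = "meta.tsv", ...)`.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("cuprosep_run_"),
                            seed = 1, ...) {
  cfg <- list(
    output_dir = output_dir,
    seed = as.integer(seed),
    stages = list(preprocess = TRUE, select = TRUE, immune = TRUE,
                  cluster = TRUE, cerna = TRUE, roc = TRUE),
    thresholds = list(fc_threshold = 1.2, de_alpha = 0.05,
                      deconv_alpha = 0.05, corr_min = 0.3, corr_alpha = 0.05,
                      hyper_alpha = 0.01, pcc_min = 0.3, pcc_alpha = 0.01),
    cluster = list(k_range = 2:6, H = 200, p_item = 0.8),
    inputs = list(simulate = list(n_case = 60, n_control = 40,
                                  n_genes = 1000))
  )
  dots <- list(...)
  for (nm in names(dots)) {
    # stages/thresholds/cluster merge field-wise; anything else (notably
    # `inputs`) replaces the default outright
    cfg[[nm]] <- if (nm %in% c("stages", "thresholds", "cluster"))
      utils::modifyList(cfg[[nm]], as.list(dots[[nm]])) else dots[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  structure(cfg, class = c("pipeline_config", "list"))
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$fc_threshold > 1,
            th$de_alpha > 0, th$de_alpha < 1,
            th$deconv_alpha > 0, th$deconv_alpha < 1,
            th$hyper_alpha > 0, th$hyper_alpha < 1,
            th$pcc_min >= -1, th$pcc_min <= 1,
            th$pcc_alpha > 0, th$pcc_alpha < 1)
  if (is.null(cfg$inputs$simulate)) {
    needed <- c("expression", "metadata")
    for (f in needed)
      if (is.null(cfg$inputs[[f]]))
        stop(sprintf("config inputs must provide `%s` (or a `simulate` block)", f))
    for (f in setdiff(names(cfg$inputs), "simulate")) {
      p <- cfg$inputs[[f]]
      if (is.character(p) && !file.exists(p))
        stop(sprintf("input file for `%s` not found: %s", f, p))
    }
  }
  invisible(cfg)
}

#' Load a pipeline configuration from YAML (or JSON)
#'
#' @param path Path to a YAML file (JSON is a subset of YAML and is
#'   accepted).
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order — preprocess (merge +
#' batch correction + differential expression + panel intersection), dual
#' machine-learning biomarker selection, then the four downstream analyses
#' (immune correlation, consensus subtyping, ceRNA network, ROC) — writing
#' every intermediate table as TSV under `config$output_dir` and a
#' `manifest.json` recording the package version, the configuration hash,
#' seeds, thresholds, per-stage status and record counts. Rerunning with an
#' identical configuration reproduces identical table outputs.
#'
#' With a `simulate` input block the synthetic generator provides all inputs
#' (and the simulated truth is written alongside, so a run is self-scoring);
#' with file inputs the corresponding readers are used. Missing inputs fail
#' validation before any stage executes.
#'
#' @param config A `pipeline_config`, a plain list of overrides, or a path
#'   to a YAML/JSON config file.
#' @return The manifest (invisibly), a list also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- do.call(pipeline_config, config)
  validate_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  seed <- config$seed
  manifest <- list(package_version = as.character(utils::packageVersion("cuprosep")),
                   config_hash = rlang::hash(unclass(config)),
                   seed = seed, thresholds = th, stages = list())
  note <- function(stage, status, counts = list()) {
    manifest$stages[[stage]] <<- c(list(status = status), counts)
    message(sprintf("[%s] %s %s", stage, status,
                    paste(sprintf("%s=%s", names(counts), unlist(counts)),
                          collapse = " ")))
  }

  # ---- inputs ---------------------------------------------------------
  sim_truth <- NULL
  if (!is.null(config$inputs$simulate)) {
    sim_args <- utils::modifyList(list(seed = seed), config$inputs$simulate)
    sim <- do.call(simulate_cohort, sim_args)
    expr_raw <- sim$expr; sim_truth <- sim$truth
    panel <- sim$truth$panel_genes
    fr <- simulate_fractions(
      n_samples = sum(expr_raw$samples$group == "case"),
      linked_gene_values = if (length(sim_truth$key_genes) > 0)
        expr_raw$values[sim_truth$key_genes[1],
                        expr_raw$samples$group == "case"] else NULL,
      link_strength = 0.8, seed = seed + 1)
    rownames(fr) <- expr_raw$samples$sample_id[expr_raw$samples$group == "case"]
    si <- simulate_interactions(n_mirna = 200, n_mrna = 30, n_lncrna = 30,
                                planted_pairs = 5, shared_per_planted = 20,
                                background_rate = 0.02, seed = seed + 2)
    write_expression(expr_raw, file.path(config$output_dir, "input_expression.tsv"),
                     file.path(config$output_dir, "input_metadata.tsv"))
    write_gmt(list(panel = panel), file.path(config$output_dir, "input_panel.gmt"))
    note("inputs", "simulated",
         list(samples = ncol(expr_raw$values), genes = nrow(expr_raw$values)))
  } else {
    expr_raw <- read_expression(config$inputs$expression,
                                config$inputs$metadata)
    panel <- if (!is.null(config$inputs$panel))
      read_panel(config$inputs$panel) else rownames(expr_raw$values)
    fr <- if (!is.null(config$inputs$fractions))
      read_fractions(config$inputs$fractions) else NULL
    si <- if (!is.null(config$inputs$mrna_mirna) &&
              !is.null(config$inputs$lncrna_mirna))
      list(mrna_mirna = read_interactions(config$inputs$mrna_mirna),
           lncrna_mirna = read_interactions(config$inputs$lncrna_mirna),
           expression = expr_raw) else NULL
    note("inputs", "loaded", list(samples = ncol(expr_raw$values)))
  }

  # ---- preprocess -----------------------------------------------------
  expr <- merge_and_correct(expr_raw)
  de <- differential_expression(expr, fc_threshold = th$fc_threshold,
                                alpha = th$de_alpha)
  decug <- intersect_panel(de, panel)
  write_tsv(de, file.path(config$output_dir, "de_results.tsv"))
  writeLines(decug, file.path(config$output_dir, "panel_de_genes.txt"))
  note("preprocess", "complete",
       list(de_genes = sum(de$is_de), panel_de_genes = length(decug)))
  if (length(decug) < 2) {
    note("select", "skipped (fewer than 2 panel DE genes)")
    manifest_path <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
    return(invisible(manifest))
  }

  # ---- feature selection ----------------------------------------------
  key_genes <- decug
  if (isTRUE(config$stages$select)) {
    sel <- select_biomarkers(expr, decug, seed = seed)
    key_genes <- sel$key_genes
    jsonlite::write_json(
      list(lasso = list(selected = sel$lasso$selected,
                        lambda = sel$lasso$lambda),
           svmrfe = list(ranking = sel$svmrfe$ranking,
                         selected = sel$svmrfe$selected),
           key_genes = key_genes),
      file.path(config$output_dir, "selection.json"), auto_unbox = TRUE)
    write_tsv(data.frame(rank = seq_along(sel$svmrfe$ranking),
                         gene = sel$svmrfe$ranking),
              file.path(config$output_dir, "svmrfe_ranking.tsv"))
    note("select", "complete", list(lasso = length(sel$lasso$selected),
                                    svmrfe = length(sel$svmrfe$selected),
                                    key_genes = length(key_genes)))
  }
  if (length(key_genes) == 0) key_genes <- decug

  case_idx <- expr$samples$group == "case"
  # ---- immune correlation ---------------------------------------------
  if (isTRUE(config$stages$immune) && !is.null(fr)) {
    fr_ok <- filter_samples(fr, th$deconv_alpha)
    corr <- gene_cell_correlations(expr, key_genes, fr_ok, cohort = "case")
    write_tsv(corr, file.path(config$output_dir, "immune_correlations.tsv"))
    note("immune", "complete",
         list(samples_kept = nrow(fr_ok),
              significant = sum(corr$p_adj < th$corr_alpha &
                                  abs(corr$rho) > th$corr_min, na.rm = TRUE)))
  } else note("immune", "skipped")

  # ---- consensus clustering -------------------------------------------
  cluster_labels <- NULL
  if (isTRUE(config$stages$cluster) &&
      sum(case_idx) >= 2 * max(config$cluster$k_range)) {
    Xc <- t(expr$values[key_genes, case_idx, drop = FALSE])
    cres <- consensus_cluster(Xc, k_range = config$cluster$k_range,
                              H = config$cluster$H,
                              p_item = config$cluster$p_item, seed = seed)
    cluster_labels <- cres$labels
    write_tsv(data.frame(sample_id = names(cres$labels),
                         cluster = cres$labels),
              file.path(config$output_dir, "cluster_labels.tsv"))
    write_tsv(data.frame(k = as.integer(names(cres$area)), area = cres$area,
                         delta_area = cres$delta_area),
              file.path(config$output_dir, "cluster_delta_area.tsv"))
    if (cres$chosen_k == 2) {
      contrast <- subcluster_contrast(subset_samples(expr, case_idx),
                                      cres$labels, key_genes)
      write_tsv(contrast, file.path(config$output_dir,
                                    "subcluster_contrast.tsv"))
    }
    note("cluster", "complete",
         list(chosen_k = cres$chosen_k,
              sizes = paste(table(cres$labels), collapse = "/")))
  } else note("cluster", "skipped")

  # ---- ceRNA network --------------------------------------------------
  if (isTRUE(config$stages$cerna) && !is.null(si)) {
    # gate the mRNA side by the cohort's key genes where they overlap the
    # interaction data; otherwise test every interaction-table mRNA
    cerna_keys <- intersect(key_genes, unique(si$mrna_mirna$target_id))
    if (length(cerna_keys) == 0) cerna_keys <- unique(si$mrna_mirna$target_id)
    net <- build_cerna_network(si$mrna_mirna, si$lncrna_mirna,
                               si$expression, key_genes = cerna_keys,
                               alpha_hyper = th$hyper_alpha,
                               pcc_min = th$pcc_min,
                               alpha_pcc = th$pcc_alpha)
    write_tsv(net$candidates, file.path(config$output_dir,
                                        "cerna_candidates.tsv"))
    write_tsv(net$network$nodes, file.path(config$output_dir,
                                           "cerna_nodes.tsv"))
    if (igraph::vcount(net$network$graph) > 0)
      write_network_graphml(net$network,
                            file.path(config$output_dir, "cerna_network.graphml"))
    hubs <- rank_hubs(net$network)
    write_tsv(hubs, file.path(config$output_dir, "cerna_hubs.tsv"))
    note("cerna", "complete",
         list(candidates = nrow(net$candidates),
              retained = sum(net$candidates$retained),
              nodes = nrow(net$network$nodes)))
  } else note("cerna", "skipped")

  # ---- diagnostics ----------------------------------------------------
  if (isTRUE(config$stages$roc)) {
    pr <- panel_roc(expr, key_genes)
    write_tsv(pr$per_gene, file.path(config$output_dir, "roc_auc.tsv"))
    jsonlite::write_json(
      c(as.list(stats::setNames(pr$per_gene$auc, pr$per_gene$gene)),
        list(combined = pr$combined$auc)),
      file.path(config$output_dir, "auc_summary.json"), auto_unbox = TRUE)
    note("roc", "complete",
         list(best_gene = pr$per_gene$gene[which.max(pr$per_gene$auc)],
              combined_auc = round(pr$combined$auc, 3)))
  } else note("roc", "skipped")

  if (!is.null(sim_truth))
    manifest$truth <- list(de_genes = length(sim_truth$de_genes),
                           key_genes = sim_truth$key_genes)
  manifest$key_genes <- key_genes
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
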