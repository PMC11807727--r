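# Orchestration: configuration, input validation, and the end-to-end run
# tying the stages together in the discovery order — coexpression modules ->
# reference-module enrichment -> PPI subnetwork and hubs -> differential
# expression -> overlay -> ORA -> phenotype correlation -> prioritization.

#' Pipeline configuration
#'
#' Flat list of input paths and stage thresholds. Every threshold is echoed
#' into the run manifest so the run record shows each cutoff in force.
#'
#' @param input_dir directory holding the standard input files (see
#'   [write_synthetic_fixture()] for the layout); individual paths may be
#'   overridden.
#' @param out_dir output directory for stage tables and the manifest.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @param ... overrides for any default below.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, out_dir = file.path(input_dir, "out"),
                            seed = 1, ...) {
  cfg <- list(
    expr_path = file.path(input_dir, "expression.tsv"),
    reference_gmt = file.path(input_dir, "reference.gmt"),
    edges_path = file.path(input_dir, "interactions.tsv"),
    counts_path = file.path(input_dir, "counts.tsv"),
    groups_path = file.path(input_dir, "groups.tsv"),
    panel_dir = file.path(input_dir, "panels"),
    gwas_path = file.path(input_dir, "gwas.tsv"),
    pathways_gmt = file.path(input_dir, "pathways.gmt"),
    tf_gmt = file.path(input_dir, "tf_targets.gmt"),
    out_dir = out_dir, seed = seed,
    # coexpression
    outlier_height = Inf, n_top = Inf, beta = NA, r2_target = 0.8,
    min_module_size = 50, cut_quantile = 0.4, merge_height = 0.25,
    # enrichment
    module_fdr = 0.05, ora_min_genes = 5, ora_fdr = 0.1, tf_p = 0.05,
    kappa_threshold = 0.3,
    # ppi
    score_threshold = 0.7,
    # differential expression
    de_fc = 1.5, de_fdr = 0.05,
    # phenotype correlation
    corr_alpha = 0.05,
    # shortlist
    min_degree = 4, min_fc = 2, max_fdr = 0.05, min_gwas = 1, min_regions = 4
  )
  override <- list(...)
  cfg[names(override)] <- override
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Validate pipeline inputs before running
#'
#' Checks that all files exist and that the gene identifier spaces overlap
#' across them (expression vs reference vs edges vs counts vs panels vs GWAS
#' table), reporting per-file gene counts and intersection sizes. An empty
#' intersection between the expression genes and the reference set is a hard
#' error.
#'
#' @param config a [pipeline_config()].
#' @return tibble: source, n_genes, n_in_expression.
#' @export
validate_inputs <- function(config) {
  paths <- config[c("expr_path", "reference_gmt", "edges_path", "counts_path",
                    "groups_path", "gwas_path")]
  missing <- unlist(paths)[!file.exists(unlist(paths))]
  if (length(missing)) {
    pmn_abort(sprintf("missing input file(s): %s",
                      paste(missing, collapse = ", ")))
  }
  expr_genes <- rownames(read_expression_tsv(config$expr_path))
  ref <- unique(unlist(read_gmt(config$reference_gmt)$sets))
  edges <- read_interactions_tsv(config$edges_path)
  edge_genes <- unique(c(edges$protein_a, edges$protein_b))
  count_genes <- rownames(read_counts_tsv(config$counts_path,
                                          config$groups_path)$counts)
  gwas_genes <- unique(read_associations_tsv(config$gwas_path)$gene)
  panel_genes <- unique(unlist(lapply(read_panel_dir(config$panel_dir),
                                      function(p) rownames(p$expression))))
  sets <- list(expression = expr_genes, reference = ref, edges = edge_genes,
               counts = count_genes, gwas = gwas_genes, panels = panel_genes)
  report <- tibble::tibble(
    source = names(sets),
    n_genes = lengths(sets),
    n_in_expression = vapply(sets, function(s)
      length(intersect(s, expr_genes)), integer(1)))
  if (length(intersect(ref, expr_genes)) == 0) {
    pmn_abort(paste("reference set and expression genes are disjoint;",
                    "check identifier spaces or supply a mapping"))
  }
  report
}

#' Run the full discovery pipeline
#'
#' Executes every stage on the configured inputs, writes one TSV per stage
#' under `out_dir` plus a `manifest.json` (config echo, config hash, seed,
#' per-stage row counts), and returns the stage results. Deterministic:
#' identical inputs and config give byte-identical output tables. Any stage
#' failure aborts with the stage name; tables written so far are preserved.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of stage results: assignment, scan, enrichment,
#'   pain_module, subnetwork, hub_ranks, de, degs, overlay_n, ora_pathway,
#'   ora_tf, term_network, correlations, corr_counts, pan_region, candidates,
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  counts_written <- list()
  emit <- function(tbl, name) {
    write_table_tsv(tbl, file.path(config$out_dir, paste0(name, ".tsv")))
    counts_written[[name]] <<- nrow(as.data.frame(tbl))
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      pmn_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                class = "painmodnet_stage_error")
    })
  }

  ## coexpression
  assignment <- NULL; expr <- NULL; scan <- NULL
  stage("coexpress", {
    expr0 <- read_expression_tsv(config$expr_path)
    kept <- remove_outlier_samples(expr0, config$outlier_height)
    expr <- select_top_genes(kept$expr, config$n_top)
    beta <- config$beta
    if (is.na(beta)) {
      scan <- pick_soft_threshold(expr, r2_target = config$r2_target)
      beta <- scan$chosen_power
      emit(scan$scan, "soft_threshold_scan")
    }
    tomx <- tom_from_expression(expr, beta)
    pre <- detect_modules(tomx, config$min_module_size, config$cut_quantile)
    assignment <- merge_close_modules(expr, pre, config$merge_height)
    emit(tibble::tibble(gene = names(assignment$labels),
                        premerge_label = unname(pre$labels),
                        merged_label = unname(assignment$labels),
                        color = unname(module_colors(assignment$labels))),
         "module_assignment")
    emit(tibble::tibble(module = rownames(assignment$eigengenes),
                        as.data.frame(assignment$eigengenes)),
         "eigengenes")
  })

  ## reference-set module enrichment -> pain module
  reference <- NULL; enrichment <- NULL; pain_module <- NULL
  stage("enrich_module", {
    reference <- unique(unlist(read_gmt(config$reference_gmt)$sets))
    enrichment <- hypergeom_module_enrichment(assignment, reference)
    over <- enrichment[enrichment$direction == "over" &
                         enrichment$fdr < config$module_fdr, , drop = FALSE]
    pain_module <- if (nrow(over)) over$module[1] else enrichment$module[1]
    emit(enrichment, "module_enrichment")
  })
  module_genes <- names(assignment$labels)[assignment$labels == pain_module]

  ## PPI subnetwork and hubs (restricted to the selected module's genes)
  subnet <- NULL; hub_ranks <- NULL
  stage("ppi", {
    g <- load_interactions(read_interactions_tsv(config$edges_path),
                           config$score_threshold)
    keep <- intersect(igraph::V(g)$name, module_genes)
    g <- igraph::induced_subgraph(g, keep)
    subnet <- extract_reference_subnetwork(g, reference)
    hub_ranks <- dplyr::bind_rows(rank_hubs(subnet, "degree"),
                                   rank_hubs(subnet, "mnc"))
    emit(hub_ranks, "hub_ranks")
  })

  ## differential expression
  de <- NULL; degs <- NULL
  stage("diffexpr", {
    cd <- read_counts_tsv(config$counts_path, config$groups_path)
    fac <- tmm_factors(cd$counts)
    disp <- estimate_dispersion(cd$counts, cd$groups, factors = fac)
    de <- nb_exact_test(cd$counts, cd$groups, dispersions = disp,
                         factors = fac)
    degs <- filter_degs(de, config$de_fc, config$de_fdr)
    emit(de, "differential_expression")
  })

  ## overlay DE on the subnetwork
  overlay_n <- NULL
  stage("overlay", {
    subnet <- overlay_de(subnet, de, config$de_fc, config$de_fdr)
    overlay_n <- igraph::graph_attr(subnet, "n_de")
    tabs <- graph_tables(subnet)
    emit(tabs$nodes, "subnetwork_nodes")
    emit(tabs$edges, "subnetwork_edges")
  })

  ## over-representation of the module genes (pathway + TF modes)
  ora_pathway <- NULL; ora_tf <- NULL; term_network <- NULL
  stage("enrich_ora", {
    universe <- names(assignment$labels)
    if (file.exists(config$pathways_gmt)) {
      pw <- read_gmt(config$pathways_gmt)
      ora_pathway <- ora(module_genes, pw, universe,
                          min_genes_per_set = config$ora_min_genes,
                          mode = "pathway", fdr_threshold = config$ora_fdr)
      term_network <- kappa_term_network(ora_pathway, pw, universe,
                                          config$kappa_threshold)
      emit(ora_pathway, "ora_pathway")
      emit(term_network$clusters, "term_clusters")
    }
    if (file.exists(config$tf_gmt)) {
      ora_tf <- ora(module_genes, read_gmt(config$tf_gmt), universe,
                     min_genes_per_set = config$ora_min_genes,
                     mode = "tf", p_threshold = config$tf_p)
      emit(ora_tf, "ora_tf")
    }
  })

  ## phenotype correlation screen over the subnetwork genes
  correlations <- NULL; corr_counts <- NULL
  stage("phenocorr", {
    panels <- read_panel_dir(config$panel_dir)
    screen_genes <- intersect(igraph::V(subnet)$name,
                              rownames(panels[[1]]$expression))
    correlations <- correlate_panels(panels, genes = screen_genes,
                                      alpha = config$corr_alpha)
    corr_counts <- count_significant(correlations)
    emit(correlations, "phenotype_correlations")
    emit(corr_counts$per_gene, "region_counts")
  })

  ## prioritization
  candidates <- NULL
  stage("prioritize", {
    gwas <- filter_gwas(read_associations_tsv(config$gwas_path))
    nodes <- graph_tables(subnet)$nodes
    candidates <- shortlist_candidates(
      nodes, de, gwas, corr_counts$per_gene,
      thresholds = shortlist_thresholds(config$min_degree, config$min_fc,
                                        config$max_fdr, config$min_gwas,
                                        config$min_regions))
    candidates <- direction_consistency(candidates,
                                         sign_balance(correlations)$overall)
    candidates <- annotate_reference(candidates, reference)
    emit(candidates, "candidates")
  })

  cfg_echo <- config[setdiff(names(unclass(config)), "out_dir")]
  manifest <- list(
    seed = config$seed,
    config = cfg_echo,
    config_hash = rlang::hash(cfg_echo[sort(names(cfg_echo))]),
    n_up = length(degs$up), n_down = length(degs$down),
    pain_module = pain_module, overlay_n = overlay_n,
    n_shortlisted = sum(candidates$shortlist),
    stage_rows = counts_written)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(assignment = assignment, scan = scan,
                 enrichment = enrichment, pain_module = pain_module,
                 subnetwork = subnet, hub_ranks = hub_ranks, de = de,
                 degs = degs, overlay_n = overlay_n,
                 ora_pathway = ora_pathway, ora_tf = ora_tf,
                 term_network = term_network, correlations = correlations,
                 corr_counts = corr_counts,
                 pan_region = pan_region_genes(correlations,
                                               min(config$min_regions,
                                                   length(unique(correlations$region)))),
                 candidates = candidates, manifest = manifest))
}
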