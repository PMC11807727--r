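# The default synthetic study: one preset describing every generator's
# parameters, and a writer that materializes a complete fixture directory
# (expression, reference GMT, interactions, counts, panels, GWAS table,
# pathway and TF-target collections) plus a ground-truth JSON.

#' Default synthetic study preset
#'
#' The parameter set the package's recovery experiments are run under:
#' 2000 genes x 60 samples with four planted modules (300/200/150/100) at
#' factor loading 0.8 and noise sd 0.6; a reference set of 40 module-1 genes
#' plus 60 background genes; an interaction graph over the module-1 genes
#' (mean degree 4) whose planted candidates and a fifth of the reference
#' genes are degree-boosted, scores drawn in \[0.7, 1\] (a high-confidence
#' export, so the load threshold keeps everything); NB counts for all genes,
#' 3 vs 3 at dispersion 0.1, with fold-change tiers of |log2FC| 1/2/4 planted
#' on background genes and strong |log2FC| 4-6.5 on the six candidates (two
#' of which sit in the reference set); 8 brain-region panels of 27-69 strains
#' with 31 phenotypes, candidates planted at |rho| = 0.7 in four phenotypes
#' per region in all 8 regions, signs matching their fold-change direction;
#' and a PheWAS-style table over module-1 genes and 6 pain-trait categories
#' with planted p below 1e-4.
#'
#' @return named list of preset parameters.
#' @export
synth_preset <- function() {
  list(
    n_genes = 2000L, n_samples = 60L,
    module_sizes = c(300L, 200L, 150L, 100L),
    factor_loading = 0.8, noise_sd = 0.6,
    ref_in_module = 40L, ref_background = 60L,
    graph_mean_degree = 4, hub_boost = 20L, n_ref_hubs = 8L,
    score_range = c(0.7, 1.0),
    n_per_group = 3L, baseline_mean_range = c(20, 500), dispersion = 0.1,
    n_candidates = 6L, n_candidates_in_reference = 2L,
    candidate_lfc = c(6.5, -4.5, 4, -4, 5, -5),
    tier_lfc = c(1, 2, 4), tier_size = 10L,
    regions = c("amygdala", "hypothalamus", "cerebellum", "nac", "pfc",
                "neocortex", "vta", "hippocampus"),
    n_phenotypes = 31L, rho = 0.7, strain_range = c(27L, 69L),
    missing_rate = 0.1, phen_per_region = 4L,
    traits = c("neck_shoulder_pain", "back_pain", "knee_pain", "headache",
               "hip_pain", "abdominal_pain"),
    gwas_p_strength = 1e-4, candidate_traits = 2L
  )
}

#' Generate the full synthetic study in memory
#'
#' Runs every generator under one seed schedule and assembles the complete
#' ground truth, including the planted candidate set (genes simultaneously
#' module-1 members, degree-boosted in the graph, strongly differentially
#' expressed, GWAS-associated, and phenotype-correlated in all regions).
#'
#' @param preset list from [synth_preset()].
#' @param seed integer master seed; sub-generators use fixed offsets from it.
#' @return list: expr, reference (genes), edge_table, counts, groups, panels,
#'   gwas, collections (pathway/TF gene sets), truth.
#' @export
simulate_study <- function(preset = synth_preset(), seed = 1) {
  p <- preset
  sim <- simulate_module_expression(p$n_genes, p$n_samples, p$module_sizes,
                                    p$factor_loading, p$noise_sd,
                                    seed = seed)
  truth <- sim$truth
  ref <- plant_reference_set(truth, target_module = 1L,
                             n_in_module = p$ref_in_module,
                             n_background = p$ref_background,
                             seed = seed + 1)
  truth <- ref$truth
  module1 <- names(truth$module_of_gene)[truth$module_of_gene == 1L]
  ref_in_mod <- intersect(ref$genes, module1)
  # planted candidates: module-1 genes, some inside the reference set
  cand <- with_seed(seed + 2, {
    in_ref <- sample(ref_in_mod, p$n_candidates_in_reference)
    out_ref <- sample(setdiff(module1, ref$genes),
                      p$n_candidates - p$n_candidates_in_reference)
    c(in_ref, out_ref)
  })
  truth$candidate_genes <- cand
  ref_hubs <- with_seed(seed + 3,
                        sample(setdiff(ref_in_mod, cand), p$n_ref_hubs))
  truth$hub_genes <- c(cand, ref_hubs)
  edge_table <- simulate_interaction_graph(
    module1, mean_degree = p$graph_mean_degree,
    hub_genes = truth$hub_genes, hub_degree_boost = p$hub_boost,
    score_range = p$score_range, seed = seed + 4)
  # DE: strong planted fold changes on candidates; tiers on background genes
  bg <- names(truth$module_of_gene)[truth$module_of_gene == 0L]
  bg <- setdiff(bg, ref$genes)
  tier_genes <- with_seed(seed + 5,
                          sample(bg, p$tier_size * 2 * length(p$tier_lfc)))
  tier_lfc <- rep(c(p$tier_lfc, -p$tier_lfc), each = p$tier_size)
  de_plan <- c(stats::setNames(p$candidate_lfc[seq_along(cand)], cand),
               stats::setNames(tier_lfc, tier_genes))
  cnt <- simulate_counts(names(truth$module_of_gene), p$n_per_group,
                         p$baseline_mean_range, p$dispersion,
                         de_genes_with_lfc = de_plan, seed = seed + 6)
  truth$de_genes <- de_plan
  # phenotype panels over the module-1 genes; candidate signs follow DE sign
  pair_rows <- do.call(rbind, lapply(seq_along(cand), function(i) {
    expand.grid(gene = cand[i], region = p$regions,
                phenotype = seq_len(p$phen_per_region),
                stringsAsFactors = FALSE)
  }))
  pairs <- tibble::tibble(
    gene = pair_rows$gene, region = pair_rows$region,
    phenotype = pair_rows$phenotype,
    sign = as.integer(sign(de_plan[pair_rows$gene])))
  pan <- simulate_strain_panels(module1, regions = p$regions,
                                n_phenotypes = p$n_phenotypes,
                                correlated_pairs = pairs, rho = p$rho,
                                strain_range = p$strain_range,
                                missing_rate = p$missing_rate,
                                seed = seed + 7)
  truth$correlated_pairs <- pan$truth
  assoc_pairs <- with_seed(seed + 8, {
    per_cand <- lapply(cand, function(g) {
      tibble::tibble(gene = g, trait = sample(p$traits, p$candidate_traits))
    })
    decoys <- tibble::tibble(gene = sample(setdiff(bg, tier_genes), 3),
                             trait = sample(p$traits, 3, replace = TRUE))
    dplyr::bind_rows(c(per_cand, list(decoys)))
  })
  gwas <- simulate_gwas_table(names(truth$module_of_gene), p$traits,
                              associated_pairs = assoc_pairs,
                              p_strength = p$gwas_p_strength, seed = seed + 9)
  truth$associated_pairs <- assoc_pairs
  collections <- simulate_collections(truth, seed = seed + 10)
  list(expr = sim$expr, reference = ref$genes, edge_table = edge_table,
       counts = cnt$counts, groups = cnt$groups, panels = pan$panels,
       gwas = gwas, collections = collections, truth = truth)
}

# Pathway- and TF-target-style gene-set collections for the ORA stages:
# a few sets carved from planted modules (with noise genes mixed in), random
# decoy sets, and TF-target sets of which one targets the candidates.
simulate_collections <- function(truth, seed, n_random = 12, tf_n = 8) {
  genes <- names(truth$module_of_gene)
  with_seed(seed, {
    sets <- list()
    for (m in sort(unique(truth$module_of_gene[truth$module_of_gene > 0]))) {
      members <- genes[truth$module_of_gene == m]
      take <- sample(members, min(40, length(members)))
      noise <- sample(setdiff(genes, members), 10)
      sets[[sprintf("pathway_module%d", m)]] <- c(take, noise)
    }
    for (i in seq_len(n_random)) {
      sets[[sprintf("pathway_random%02d", i)]] <- sample(genes,
                                                         sample(20:80, 1))
    }
    pathways <- geneset_collection(sets)
    tf_sets <- list(
      TF_CAND = unique(c(truth$candidate_genes,
                         sample(genes, 30)))
    )
    for (i in seq_len(tf_n - 1)) {
      tf_sets[[sprintf("TF_%02d", i)]] <- sample(genes, sample(25:60, 1))
    }
    list(pathways = pathways, tf = geneset_collection(tf_sets))
  })
}

#' Write a complete synthetic fixture directory
#'
#' Materializes every input file the pipeline consumes — expression TSV,
#' reference GMT, interaction TSV, counts + groups TSVs, per-region panel
#' TSVs, association TSV, pathway and TF GMTs — plus `truth.json`, and
#' returns a ready [pipeline_config()] pointing at them.
#'
#' @param dir output directory (created).
#' @param preset generator preset.
#' @param seed master seed.
#' @return a `pipeline_config` list (with the study attached as attribute
#'   "study" for convenience in tests).
#' @export
write_synthetic_fixture <- function(dir, preset = synth_preset(), seed = 1) {
  study <- simulate_study(preset, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(study$expr, file.path(dir, "expression.tsv"))
  write_gmt(geneset_collection(
    list(pain_reference = study$reference),
    c(pain_reference = "planted reference gene set")),
    file.path(dir, "reference.gmt"))
  write_table_tsv(study$edge_table, file.path(dir, "interactions.tsv"))
  write_counts_tsv(study$counts, study$groups,
                   file.path(dir, "counts.tsv"), file.path(dir, "groups.tsv"))
  panel_dir <- file.path(dir, "panels")
  for (pn in study$panels) write_panel(pn, panel_dir)
  write_table_tsv(study$gwas, file.path(dir, "gwas.tsv"))
  write_gmt(study$collections$pathways, file.path(dir, "pathways.gmt"))
  write_gmt(study$collections$tf, file.path(dir, "tf_targets.gmt"))
  truth <- study$truth
  jsonlite::write_json(list(
    module_of_gene = as.list(truth$module_of_gene),
    reference_genes = truth$reference_genes,
    de_genes = as.list(truth$de_genes),
    hub_genes = truth$hub_genes,
    candidate_genes = truth$candidate_genes,
    correlated_pairs = truth$correlated_pairs,
    associated_pairs = truth$associated_pairs
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- pipeline_config(input_dir = dir, seed = seed)
  attr(cfg, "study") <- study
  cfg
}
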