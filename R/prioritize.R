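# Candidate prioritization: GWAS-trait filtering, the four-criterion
# shortlist (subnetwork degree, differential expression, GWAS associations,
# pan-region phenotype correlation), direction consistency between fold
# change and correlation signs, and reference-set annotation.

#' Count significant GWAS traits per gene
#'
#' Distinct traits with p below `alpha` and below `strict_alpha` per gene;
#' a gene appearing in the table with no significant association is reported
#' with count 0. Duplicated gene-trait rows count once.
#'
#' @param association_table tibble(gene, trait, p).
#' @param alpha significance threshold (default 0.05).
#' @param strict_alpha stricter threshold (default 1e-3).
#' @return tibble: gene, gwas_trait_count, strict_gwas_count.
#' @export
filter_gwas <- function(association_table, alpha = 0.05, strict_alpha = 1e-3) {
  tab <- association_table
  if (!all(c("gene", "trait", "p") %in% names(tab))) {
    pmn_abort("association table needs columns gene, trait, p")
  }
  bad <- which(!is.finite(tab$p) | tab$p < 0 | tab$p > 1)
  if (length(bad)) {
    pmn_abort(sprintf("p-value outside [0, 1] at row %d", bad[1]))
  }
  dplyr::summarise(
    dplyr::group_by(tab, .data$gene),
    gwas_trait_count = dplyr::n_distinct(.data$trait[.data$p < alpha]),
    strict_gwas_count = dplyr::n_distinct(.data$trait[.data$p < strict_alpha]),
    .groups = "drop")
}

#' Default shortlist thresholds
#'
#' `min_degree` and `min_regions` default to 4 — the minima observed among
#' the kinds of genes such shortlists retain — and remain configurable;
#' `min_fc = 2` is deliberately stricter than the DE stage's own 1.5 (the
#' shortlist demands strong differential expression); `max_fdr = 0.05`
#' (strict below); `min_gwas = 1` significant trait.
#'
#' @return named list of thresholds.
#' @export
shortlist_thresholds <- function(min_degree = 4, min_fc = 2, max_fdr = 0.05,
                                 min_gwas = 1, min_regions = 4) {
  list(min_degree = min_degree, min_fc = min_fc, max_fdr = max_fdr,
       min_gwas = min_gwas, min_regions = min_regions)
}

#' Four-criterion candidate shortlist
#'
#' Integrates the reference subnetwork (node degrees), the DE table, GWAS
#' trait counts and per-gene region-correlation counts over the subnetwork's
#' gene set. A gene is shortlisted when it passes all four criteria:
#' degree >= min_degree; |log2fc| >= log2(min_fc) with fdr < max_fdr;
#' gwas_trait_count >= min_gwas; regions_correlated >= min_regions.
#' Reference-set membership is reported but not required. The table is sorted
#' by (regions_correlated, node_degree, |log2fc|) descending.
#'
#' @param subnet_nodes tibble with columns `node` (gene) and `degree`
#'   (e.g. from [graph_tables()]), optionally `is_reference`.
#' @param de_result DE tibble (gene, log2fc, fdr).
#' @param gwas_counts tibble from [filter_gwas()].
#' @param corr_counts per-gene region counts (gene, n_regions), e.g.
#'   `count_significant(...)$per_gene`.
#' @param thresholds list from [shortlist_thresholds()].
#' @return candidate tibble: gene, node_degree, is_reference, log2fc, fdr,
#'   gwas_trait_count, strict_gwas_count, regions_correlated, pass_degree,
#'   pass_de, pass_gwas, pass_regions, shortlist.
#' @export
shortlist_candidates <- function(subnet_nodes, de_result, gwas_counts,
                                 corr_counts,
                                 thresholds = shortlist_thresholds()) {
  for (nm in c("subnet_nodes", "de_result", "gwas_counts", "corr_counts")) {
    if (is.null(get(nm)) || !nrow(get(nm))) {
      pmn_abort(sprintf("missing or empty input table: %s", nm))
    }
  }
  th <- utils::modifyList(shortlist_thresholds(), thresholds)
  tab <- tibble::tibble(
    gene = subnet_nodes$node,
    node_degree = subnet_nodes$degree,
    is_reference = if ("is_reference" %in% names(subnet_nodes))
      subnet_nodes$is_reference else FALSE)
  tab <- dplyr::left_join(tab,
                          de_result[, c("gene", "log2fc", "fdr")], by = "gene")
  tab <- dplyr::left_join(tab, gwas_counts, by = "gene")
  cc <- corr_counts
  names(cc)[names(cc) == "n_regions"] <- "regions_correlated"
  tab <- dplyr::left_join(tab, cc[, c("gene", "regions_correlated")],
                          by = "gene")
  tab$gwas_trait_count[is.na(tab$gwas_trait_count)] <- 0L
  tab$strict_gwas_count[is.na(tab$strict_gwas_count)] <- 0L
  tab$regions_correlated[is.na(tab$regions_correlated)] <- 0L
  tab$pass_degree <- tab$node_degree >= th$min_degree
  tab$pass_de <- !is.na(tab$fdr) & tab$fdr < th$max_fdr &
    abs(tab$log2fc) >= log2(th$min_fc)
  tab$pass_gwas <- tab$gwas_trait_count >= th$min_gwas
  tab$pass_regions <- tab$regions_correlated >= th$min_regions
  tab$shortlist <- tab$pass_degree & tab$pass_de & tab$pass_gwas &
    tab$pass_regions
  dplyr::arrange(tab, dplyr::desc(.data$regions_correlated),
                 dplyr::desc(.data$node_degree),
                 dplyr::desc(abs(dplyr::coalesce(.data$log2fc, 0))),
                 .data$gene)
}

#' Direction consistency between fold change and correlation signs
#'
#' A candidate is direction-consistent when its differential expression and
#' its dominant correlation sign agree: upregulated with mostly positive
#' correlations, or downregulated with mostly negative ones. Equal positive
#' and negative counts are flagged as ties (inconsistent-by-tie), reported
#' separately from a plain inconsistency.
#'
#' @param candidate_table tibble with `gene` and `log2fc`.
#' @param balance overall sign balance (gene, n_positive, n_negative), e.g.
#'   `sign_balance(...)$overall`.
#' @return the table with n_positive, n_negative, `consistent` (logical) and
#'   `tie` (logical) columns appended.
#' @export
direction_consistency <- function(candidate_table, balance) {
  tab <- dplyr::left_join(candidate_table, balance, by = "gene")
  tab$n_positive[is.na(tab$n_positive)] <- 0L
  tab$n_negative[is.na(tab$n_negative)] <- 0L
  tab$tie <- tab$n_positive == tab$n_negative
  tab$consistent <- !tab$tie & !is.na(tab$log2fc) &
    ((tab$log2fc > 0 & tab$n_positive > tab$n_negative) |
     (tab$log2fc < 0 & tab$n_negative > tab$n_positive))
  tab
}

#' Annotate shortlist membership in the reference set
#'
#' Sets/overrides `is_reference` and attaches a `summary` attribute with the
#' counts of known (reference) versus novel shortlisted genes.
#'
#' @param candidate_table tibble with `gene` and `shortlist`.
#' @param reference_set character vector (may be empty).
#' @return annotated tibble; `attr(, "summary")` holds
#'   list(known, novel, text).
#' @export
annotate_reference <- function(candidate_table, reference_set) {
  tab <- candidate_table
  tab$is_reference <- tab$gene %in% reference_set
  short <- tab[tab$shortlist, , drop = FALSE]
  known <- sum(short$is_reference)
  novel <- nrow(short) - known
  attr(tab, "summary") <- list(
    known = known, novel = novel,
    text = sprintf("%d known / %d novel shortlisted genes", known, novel))
  tab
}
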