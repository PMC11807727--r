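# Gene-phenotype correlation screen across brain-region strain panels:
# pairwise-complete Pearson correlation with t-distribution p-values, per-gene
# significant-phenotype counts, pan-region membership, and sign balance.
#
# The screen deliberately uses raw p < alpha with no multiple-testing
# correction (the reference-population workflow it mirrors reports raw
# Pearson significance); an optional BH mode is available.

#' Correlate gene expression with phenotypes within one panel
#'
#' Pairwise-complete Pearson correlation of each requested gene's strain
#' profile against each phenotype; two-sided p from
#' t = r sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom. Tests with
#' fewer than 4 complete pairs, or with a zero-variance vector, are reported
#' untestable (`testable = FALSE`, NA statistics).
#'
#' @param panel a [strain_panel()].
#' @param genes genes to screen (default all in the panel); genes absent from
#'   the panel are skipped with a warning.
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param adjust "none" (default, raw p) or "BH" (flag on FDR instead).
#' @return tibble: gene, region, phenotype, r, n, p, significant, testable.
#' @export
correlate_panel <- function(panel, genes = NULL, alpha = 0.05,
                            adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(panel, "strain_panel"))
  genes <- genes %||% rownames(panel$expression)
  missing <- setdiff(genes, rownames(panel$expression))
  if (length(missing)) {
    warning(sprintf("%d gene(s) absent from panel '%s'; skipped",
                    length(missing), panel$region), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) pmn_abort("no requested gene present in the panel")
  ex <- t(panel$expression[genes, , drop = FALSE])   # strain x gene
  ph <- panel$phenotypes                             # strain x phenotype
  r <- suppressWarnings(stats::cor(ex, ph, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(ex), !is.na(ph))             # complete pairs
  testable <- n >= 4 & is.finite(r)
  tstat <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = pmax(n - 2, 1), lower.tail = FALSE)
  p[r^2 >= 1] <- 0                                   # perfect correlation
  p[!testable] <- NA_real_
  r[!testable] <- NA_real_
  out <- tibble::tibble(
    gene = rep(genes, times = ncol(ph)),
    region = panel$region,
    phenotype = rep(colnames(ph), each = length(genes)),
    r = as.vector(r), n = as.vector(n), p = as.vector(p),
    testable = as.vector(testable))
  out$significant <- if (adjust == "BH") {
    adj <- rep(NA_real_, nrow(out))
    adj[out$testable] <- bh_adjust(out$p[out$testable])
    !is.na(adj) & adj < alpha
  } else {
    !is.na(out$p) & out$p < alpha
  }
  out
}

#' Screen several panels at once
#' @param panels named list of [strain_panel()] objects.
#' @inheritParams correlate_panel
#' @return row-bound tibble over all regions.
#' @export
correlate_panels <- function(panels, genes = NULL, alpha = 0.05,
                             adjust = c("none", "BH")) {
  dplyr::bind_rows(lapply(panels, correlate_panel, genes = genes,
                          alpha = alpha, adjust = match.arg(adjust)))
}

#' Count significant correlations per gene
#'
#' @param results tibble from [correlate_panel()]/[correlate_panels()].
#' @return list with `per_region` (gene, region, n_significant) and
#'   `per_gene` (gene, n_regions: regions with >= 1 significant phenotype).
#'   Every screened gene appears, with zero counts where nothing is
#'   significant.
#' @export
count_significant <- function(results) {
  if (!nrow(results)) {
    return(list(per_region = tibble::tibble(gene = character(),
                                            region = character(),
                                            n_significant = integer()),
                per_gene = tibble::tibble(gene = character(),
                                          n_regions = integer())))
  }
  per_region <- dplyr::summarise(
    dplyr::group_by(results, .data$gene, .data$region),
    n_significant = sum(.data$significant, na.rm = TRUE), .groups = "drop")
  per_gene <- dplyr::summarise(
    dplyr::group_by(per_region, .data$gene),
    n_regions = sum(.data$n_significant > 0), .groups = "drop")
  list(per_region = per_region, per_gene = per_gene)
}

#' Genes significantly correlated in at least n regions
#'
#' @param results correlation tibble.
#' @param n_regions_required required region count; must not exceed the
#'   number of regions present in `results`.
#' @return character vector of genes.
#' @export
pan_region_genes <- function(results, n_regions_required) {
  n_regions <- length(unique(results$region))
  if (n_regions_required > n_regions) {
    pmn_abort(sprintf("n_regions_required (%d) exceeds regions supplied (%d)",
                      n_regions_required, n_regions))
  }
  counts <- count_significant(results)$per_gene
  if (n_regions_required <= 0) return(unique(results$gene))
  counts$gene[counts$n_regions >= n_regions_required]
}

#' Sign balance of significant correlations
#'
#' Counts of significant positive (r > 0) and negative (r < 0) correlations
#' per region and overall for the given genes.
#'
#' @param results correlation tibble.
#' @param genes genes of interest (default all).
#' @return list with `per_region` (gene, region, n_positive, n_negative) and
#'   `overall` (gene, n_positive, n_negative).
#' @export
sign_balance <- function(results, genes = NULL) {
  genes <- genes %||% unique(results$gene)
  sub <- results[results$gene %in% genes, , drop = FALSE]
  per_region <- dplyr::summarise(
    dplyr::group_by(sub, .data$gene, .data$region),
    n_positive = sum(.data$significant & .data$r > 0, na.rm = TRUE),
    n_negative = sum(.data$significant & .data$r < 0, na.rm = TRUE),
    .groups = "drop")
  overall <- dplyr::summarise(
    dplyr::group_by(per_region, .data$gene),
    n_positive = sum(.data$n_positive),
    n_negative = sum(.data$n_negative), .groups = "drop")
  missing <- setdiff(genes, overall$gene)
  if (length(missing)) {
    overall <- dplyr::bind_rows(
      overall, tibble::tibble(gene = missing, n_positive = 0L, n_negative = 0L))
  }
  list(per_region = per_region, overall = dplyr::arrange(overall, .data$gene))
}
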