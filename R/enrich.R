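# Gene-set machinery: module-vs-reference hypergeometric enrichment (the
# pain-module selection step), generic over-representation analysis for
# pathway/GO/TF-target collections, BH adjustment, and the kappa-similarity
# term network used to cluster redundant enriched terms.

#' Hypergeometric enrichment of each module against a reference set
#'
#' For every non-gray module of size m in a universe of N genes containing K
#' reference genes, the overlap x is tested under Hypergeometric(N, K, m):
#' p_over = P(X >= x), p_under = P(X <= x), two-sided p = min(1, 2 min(tails)).
#' BH adjustment is applied across modules. The enrichment ratio is
#' x / (m K / N), the observed over expected overlap; direction is "over" when
#' the ratio exceeds 1 and "under" below 1 (both directions can be
#' significant, as when a module is significantly depleted of reference
#' genes). Reference genes outside the universe are dropped before K is
#' computed.
#'
#' @param assignment a `module_assignment`.
#' @param reference_set character vector of reference genes.
#' @param universe gene universe; defaults to the clustered gene list (the
#'   genes carried into module detection), never the whole genome.
#' @return tibble sorted by fdr: module, universe_size, query_size,
#'   set_in_universe, overlap, enrichment_ratio, direction, p_over, p_under,
#'   p_two_sided, fdr.
#' @export
hypergeom_module_enrichment <- function(assignment, reference_set,
                                        universe = names(assignment$labels)) {
  stopifnot(inherits(assignment, "module_assignment"))
  labels <- assignment$labels
  if (!all(names(labels) %in% universe)) {
    pmn_abort("module genes absent from the declared universe")
  }
  ref <- intersect(unique(reference_set), universe)
  if (!length(ref)) pmn_abort("reference set does not intersect the universe")
  N <- length(universe)
  K <- length(ref)
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) pmn_abort("no non-gray module to test")
  rows <- lapply(mods, function(mod) {
    members <- names(labels)[labels == mod]
    m <- length(members)
    x <- length(intersect(members, ref))
    ht <- hypergeom_tails(x, N, K, m)
    tibble::tibble(
      module = mod, universe_size = N, query_size = m, set_in_universe = K,
      overlap = x,
      enrichment_ratio = if (m * K > 0) x / (m * K / N) else NA_real_,
      direction = dplyr::case_when(x / (m * K / N) > 1 ~ "over",
                                   x / (m * K / N) < 1 ~ "under",
                                   TRUE ~ "none"),
      p_over = ht$p_over, p_under = ht$p_under, p_two_sided = ht$p_two)
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p_two_sided)
  dplyr::arrange(out, .data$fdr, .data$p_two_sided, .data$module)
}

# Hypergeometric tail probabilities for overlap x with population N,
# successes K, draws m.
hypergeom_tails <- function(x, N, K, m) {
  p_over <- stats::phyper(x - 1, K, N - K, m, lower.tail = FALSE)
  p_under <- stats::phyper(x, K, N - K, m, lower.tail = TRUE)
  list(p_over = p_over, p_under = p_under,
       p_two = min(1, 2 * min(p_over, p_under)))
}

#' Over-representation analysis against a gene-set collection
#'
#' One-sided hypergeometric over-representation of `query_genes` in each set
#' of the collection, restricted to the universe. Sets with fewer than
#' `min_genes_per_set` genes in the universe are excluded before testing.
#' Significance follows the mode: pathway mode flags FDR <= `fdr_threshold`
#' (0.1 by default); TF mode flags raw p < `p_threshold` (0.05 by default).
#' Query genes outside the universe are dropped (their count is reported as
#' an attribute); duplicates are removed.
#'
#' @param query_genes character vector of genes of interest.
#' @param collection a [geneset_collection()].
#' @param universe background gene list.
#' @param min_genes_per_set minimum in-universe set size tested.
#' @param mode "pathway" (FDR rule) or "tf" (raw-p rule).
#' @param fdr_threshold,p_threshold significance cutoffs for the two modes.
#' @return tibble: set_name, universe_size, query_size, set_in_universe,
#'   overlap, enrichment_ratio, p_over, fdr, significant; attribute
#'   `n_query_dropped` reports out-of-universe query genes.
#' @export
ora <- function(query_genes, collection, universe, min_genes_per_set = 5,
                mode = c("pathway", "tf"), fdr_threshold = 0.1,
                p_threshold = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(collection, "geneset_collection"))
  query0 <- unique(query_genes)
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  if (!length(query)) pmn_abort("query empty after intersecting with universe")
  N <- length(universe)
  m <- length(query)
  in_universe <- lapply(collection$sets, intersect, universe)
  keep <- lengths(in_universe) >= min_genes_per_set
  sets <- in_universe[keep]
  if (!length(sets)) {
    out <- tibble::tibble(set_name = character(), universe_size = integer(),
                          query_size = integer(), set_in_universe = integer(),
                          overlap = integer(), enrichment_ratio = numeric(),
                          p_over = numeric(), fdr = numeric(),
                          significant = logical())
    attr(out, "n_query_dropped") <- dropped
    return(out)
  }
  rows <- lapply(names(sets), function(nm) {
    K <- length(sets[[nm]])
    x <- length(intersect(query, sets[[nm]]))
    tibble::tibble(set_name = nm, universe_size = N, query_size = m,
                   set_in_universe = K, overlap = x,
                   enrichment_ratio = x / (m * K / N),
                   p_over = stats::phyper(x - 1, K, N - K, m,
                                          lower.tail = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- bh_adjust(out$p_over)
  out$significant <- if (mode == "pathway") out$fdr <= fdr_threshold
    else out$p_over < p_threshold
  out <- dplyr::arrange(out, .data$p_over, .data$set_name)
  attr(out, "n_query_dropped") <- dropped
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order matches
#' input order.
#'
#' @param p_values numeric vector in \[0, 1\]; NAs are rejected.
#' @return adjusted values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values))) pmn_abort("NA p-values passed to bh_adjust")
  if (any(p_values < 0 | p_values > 1)) pmn_abort("p-values outside [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Kappa-similarity network over enriched terms
#'
#' Builds the term-redundancy network used to group overlapping enriched
#' annotations: for every pair of significant terms, Cohen's kappa is computed
#' between their universe-membership indicator vectors; terms are connected
#' when kappa exceeds `kappa_threshold`; connected components define clusters;
#' each cluster is labeled by its lowest-p term and reports up to
#' `max_terms_per_cluster` best-scoring terms.
#'
#' @param enrichment_table result of [ora()] (significant rows are used; if
#'   no `significant` column, all rows are used).
#' @param collection the [geneset_collection()] behind the table.
#' @param universe gene universe for the membership vectors.
#' @param kappa_threshold edge threshold (default 0.3, strict inequality).
#' @param max_terms_per_cluster terms reported per cluster (default 10).
#' @return list with `edges` (tibble: term_a, term_b, kappa), `clusters`
#'   (tibble: term, p_over, cluster, representative, reported).
#' @export
kappa_term_network <- function(enrichment_table, collection, universe,
                               kappa_threshold = 0.3,
                               max_terms_per_cluster = 10) {
  stopifnot(inherits(collection, "geneset_collection"))
  tab <- enrichment_table
  if ("significant" %in% names(tab)) tab <- tab[tab$significant, , drop = FALSE]
  terms <- tab$set_name
  if (!length(terms)) {
    return(list(edges = tibble::tibble(term_a = character(),
                                       term_b = character(), kappa = numeric()),
                clusters = tibble::tibble(term = character(), p_over = numeric(),
                                          cluster = integer(),
                                          representative = character(),
                                          reported = logical())))
  }
  membership <- vapply(terms, function(nm) {
    universe %in% collection$sets[[nm]]
  }, logical(length(universe)))
  membership <- matrix(membership, ncol = length(terms),
                       dimnames = list(NULL, terms))
  edges <- list()
  if (length(terms) > 1) {
    for (i in seq_len(length(terms) - 1)) for (j in (i + 1):length(terms)) {
      k <- cohen_kappa(membership[, i], membership[, j])
      if (is.finite(k) && k > kappa_threshold) {
        edges[[length(edges) + 1L]] <- tibble::tibble(
          term_a = terms[i], term_b = terms[j], kappa = k)
      }
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else
    tibble::tibble(term_a = character(), term_b = character(), kappa = numeric())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = terms))
  comp <- igraph::components(g)$membership
  clusters <- tibble::tibble(term = terms,
                             p_over = tab$p_over[match(terms, tab$set_name)],
                             cluster = unname(comp[terms]))
  clusters <- dplyr::group_by(clusters, .data$cluster)
  clusters <- dplyr::mutate(
    clusters,
    representative = .data$term[which.min(.data$p_over)],
    reported = rank(.data$p_over, ties.method = "first") <= max_terms_per_cluster)
  clusters <- dplyr::ungroup(dplyr::arrange(clusters, .data$cluster,
                                            .data$p_over))
  list(edges = edges, clusters = clusters)
}

#' Cohen's kappa between two logical membership vectors
#' @param a,b logical vectors of equal length.
#' @return kappa; 0 when chance agreement is exact.
#' @export
cohen_kappa <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}
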