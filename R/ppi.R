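# Protein-interaction graph handling: score-thresholded loading,
# reference-plus-first-neighbor subnetwork extraction, degree and maximum
# neighborhood component (MNC) hub scoring, ranking, and overlay of
# differential-expression results onto the network. Graphs are igraph objects
# with a `score` edge attribute and node attributes set by the stages.

#' Load a scored interaction edge list into a graph
#'
#' Edges with score below `score_threshold` are dropped (">= threshold" keeps
#' an edge at exactly the cutoff); duplicate undirected pairs collapse to the
#' maximum score; self-loops are dropped with a warning; nodes appear only via
#' surviving edges, so isolated nodes are never present. Integer score columns
#' in 0-1000 (the STRING wire format) are auto-detected and divided by 1000;
#' set `autoscale = FALSE` to disable.
#'
#' @param edge_table data frame with columns protein_a, protein_b,
#'   combined_score (see [read_interactions_tsv()]).
#' @param score_threshold minimum retained score in \[0, 1\] (default 0.7).
#' @param autoscale divide 0-1000 integer scores by 1000 when detected.
#' @return undirected igraph with edge attribute `score`.
#' @export
load_interactions <- function(edge_table, score_threshold = 0.7,
                              autoscale = TRUE) {
  if (score_threshold < 0 || score_threshold > 1) {
    pmn_abort("score_threshold must lie in [0, 1]")
  }
  et <- as.data.frame(edge_table)[, c("protein_a", "protein_b",
                                      "combined_score")]
  if (any(!is.finite(et$combined_score))) {
    pmn_abort(sprintf("malformed score at row %d",
                      which(!is.finite(et$combined_score))[1]),
              class = "painmodnet_format_error")
  }
  if (autoscale && nrow(et) &&
      all(et$combined_score == round(et$combined_score)) &&
      max(et$combined_score) > 1 && max(et$combined_score) <= 1000) {
    et$combined_score <- et$combined_score / 1000
  }
  if (any(et$combined_score < 0 | et$combined_score > 1)) {
    pmn_abort("combined scores must lie in [0, 1] after scaling")
  }
  self <- et$protein_a == et$protein_b
  if (any(self)) {
    warning(sprintf("dropped %d self-interaction(s)", sum(self)), call. = FALSE)
    et <- et[!self, , drop = FALSE]
  }
  df <- data.frame(from = character(), to = character(), score = numeric(),
                   stringsAsFactors = FALSE)
  if (nrow(et)) {
    a <- pmin(et$protein_a, et$protein_b)
    b <- pmax(et$protein_a, et$protein_b)
    key <- paste(a, b, sep = "\r")
    agg <- tapply(et$combined_score, key, max)
    pair <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
    keep <- unname(agg) >= score_threshold
    if (any(keep)) {
      df <- data.frame(from = pair[keep, 1], to = pair[keep, 2],
                       score = unname(agg)[keep], stringsAsFactors = FALSE)
    }
  }
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Extract the reference-plus-first-neighbor subnetwork
#'
#' Node set: reference genes present in the graph plus all their direct
#' neighbors; edge set: every graph edge with both endpoints in that node set,
#' including interactor-interactor edges. Nodes gain a logical `is_reference`
#' attribute.
#'
#' @param graph igraph from [load_interactions()].
#' @param reference_genes non-empty character vector.
#' @return induced igraph subgraph.
#' @export
extract_reference_subnetwork <- function(graph, reference_genes) {
  if (!length(reference_genes)) pmn_abort("reference_genes must be non-empty")
  present <- intersect(reference_genes, igraph::V(graph)$name)
  if (!length(present)) {
    pmn_abort("no reference gene present in the interaction graph")
  }
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(graph, present),
                               names)))
  nodes <- union(present, nbrs)
  sub <- igraph::induced_subgraph(graph, nodes)
  igraph::V(sub)$is_reference <- igraph::V(sub)$name %in% reference_genes
  sub
}

#' Maximum Neighborhood Component score of a node
#'
#' Size (node count) of the largest connected component of the subgraph
#' induced by v's neighbors, v excluded. 1 when no two neighbors are
#' adjacent; bounded above by degree(v).
#'
#' @param graph igraph.
#' @param v node name (or vector of names).
#' @return integer vector of MNC scores.
#' @export
mnc <- function(graph, v) {
  missing <- setdiff(v, igraph::V(graph)$name)
  if (length(missing)) {
    pmn_abort(sprintf("node(s) absent from graph: %s",
                      paste(missing, collapse = ", ")))
  }
  vapply(v, function(node) {
    nb <- igraph::neighbors(graph, node)
    if (!length(nb)) return(0L)
    sub <- igraph::induced_subgraph(graph, nb)
    as.integer(max(igraph::components(sub)$csize))
  }, integer(1))
}

#' Rank hub nodes by degree or MNC
#'
#' Descending score; ties broken lexicographically by node id for
#' reproducibility; ranks are dense over tied scores (equal scores share a
#' rank and the next distinct score takes the next rank).
#'
#' @param graph igraph.
#' @param method "degree" or "mnc".
#' @param top_n rows returned (default all).
#' @return tibble: node, method, score, rank.
#' @export
rank_hubs <- function(graph, method = c("degree", "mnc"), top_n = Inf) {
  method <- match.arg(method)
  nodes <- igraph::V(graph)$name
  score <- switch(method,
                  degree = igraph::degree(graph),
                  mnc = mnc(graph, nodes))
  tab <- tibble::tibble(node = nodes, method = method,
                        score = as.integer(score))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$score), .data$node)
  tab$rank <- match(tab$score, sort(unique(tab$score), decreasing = TRUE))
  utils::head(tab, n = top_n)
}

#' Overlay differential-expression results on a graph
#'
#' Annotates every node with `log2fc`, `fdr` and a `de_flag` of "up", "down",
#' "ns" (tested, not passing the fold-change/FDR rule) or "untested" (absent
#' from the DE table). The graph-level attribute `n_de` carries the count of
#' up or down nodes — the network/DE overlap size.
#'
#' @param graph igraph (typically the reference subnetwork).
#' @param de_result DE tibble with columns gene, log2fc, fdr.
#' @param fc_min,fdr_max thresholds defining up/down (defaults 1.5 and 0.05;
#'   fdr strictly below, |log2fc| at or above log2(fc_min)).
#' @return the annotated igraph; retrieve the overlap count with
#'   `igraph::graph_attr(g, "n_de")`.
#' @export
overlay_de <- function(graph, de_result, fc_min = 1.5, fdr_max = 0.05) {
  nodes <- igraph::V(graph)$name
  idx <- match(nodes, de_result$gene)
  lfc <- de_result$log2fc[idx]
  fdr <- de_result$fdr[idx]
  flag <- ifelse(is.na(idx), "untested",
          ifelse(fdr < fdr_max & lfc >= log2(fc_min), "up",
          ifelse(fdr < fdr_max & lfc <= -log2(fc_min), "down", "ns")))
  igraph::V(graph)$log2fc <- lfc
  igraph::V(graph)$fdr <- fdr
  igraph::V(graph)$de_flag <- flag
  graph <- igraph::set_graph_attr(graph, "n_de",
                                  sum(flag %in% c("up", "down")))
  graph
}

#' Export graph node and edge tables
#' @param graph annotated igraph.
#' @return list of tibbles `nodes` and `edges`.
#' @export
graph_tables <- function(graph) {
  nodes <- tibble::as_tibble(igraph::as_data_frame(graph, what = "vertices"))
  names(nodes)[names(nodes) == "name"] <- "node"
  nodes$degree <- unname(igraph::degree(graph)[nodes$node])
  edges <- tibble::as_tibble(igraph::as_data_frame(graph, what = "edges"))
  list(nodes = nodes, edges = edges)
}
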