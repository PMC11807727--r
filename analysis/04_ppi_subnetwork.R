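#!/usr/bin/env Rscript

# Stage 4: protein-interaction subnetwork of the pain module.
#
# Loads the score-thresholded interaction graph, restricts it to the pain
# module's genes, extracts the reference subnetwork (reference genes plus
# first neighbors) and ranks hubs by degree and MNC.
# Requires: analysis/03_module_enrichment.R

suppressMessages(library(painmodnet))

asg <- utils::read.delim(file.path("results", "02_module_assignment.tsv"))
pain_module <- as.integer(readLines(file.path("results",
                                              "03_pain_module.txt")))
module_genes <- asg$gene[asg$module == pain_module]
reference <- unique(unlist(
  read_gmt(file.path("results", "fixture", "reference.gmt"))$sets))

g <- load_interactions(
  read_interactions_tsv(file.path("results", "fixture", "interactions.tsv")),
  score_threshold = 0.7)
g <- igraph::induced_subgraph(g, intersect(igraph::V(g)$name, module_genes))
subnet <- extract_reference_subnetwork(g, reference)
cat(sprintf("subnetwork: %d nodes, %d edges\n",
            igraph::vcount(subnet), igraph::ecount(subnet)))

hub_ranks <- dplyr::bind_rows(rank_hubs(subnet, "degree"),
                              rank_hubs(subnet, "mnc"))
write_table_tsv(hub_ranks, file.path("results", "04_hub_ranks.tsv"))

tabs <- graph_tables(subnet)
write_table_tsv(tabs$nodes, file.path("results", "04_subnetwork_nodes.tsv"))
write_table_tsv(tabs$edges, file.path("results", "04_subnetwork_edges.tsv"))
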