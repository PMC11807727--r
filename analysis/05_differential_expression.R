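#!/usr/bin/env Rscript

# Stage 5: differential expression and subnetwork overlay.
#
# TMM normalization, dispersion estimation, the conditional NB exact test,
# the fold-change/FDR filter, and the DE overlay on the subnetwork.
# Requires: analysis/04_ppi_subnetwork.R

suppressMessages(library(painmodnet))

cd <- read_counts_tsv(file.path("results", "fixture", "counts.tsv"),
                      file.path("results", "fixture", "groups.tsv"))
fac <- tmm_factors(cd$counts)
disp <- estimate_dispersion(cd$counts, cd$groups, factors = fac)
cat(sprintf("common dispersion: %.4f\n", disp$common))

de <- nb_exact_test(cd$counts, cd$groups, dispersions = disp, factors = fac)
write_table_tsv(de, file.path("results", "05_differential_expression.tsv"))

degs <- filter_degs(de, fc_min = 1.5, fdr_max = 0.05)
cat(sprintf("DEGs at |FC| >= 1.5, FDR < 0.05: %d up, %d down\n",
            length(degs$up), length(degs$down)))

# overlay on the stage-4 subnetwork
edges <- read_interactions_tsv(file.path("results",
                                         "04_subnetwork_edges.tsv"))
nodes <- utils::read.delim(file.path("results", "04_subnetwork_nodes.tsv"))
subnet <- load_interactions(edges, score_threshold = 0)
subnet <- overlay_de(subnet, de, fc_min = 1.5, fdr_max = 0.05)
cat(sprintf("DE genes on the subnetwork: %d\n",
            igraph::graph_attr(subnet, "n_de")))
write_table_tsv(graph_tables(subnet)$nodes,
                file.path("results", "05_subnetwork_nodes_de.tsv"))
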