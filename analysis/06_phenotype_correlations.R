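#!/usr/bin/env Rscript

# Stage 6: phenotype correlation screen across the strain panels.
#
# Pearson screen of each subnetwork gene against every phenotype in every
# brain-region panel; per-gene significant-region counts and sign balance.
# Requires: analysis/05_differential_expression.R

suppressMessages(library(painmodnet))

panels <- read_panel_dir(file.path("results", "fixture", "panels"))
nodes <- utils::read.delim(file.path("results",
                                     "05_subnetwork_nodes_de.tsv"))
screen_genes <- intersect(nodes$node, rownames(panels[[1]]$expression))

correlations <- correlate_panels(panels, genes = screen_genes, alpha = 0.05)
write_table_tsv(correlations,
                file.path("results", "06_phenotype_correlations.tsv"))

counts <- count_significant(correlations)
write_table_tsv(counts$per_gene, file.path("results", "06_region_counts.tsv"))
balance <- sign_balance(correlations)
write_table_tsv(balance$overall, file.path("results", "06_sign_balance.tsv"))

pan4 <- pan_region_genes(correlations, 4)
cat(sprintf("genes significantly correlated in >= 4 regions: %d\n",
            length(pan4)))
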