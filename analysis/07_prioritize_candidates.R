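#!/usr/bin/env Rscript

# Stage 7: candidate shortlist.
#
# Four-criterion integration (subnetwork degree, differential expression,
# GWAS associations, pan-region correlation), direction consistency, and
# reference-set annotation.
# Requires: analysis/06_phenotype_correlations.R

suppressMessages(library(painmodnet))

nodes <- utils::read.delim(file.path("results",
                                     "05_subnetwork_nodes_de.tsv"))
de <- tibble::as_tibble(
  utils::read.delim(file.path("results", "05_differential_expression.tsv")))
gwas <- filter_gwas(
  read_associations_tsv(file.path("results", "fixture", "gwas.tsv")))
corr_counts <- tibble::as_tibble(
  utils::read.delim(file.path("results", "06_region_counts.tsv")))
balance <- tibble::as_tibble(
  utils::read.delim(file.path("results", "06_sign_balance.tsv")))
reference <- unique(unlist(
  read_gmt(file.path("results", "fixture", "reference.gmt"))$sets))

candidates <- shortlist_candidates(nodes, de, gwas, corr_counts,
                                   thresholds = shortlist_thresholds())
candidates <- direction_consistency(candidates, balance)
candidates <- annotate_reference(candidates, reference)

write_table_tsv(candidates, file.path("results", "07_candidates.tsv"))

short <- candidates[candidates$shortlist, ]
cat(sprintf("shortlisted candidates (%s):\n",
            attr(candidates, "summary")$text))
print(as.data.frame(short[, c("gene", "node_degree", "log2fc", "fdr",
                              "gwas_trait_count", "regions_correlated",
                              "consistent", "is_reference")]))
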