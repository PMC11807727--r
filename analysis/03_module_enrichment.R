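#!/usr/bin/env Rscript

# Stage 3: reference-set enrichment of the detected modules.
#
# Hypergeometric enrichment of each module against the curated reference
# gene set, picking the most enriched ("pain") module, plus pathway/TF
# over-representation of its members.
# Requires: analysis/02_coexpression_modules.R

suppressMessages(library(painmodnet))

asg <- utils::read.delim(file.path("results", "02_module_assignment.tsv"))
labels <- stats::setNames(as.integer(asg$module), asg$gene)
assignment <- structure(list(labels = labels), class = "module_assignment")

reference <- unique(unlist(
  read_gmt(file.path("results", "fixture", "reference.gmt"))$sets))

enrichment <- hypergeom_module_enrichment(assignment, reference)
print(enrichment)
write_table_tsv(enrichment, file.path("results", "03_module_enrichment.tsv"))

over <- enrichment[enrichment$direction == "over" & enrichment$fdr < 0.05, ]
pain_module <- if (nrow(over)) over$module[1] else enrichment$module[1]
cat(sprintf("selected pain module: %d\n", pain_module))

module_genes <- names(labels)[labels == pain_module]
universe <- names(labels)

pathways <- read_gmt(file.path("results", "fixture", "pathways.gmt"))
ora_pw <- ora(module_genes, pathways, universe, mode = "pathway")
write_table_tsv(ora_pw, file.path("results", "03_ora_pathway.tsv"))
net <- kappa_term_network(ora_pw, pathways, universe)
write_table_tsv(net$clusters, file.path("results", "03_term_clusters.tsv"))

tf <- read_gmt(file.path("results", "fixture", "tf_targets.gmt"))
ora_tf <- ora(module_genes, tf, universe, mode = "tf")
write_table_tsv(ora_tf, file.path("results", "03_ora_tf.tsv"))

writeLines(as.character(pain_module),
           file.path("results", "03_pain_module.txt"))
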