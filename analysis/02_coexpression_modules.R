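#!/usr/bin/env Rscript

# Stage 2: coexpression network and module detection.
#
# Soft-threshold scan, topological overlap, hierarchical module detection
# and eigengene-based merging on the fixture expression matrix.
# Requires: analysis/01_simulate_data.R

suppressMessages(library(painmodnet))

expr <- read_expression_tsv(file.path("results", "fixture", "expression.tsv"))
kept <- remove_outlier_samples(expr, height_cut = Inf)

scan <- pick_soft_threshold(kept$expr, powers = 1:20, r2_target = 0.8)
print(scan)
write_table_tsv(scan$scan, file.path("results", "02_soft_threshold_scan.tsv"))

tomx <- tom_from_expression(kept$expr, beta = scan$chosen_power)
pre <- detect_modules(tomx, min_module_size = 50)
assignment <- merge_close_modules(kept$expr, pre, cut_height = 0.25)
print(assignment)

write_table_tsv(
  tibble::tibble(gene = names(assignment$labels),
                 premerge_label = unname(pre$labels),
                 module = unname(assignment$labels),
                 color = unname(module_colors(assignment$labels))),
  file.path("results", "02_module_assignment.tsv"))
write_table_tsv(
  tibble::tibble(module = rownames(assignment$eigengenes),
                 as.data.frame(assignment$eigengenes)),
  file.path("results", "02_module_eigengenes.tsv"))
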