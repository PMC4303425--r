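#!/usr/bin/env Rscript
# Group-level constraint: disorder-adjusted LRT per gene set and tissue set,
# expression/conservation trends, disease-gene overlap and enrichment-map
# export tables.

source("analysis/00_common.R")

ub <- define_ubiquitous(cohort$expression)
sets <- c(cohort$gene_sets, list(ubiquitous = ub$ubiquitous),
          ub$tissue_sets[lengths(ub$tissue_sets) >= 5])
gt <- run_group_tests(features, sets)
disease_genes <- unique(cohort$disease$protein[
  in_ptm_region(cohort$disease$protein, cohort$disease$position, regions)])
ov <- disease_overlap(gt, sets, disease_genes, unique(features$protein))
em <- enrichment_map_export(gt, sets, ov)
expr_tr <- binned_trend(features, apply(cohort$expression, 1, median), 50L)
consv_tr <- binned_trend(features, vapply(cohort$conservation, median, 0), 50L)

write_tsv(gt, file.path(RESULTS, "context_groups.tsv"))
write_tsv(ov, file.path(RESULTS, "context_disease_overlap.tsv"))
write_tsv(em$nodes, file.path(RESULTS, "enrichment_map_nodes.tsv"))
if (!is.null(em$edges)) write_tsv(em$edges, file.path(RESULTS, "enrichment_map_edges.tsv"))
write_tsv(expr_tr$bin_table, file.path(RESULTS, "expression_trend.tsv"))
write_tsv(consv_tr$bin_table, file.path(RESULTS, "conservation_trend.tsv"))
write_tsv(disease_word_frequencies(cohort$disease, disease_genes),
          file.path(RESULTS, "disease_word_frequencies.tsv"))

cat(sum(gt$q < 0.05), "of", nrow(gt), "groups significant;",
    round(100 * mean(gt$direction[gt$q < 0.05] == "negative")),
    "% show negative selection in PTM regions\n")
cat(sprintf("expression trend r = %.3f (p = %.3g); conservation trend r = %.3f (p = %.3g)\n",
            expr_tr$r, expr_tr$p_value, consv_tr$r, consv_tr$p_value))
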