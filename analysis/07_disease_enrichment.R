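#!/usr/bin/env Rscript
# Disease-mutation enrichment in PTM regions (Fisher by structure class,
# Poisson with multiplicities, amino-acid-matched central residues) and the
# per-gene mutation-hotspot model.

source("analysis/00_common.R")

rf <- region_enrichment_fisher(cohort, regions)
rp <- region_enrichment_poisson(cohort, regions)
ce <- central_residue_enrichment(cohort)
ad <- active_driver(cohort, regions)
cancer <- unique(cohort$disease$protein[
  cohort$disease$disease %in% c("leukemia", "carcinoma")])
cg <- cancer_gene_enrichment(ad$protein[ad$gene_q < 0.05], cancer, ad$protein)

write_tsv(rf, file.path(RESULTS, "disease_fisher.tsv"))
write_tsv(rp, file.path(RESULTS, "disease_poisson.tsv"))
write_tsv(ce, file.path(RESULTS, "disease_central_residues.tsv"))
write_tsv(ad, file.path(RESULTS, "active_driver.tsv"))
write_tsv(attr(ad, "region_table"), file.path(RESULTS, "active_driver_regions.tsv"))

for (i in seq_len(nrow(rf))) {
  cat(sprintf("%s: OR %.2f, Fisher p = %.3g\n", rf$stratum[i],
              rf$odds_ratio[i], rf$p[i]))
}
cat(sprintf("Poisson: %d annotations in regions vs %.1f +/- %.1f expected (p = %.3g)\n",
            rp$observed, rp$expected, rp$expected_sd, rp$p))
sig <- ad[ad$gene_q < 0.05, ]
cat(nrow(sig), "hotspot-significant genes at FDR < 0.05; planted:",
    paste(cohort$truth$planted_hotspots$protein, collapse = ","), "\n")
cat(sprintf("cancer-gene overlap: OR %.2f, p = %.3g\n",
            cg$odds_ratio, cg$p_value))
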