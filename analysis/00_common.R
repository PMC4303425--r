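# Shared prologue for the analysis drivers: loads the simulated cohort
# written by 01_simulate.R and rebuilds the cheap intermediates every stage
# needs (regions, annotated substitutions, per-substitution features).

library(ptmvar)

RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
if (!dir.exists(COHORT_DIR)) {
  stop("cohort not found under ", COHORT_DIR,
       " -- run analysis/01_simulate.R first")
}

cohort <- read_cohort(COHORT_DIR)
regions <- build_regions(cohort$ptm_sites, cohort$proteins)
zones <- classify_zones(regions, cohort$ptm_sites)
clusters <- cluster_bins(regions, cohort$ptm_sites)
subs <- classify_rare(filter_codon_conflicts(
  annotate_variants(cohort$variants, cohort$gene_models)))
features <- build_feature_table(cohort, subs, regions, zones)
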