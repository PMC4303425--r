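#!/usr/bin/env Rscript
# Simulate the demo cohort: 300 proteins with a planted rare-substitution
# odds effect of 2 in PTM regions, a planted consensus motif for one kinase,
# and three planted disease-mutation hotspots. Everything downstream reads
# this cohort from results/cohort/.

library(ptmvar)

cfg <- demo_config(seed = 42L)
cohort <- generate_cohort(cfg)
cohort <- plant_motif_breakers(cohort, names(cohort$pwms)[1], 20L)
# heavily annotated disease genes carry dozens of records in one region;
# at the demo's sparse background rate that corresponds to a large density
# multiplier
for (i in 1:3) {
  cand <- setdiff(unique(cohort$ptm_sites$protein),
                  cohort$truth$planted_hotspots$protein)
  cohort <- plant_mutation_hotspot(cohort, protein = cand[i], multiplier = 25)
}

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, file.path("results", "cohort"))
print(cohort)
cat("planted: odds effect", cfg$ptm_constraint_effect, "on rare substitutions;",
    nrow(cohort$truth$planted_motifs), "consensus motif sites;",
    nrow(cohort$truth$planted_hotspots), "mutation hotspots\n")
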