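#!/usr/bin/env Rscript
# Build merged PTM regions with zone/cluster labels and annotate the
# cohort's coding variants to protein substitutions.

source("analysis/00_common.R")

write_tsv(regions, file.path(RESULTS, "regions.tsv"))
write_tsv(zones, file.path(RESULTS, "zones.tsv"))
write_tsv(clusters, file.path(RESULTS, "clusters.tsv"))
write_tsv(subs[subs$status != "rejected", ], file.path(RESULTS, "substitutions.tsv"))

cat(nrow(regions), "PTM regions covering",
    round(100 * sum(regions$end - regions$start + 1) /
            sum(nchar(cohort$proteins)), 1),
    "% of total sequence;",
    round(100 * mean(regions$n_sites > 1)), "% have multiple sites\n")
cat(sum(subs$status == "nonsyn"), "non-synonymous and",
    sum(subs$status == "syn"), "synonymous substitutions;",
    sum(subs$status == "rejected"), "records rejected\n")
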