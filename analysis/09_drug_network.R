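#!/usr/bin/env Rscript
# Drug -> PTM enzyme -> disease gene -> disease paths through
# hotspot-significant genes, with the (drug, disease) pair summary that
# doubles as a literature-query list.

source("analysis/00_common.R")

ad <- active_driver(cohort, regions)
dn <- assemble_drug_network(ad, cohort$ptm_sites, cohort$drug_links,
                            cohort$disease)
pairs <- pair_summary(dn$paths)

if (!is.null(dn$paths)) {
  write_tsv(dn$paths, file.path(RESULTS, "drug_disease_paths.tsv"))
  write_tsv(pairs, file.path(RESULTS, "drug_disease_pairs.tsv"))
  write_tsv(dn$nodes, file.path(RESULTS, "drug_network_nodes.tsv"))
  write_tsv(dn$edges, file.path(RESULTS, "drug_network_edges.tsv"))
}
cat(if (is.null(dn$paths)) 0L else nrow(dn$paths), "paths over",
    nrow(pairs), "distinct (drug, disease) pairs;",
    length(dn$dangling), "enzymes lacked a drug\n")
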