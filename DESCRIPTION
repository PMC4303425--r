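Package: ptmvar
Title: Evolutionary Constraint and Disease Association of Post-Translational
    Modification Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantifying negative selection and disease
    mutation enrichment in post-translational modification (PTM) regions of
    protein-coding genes. Maps PTM peptides onto proteins, builds merged
    +/-7-residue PTM regions with zone and cluster labels, annotates coding
    variants to protein substitutions with derived allele frequency classes,
    computes rare-variant fractions and Ka/Ks with matched-bin paired Wilcoxon
    tests, fits confounder-adjusted logistic models with deviance ranking,
    runs amino-acid-weighted permutation nulls, scores kinase position weight
    matrices to enumerate motif-breaker residues, detects per-gene PTM
    mutation hotspots with a Poisson regression model, and assembles
    drug-enzyme-gene-disease networks. Includes a synthetic-cohort generator
    with planted effects for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
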