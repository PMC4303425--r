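# ptmvar

Evolutionary constraint and disease association of post-translational
modification (PTM) regions in protein-coding genes.

PTMs — phosphorylation (S/T/Y), ubiquitination and acetylation (K),
methylation (K/R) — are molecular switches recognised through short linear
motifs in the ±7 residues around the modified site. `ptmvar` asks whether
these **PTM regions** (modified residue ± 7 flanking residues, overlapping
windows merged) are under negative selection in population variation data
and enriched in disease mutations, and turns the full analysis into a
tested, reusable R pipeline:

* **Regions** — peptide-to-proteome mapping, merged ±7 windows, zone labels
  (DI = modified residue, N1 = ±1–2, N2 = ±3–7) and cluster bins (number of
  adjacent sites within ±7, capped at 5+).
* **Variants** — direct codon translation of coding SNVs on gene models;
  stop-gains/indels rejected; same-codon non-synonymous conflicts filtered;
  rare = derived allele frequency ≤ 0.5% (inclusive, configurable).
* **Selection** — rare-substitution fraction and Ka/Ks (fractional
  synonymous/non-synonymous site counting per codon, stop changes excluded),
  compared between PTM and non-PTM sequence across 100 variation-matched
  protein bins with paired one-sided Wilcoxon signed-rank tests (exact null
  by enumeration for small bin counts, ties handled).
* **Confounders** — binomial logistic models of rare vs common with
  conservation, codon degeneracy, GC content, depth, recombination rate and
  disorder plus interactions; backward AIC selection; deviance ranking with
  the PTM term assessed by likelihood ratio.
* **Permutation nulls** — expected rare fractions from 1000-fold sampling of
  background residues matching the test set's amino-acid composition
  exactly, without replacement, add-one p-values.
* **Kinase motifs** — PWM scoring of phosphosite flanks, calibration against
  positive/negative controls (10th/90th percentiles), exhaustive-substitution
  **motif-breaker** enumeration (≥ 4-fold score loss), kinase-level
  selection/disease tests and a kinase–substrate network with a disease-gene
  degree test.
* **Disease** — Fisher (structure-split) and Poisson enrichment of disease
  annotations in regions, amino-acid-matched central-residue binomial tests,
  and a per-gene Poisson-regression mutation-hotspot model with
  disorder confounding, Fisher-combined region p-values and BH FDR.
* **Context** — disorder-adjusted likelihood-ratio tests per gene set /
  tissue set, expression and conservation trends, enrichment-map and
  word-cloud export tables.
* **Drug network** — drug → PTM enzyme → disease gene → disease path
  enumeration through hotspot-significant genes.

Real resources of this kind (exome cohorts, disease-mutation databases, PTM
compendia, drug–target databases) are licensed or large, so the package
ships a first-class **synthetic-cohort generator** (`generate_cohort()`)
that emulates their statistical structure with planted, recoverable effects:
an odds multiplier on rare substitutions inside PTM regions, a disease
annotation odds multiplier, kinase PWMs with planted specificity, plantable
consensus motif sites and mutation hotspots. Every analysis is validated by
parameter recovery against that generator and by exact brute-force oracles.

## Worked example

The `analysis/` directory is a numbered end-to-end study over a bundled
synthetic demo (300 proteins, planted rare-substitution odds effect 2, one
planted consensus motif, three planted mutation hotspots):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_regions_and_annotation.R
Rscript analysis/03_selection.R
# ... through analysis/09_drug_network.R
```

Output of the first stages (tables land under `results/`):

```
ptmvar synthetic cohort: 300 proteins, 2321 PTM sites, 8950 variants, 1357 disease annotations, 6 PWMs
1734 PTM regions covering 25.1 % of total sequence; 26 % have multiple sites
6523 non-synonymous and 2154 synonymous substitutions; 0 records rejected
rare fraction: PTM 0.578 vs non-PTM 0.397 (paired Wilcoxon p = 2.6e-14)
Ka/Ks: PTM 0.963 vs non-PTM 0.947 (paired Wilcoxon p = 0.746)
PTM term: delta deviance 159.4 (df 3), LRT p = 2.43e-34, sign +, rank 1 of 4
main-effects fit recovers log-odds 0.727 +/- 0.059 (planted 0.693)
```

Reading: the planted constraint (odds 2 ⇒ log-odds 0.693) surfaces as a
higher rare fraction in PTM regions (0.578 vs 0.397), is recovered by the
confounder-adjusted logistic model within one standard error, and ranks as
the strongest predictor by deviance. Ka/Ks is flat by design — the
generator plants no non-synonymous depletion — so its null test result is
the correct answer. The permutation stage then shows the zone gradient
(DI/N1/N2 all enriched against amino-acid-matched expectation), the motif
stage recovers 100% of planted consensus sites as bound, and the disease
stage flags the planted hotspot genes, which feed the drug–disease network.

The same machinery runs on real inputs: proteins as FASTA, PTM sites or
15-mer peptides as TSV, coding variants with DAF as a VCF-like TSV, disorder
intervals, conservation, disease annotations, GMT gene sets, PWM matrices
and drug–enzyme links — see `read_cohort()` for the directory layout and the
roxygen documentation of each stage function.

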