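---
title: "Methods: evolutionary constraint and disease association of PTM regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary constraint and disease association of PTM regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Post-translational modifications (PTMs) — phosphorylation of S/T/Y,
ubiquitination and acetylation of K, methylation of K/R — are molecular
switches read and written by enzymes that recognise short linear motifs in
the ±7 residues flanking the modified residue. If these regions are
functionally important, protein-coding variants inside them should be under
measurable negative selection in human populations, and disease mutations
should concentrate there. `ptmvar` implements the full chain of analyses
needed to test that hypothesis: region construction, variant annotation,
selection statistics, confounder-adjusted regression, composition-matched
permutation nulls, kinase motif-breaker prediction, a per-gene mutation
hotspot model, and a drug–enzyme–gene–disease network.

Because the analyses were designed against licensed or large external
resources (exome cohorts, disease-mutation databases, PTM compendia), the
package ships a first-class synthetic-cohort generator that emulates the
*statistical structure* those resources provide, with planted effects whose
recovery is the package's test surface.

## PTM regions, zones and clusters

A PTM region is the union of closed intervals `[pos − 7, pos + 7]` around
modified residues, clipped to the protein and merged whenever two windows
share at least one residue. Windows that touch end-to-start without sharing
a residue are *not* merged — the merge criterion is overlapping sequence.
Residues inside a region carry two labels:

* **zone** — distance to the nearest modified residue: `DI` (the modified
  residue itself), `N1` (1–2 residues), `N2` (3–7 residues);
* **cluster bin** — the number of modified residues within ±7, capped at
  "5+".

A residue modified by two PTM types is one site with a type set; region site
counts never double-count positions. Interval arithmetic is delegated to
`IRanges::reduce()` on a per-cohort global coordinate axis.

## Variant annotation and selection metrics

Gene models are single-exon, in-frame CDS strings (codon *k* encodes residue
*k*); splicing and strand add nothing to the statistics under test. Each SNV
is translated directly through the standard genetic code: stop-gains,
indel-like records, reference mismatches and positions outside the CDS are
rejected with a reason. Non-synonymous variants sharing a codon are removed
(allele frequencies at such codons are ambiguous at the protein level); the
synonymous partner in such a codon is kept. "Rare" means derived allele
frequency ≤ 0.5%, boundary inclusive, with the threshold configurable.

Two selection metrics are computed per stratum:

* **rare fraction** — rare / all non-synonymous substitutions;
* **Ka/Ks** — non-synonymous variants per non-synonymous site over
  synonymous variants per synonymous site, with fractional site counts: each
  of a codon's nine single-nucleotide changes contributes 1/3 site to the
  class of its translated effect, and changes creating a stop codon are
  excluded from both classes (the standard proportional site-counting
  estimator). Exhaustive enumeration over the 64 codons is frozen into the
  test suite against an independent brute-force oracle.

PTM and non-PTM sequence are compared within 100 bins of proteins matched on
substitution rate (substituted residues per residue; remainder proteins go
to the leading bins, ties break on identifier). The per-bin paired
differences feed a one-sided Wilcoxon signed-rank test: zero differences are
dropped; for ≤ 25 informative pairs the exact null distribution is computed
by dynamic programming over sign assignments (correct under tied ranks);
above that the normal approximation with continuity correction is used.
Proteins without PTM sites are excluded by default (they are systematically
less variable), with an all-proteins switch.

## The confounder-adjusted model

The binomial logistic null model explains the rare/common class from six
covariates — alignment-style conservation (mean BLOSUM62 score against the
column, gaps −10), codon degeneracy, GC content of the 35 bp window around
the variant, sequencing depth (omitted when a cohort has none), nearest
measured recombination rate, and protein disorder — plus their interactions
up to a configurable order (default 2; a full factorial is combinatorially
explosive and numerically fragile). The alternative model adds the binary
PTM-region flag and its interactions. Continuous covariates are standardized
before interaction construction. The alternative fit is then challenged by
backward selection under AIC (`stats::step`), which respects marginality.
Note that AIC retains a 1-df pure-noise term with asymptotic probability
P(χ²₁ > 2) ≈ 0.16, so the expected drop rate of a junk covariate is ≈ 84%,
and the test suite gates on that rate's actual sampling band. The PTM
contribution is the likelihood-ratio chi-square of the alternative over the
matched null; other predictors are ranked by single-term-deletion deviance
with signs from their coefficients.

## Amino-acid-weighted permutation null

Amino acids differ in codon redundancy, so a residue subset (a zone, a PTM
type, a cluster bin, a kinase's motif-breaker set) cannot be compared
against unmatched background. The permutation null samples, without
replacement and excluding the test set, background residue sets with exactly
the test set's per-amino-acid composition, from the residues of proteins
carrying the relevant PTM type; flank-zone tests additionally exclude
modified residues from the background. The statistic (default: rare
substitutions over all substitutions at the sampled residues) is evaluated
over `n_perm` draws (default 1000) and the one-sided p-value uses the
add-one estimator `(1 + #extreme)/(n_perm + 1)`, which cannot return zero.
On fixtures where every residue carries exactly one substitution the
permutation mean provably converges to the stratified hypergeometric
expectation, and the tests assert that agreement within Monte-Carlo error.
Reported spread is the permutation standard deviation, labelled as such.

## Kinase motifs and motif-breakers

A kinase PWM is a 15 × 20 column-stochastic matrix centred on the
phosphoacceptor. Scores are products of per-position probabilities
(computed in log space), after adding a pseudocount of 10⁻³ and
renormalizing; terminal windows are padded with a neutral symbol scoring the
column mean. Calibration takes the 10th percentile of positive-control
scores (flanks of sites annotated to the kinase) and the 90th percentile of
negative controls (windows on non-phosphorylated S/T/Y centres), both as
type-7 quantiles; a site is predicted bound iff its score ≥ the larger of
the two (boundary inclusive). For every bound window, exhaustive
substitution of each flank position identifies **motif-breakers**: residues
for which some substitution reduces the score ≥ 4-fold (inclusive; the fold
change is the ratio of pseudocounted column probabilities, so
fold(wt→mut) × fold(mut→wt) = 1). Per kinase, breaker residues are tested
for rare-variant enrichment with the permutation null against the
phosphoprotein background and for disease-annotation enrichment with
one-sided Fisher tests, BH-adjusted across kinases. Bound sites form a
bipartite kinase–substrate network; substrate degree of disease genes vs
others is compared with a one-sided rank-sum test.

## Disease enrichment and the hotspot model

Residue-level enrichment of disease annotations in PTM regions uses
one-sided Fisher tests split by structure class (disordered vs structured),
reporting the sample cross-product odds ratio next to the exact
hypergeometric p. A Poisson test on annotation totals accounts for
multiplicity (`n_records` per residue as the proxy of mutation frequency):
expected = total × region share of residues, p = inclusive upper tail,
spread = √expected. Central-residue enrichment compares annotation of
modified residues against amino-acid-matched residues (S/T/Y, K, or K/R) of
proteins carrying that PTM type, with an exact binomial upper tail.

The hotspot model fits, per protein, per-residue mutation-record counts with
a Poisson log-linear model carrying the disorder flag as confounder
(intercept-only fallback on degenerate proteins), and compares each region's
observed total against its model-expected total. Region p-values use the
**mid-p** upper tail, P[X > obs] + ½·P[X = obs], including for zero-mutation
regions: the inclusive tail is stochastically larger than uniform for
discrete counts, and forcing zero-mutation regions to p = 1 measurably
breaks the gene-level null calibration that the hotspot FDR depends on
(measured KS distance ~0.11–0.12 against ~0.06–0.08 with the uniform mid-p
treatment). A zero-mutation region's mid-p sits just below 1, so such
regions can never rank as hotspots. Gene-level p is Fisher's combined
probability over region p-values (alternatives such as Brown's method or
minimum-p Bonferroni are deliberate non-defaults), BH-adjusted across genes
at FDR 0.05. Cancer-gene overlap among significant genes uses a one-sided
Fisher test.

## Group-level context

Per protein group (gene sets from GMT files with 5–1000 members, inclusive;
tissue sets; the ubiquitous set) the test is a 1-df likelihood-ratio
chi-square between `rare ~ disorder` and `rare ~ disorder + PTM`, with the
direction read off the PTM coefficient and BH adjustment across groups.
"High expression in a tissue" is a per-gene robust z-score across tissues,
(x − median)/(1.4826·MAD) ≥ 2; ubiquitous genes are high in ≥ 18 tissues and
leave every tissue-specific set; constant-expression genes (MAD 0) are
excluded and reported; numbered tissue replicates are merged by suffix.
Binned trends split proteins into equal-size bins of median expression or
conservation and correlate the per-bin log2 ratio of observed PTM rare
fraction over the disorder-model expectation (with model-prediction standard
errors) against the bin median covariate (Pearson). Enrichment-map export
writes node/edge tables with Jaccard ≥ 0.25 edges; word-cloud input is a
disease-label frequency table.

## Drug–disease network

Paths drug → enzyme → gene → disease are the relational join of: drugs
targeting an enzyme; enzymes experimentally annotated on a PTM site of a
hotspot-significant gene (gene FDR < 0.05) whose site lies in a
significantly mutated region (region p < 0.05) holding disease annotations;
and those annotations' disease labels. Paths are deduplicated; the
(drug, disease) pair summary doubles as the literature-query export.
Dangling identifiers are reported, never fatal.

## The synthetic cohort: what it emulates and what it does not

Defaults are the package's reference study conditions, chosen once to
mirror the scale of human PTM proteomics and exome data: ~2 PTM sites per
100 residues with phosphorylation at 72% of sites; disordered intervals
covering ~35% of residues with PTM placement preferring disorder at odds 2;
~8 substitutions per 100 residues with a Gamma-distributed per-protein rate
(so variation-matched binning has structure to match); rare fraction 0.4
outside PTM regions; DAF uniform within the rare (≤ 0.5%) and common bands;
depth negative-binomial around 60×. The planted constraint multiplies the
*odds* of rareness for non-synonymous variants inside PTM regions; with
base 0.5 and multiplier 3 the region rare fraction converges to 0.75
analytically, which the tests exploit. Conservation is simulated as
BLOSUM62-scored alignment columns with noise, systematically lower in
disorder — a correlated but (by default) causally inert covariate, so the
regression must separate it from the PTM flag. Disease annotations carry an
analogous odds multiplier inside regions. PWMs have four informative columns
(preferred-residue mass 0.8 by default) and an S/T/Y acceptor column;
enzyme-annotated phosphosites have their flanks drawn from the assigned
kinase's PWM, which supplies calibration positives.

Deliberate simplifications, hence what green tests do *not* show about real
data: no linkage or demography behind the DAF distribution; single-exon
forward-strand gene models; no planted depletion of non-synonymous variants
inside regions (so Ka/Ks contrasts are null under the generator — its
machinery is exercised by the codon-level oracles instead); disease labels
are exchangeable tokens; expression classes (flat / tissue-specific / broad)
are stylized. Parameter-recovery tests validate the statistical machinery,
not the biology of any particular cohort.

Scale choices used by the tests and the acceptance script, chosen to make
sampling error negligible relative to the planted effects: selection power
runs use 1,000-protein cohorts (20 seeds, effect 3); null calibration uses
300-protein cohorts over 100 seeds with 50 bins (the test statistic's
calibration does not depend on cohort size); hotspot recovery uses
40-protein cohorts with a densely annotated background (0.15 records per
residue, mirroring heavily curated disease genes) over 50 replicates, and a
220-protein null for the uniformity check; the bundled demo is 300 proteins.

## Numerical and degenerate-input policy

Exact tests include the observed value in their upper tails (the hotspot
model's mid-p is the single documented exception, above). Quantiles are
type-7 throughout. All tie-breaks are deterministic: equidistant
recombination loci resolve to the lower coordinate, equal variation rates
sort by protein identifier, the exact signed-rank null handles tied ranks by
enumeration. Degenerate inputs fail loudly and specifically: configs are
validated field by field, peptides with type-incompatible centres are
rejected with reasons, groups without both response classes are skipped and
reported, empty recombination tracks and empty universes are errors. Every
output table carries the package version, an MD5 hash of the generating
configuration and the seed, and rerunning any stage with the same
configuration is byte-identical.
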