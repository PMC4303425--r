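# Generator contracts: validation, determinism, structural invariants and
# realization of the planted effects.

test_that("degenerate configs are rejected with the offending field named", {
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(length_dist = c(mean = -5, sd = 1)), "length_dist")
  expect_error(simulation_config(ptm_constraint_effect = 0), "ptm_constraint_effect")
  expect_error(simulation_config(ptm_type_mix = c(phospho = 0.9, ubiq = 0.2,
                                                  acet = 0, methyl = 0)),
               "ptm_type_mix")
  expect_error(simulation_config(aa_freqs = rep(0.05, 19)), "aa_freqs")
})

test_that("the same seed reproduces a byte-identical cohort on disk", {
  c1 <- small_cohort(seed = 21L)
  c2 <- small_cohort(seed = 21L)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort files round-trip through the readers", {
  ch <- small_cohort(seed = 22L)
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(ch, d)
  back <- read_cohort(d)
  expect_identical(back$proteins, ch$proteins)
  expect_identical(back$gene_models, ch$gene_models)
  expect_equal(nrow(back$variants), nrow(ch$variants))
  expect_equal(back$truth$ptm_constraint_effect, ch$truth$ptm_constraint_effect)
  expect_equal(back$pwms[[1]]$matrix, round(ch$pwms[[1]]$matrix, 6),
               tolerance = 1e-9, ignore_attr = TRUE)
  unlink(d, recursive = TRUE)
})

test_that("structural invariants hold: sites match sequences, variants map to codons", {
  ch <- small_cohort(seed = 23L)
  expect_silent(validate_sites(ch$ptm_sites, ch$proteins))
  # every gene model translates to its protein
  for (p in names(ch$proteins)[1:5]) {
    expect_equal(translate_cds(ch$gene_models[[p]]), ch$proteins[[p]])
  }
  # every variant's reference base matches its CDS position
  ref <- substring(ch$gene_models[ch$variants$chrom], ch$variants$pos, ch$variants$pos)
  expect_equal(unname(ref), ch$variants$ref)
  expect_true(all(ch$variants$daf > 0 & ch$variants$daf <= 0.5))
})

test_that("amino-acid composition tracks the configured frequencies", {
  ch <- generate_cohort(simulation_config(n_proteins = 150, enzyme_rate = 0,
                                          seed = 24L))
  chars <- unlist(strsplit(paste(ch$proteins, collapse = ""), ""))
  n <- length(chars)
  f_obs <- table(factor(chars, levels = AA_ALPHABET)) / n
  f_exp <- default_aa_freqs()
  se <- sqrt(f_exp * (1 - f_exp) / n)
  expect_true(all(abs(f_obs - f_exp) < 3.5 * se + 1e-4))
})

test_that("a null constraint effect leaves PTM and non-PTM rare fractions level", {
  ch <- generate_cohort(simulation_config(n_proteins = 400,
                                          ptm_constraint_effect = 1.0, seed = 25L))
  ann <- classify_rare(annotate_variants(ch$variants, ch$gene_models))
  rg <- build_regions(ch$ptm_sites, ch$proteins)
  ns <- ann[ann$status == "nonsyn", ]
  inr <- in_ptm_region(ns$protein, ns$residue_index, rg)
  p1 <- mean(ns$is_rare[inr]); n1 <- sum(inr)
  p0 <- mean(ns$is_rare[!inr]); n0 <- sum(!inr)
  se <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("an odds multiplier of 3 at base 0.5 drives the PTM rare fraction to 0.75", {
  # odds 1:1 x 3 = 3:1 -> 0.75
  ch <- generate_cohort(simulation_config(n_proteins = 500,
                                          rare_fraction_base = 0.5,
                                          ptm_constraint_effect = 3.0, seed = 26L))
  ann <- classify_rare(annotate_variants(ch$variants, ch$gene_models))
  rg <- build_regions(ch$ptm_sites, ch$proteins)
  ns <- ann[ann$status == "nonsyn", ]
  inr <- in_ptm_region(ns$protein, ns$residue_index, rg)
  p1 <- mean(ns$is_rare[inr])
  se <- sqrt(0.75 * 0.25 / sum(inr))
  expect_lt(abs(p1 - 0.75), 3 * se)
  expect_lt(abs(mean(ns$is_rare[!inr]) - 0.5), 3 * sqrt(0.25 / sum(!inr)))
})

test_that("a logistic fit on a large cohort recovers the planted log-odds", {
  ch <- generate_cohort(simulation_config(n_proteins = 800,
                                          ptm_constraint_effect = 2.5, seed = 27L))
  ann <- classify_rare(filter_codon_conflicts(annotate_variants(ch$variants, ch$gene_models)))
  rg <- build_regions(ch$ptm_sites, ch$proteins)
  ns <- ann[ann$status == "nonsyn", ]
  ns$ptm <- in_ptm_region(ns$protein, ns$residue_index, rg)
  fit <- glm(is_rare ~ ptm, family = binomial(), data = ns)
  est <- summary(fit)$coefficients["ptmTRUE", ]
  expect_lt(abs(est[["Estimate"]] - log(2.5)), 3 * est[["Std. Error"]])
})

test_that("motif planting embeds the consensus, updates models and truth", {
  ch <- small_cohort(seed = 28L, n = 60L)
  kin <- names(ch$pwms)[1]
  # n_sites = 0: unchanged except the truth entry
  ch0 <- plant_motif_breakers(ch, kin, 0L)
  expect_identical(ch0$proteins, ch$proteins)
  expect_identical(ch0$variants, ch$variants)

  ch2 <- plant_motif_breakers(ch, kin, 5L)
  planted <- ch2$truth$planted_motifs
  expect_equal(nrow(planted), 5L)
  cons <- pwm_consensus(ch2$pwms[[kin]])
  for (j in seq_len(nrow(planted))) {
    w <- substring(ch2$proteins[[planted$protein[j]]],
                   planted$position[j] - 7L, planted$position[j] + 7L)
    wc <- strsplit(w, "")[[1]]
    expect_equal(wc[-8], cons[-8])  # flanks are consensus; centre untouched
    # gene model stays consistent with the edited protein
    expect_equal(translate_cds(ch2$gene_models[[planted$protein[j]]]),
                 ch2$proteins[[planted$protein[j]]])
  }
  # remaining variants still match their (possibly rewritten) CDS
  ref <- substring(ch2$gene_models[ch2$variants$chrom], ch2$variants$pos,
                   ch2$variants$pos)
  expect_equal(unname(ref), ch2$variants$ref)
  expect_error(plant_motif_breakers(ch, kin, 10000L), "not enough")
  expect_error(plant_motif_breakers(ch, "NOKIN", 1L), "unknown PWM")
})
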