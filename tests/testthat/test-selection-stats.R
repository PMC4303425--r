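# Selection metrics: percentile binning, fractional site counting, the
# paired signed-rank test against enumeration oracles, and aggregation
# identities.

test_that("variation binning splits sorted proteins with the stated remainder rule", {
  ps <- data.frame(protein = sprintf("P%03d", 1:200), length = 100L,
                   n_sub_residues = 1:200, variation_rate = (1:200) / 100)
  b <- bin_by_variation(ps, 100L)
  expect_equal(as.integer(table(b$bin)), rep(2L, 100))
  expect_true(!is.unsorted(b$variation_rate))
  # 201 proteins: remainder goes to the first bin
  ps2 <- rbind(ps, data.frame(protein = "P201", length = 100L,
                              n_sub_residues = 5L, variation_rate = 0.05))
  b2 <- bin_by_variation(ps2, 100L)
  expect_equal(as.integer(table(b2$bin))[1], 3L)
  expect_equal(as.integer(table(b2$bin))[2], 2L)
  # equal rates: deterministic placement by identifier
  ps3 <- ps; ps3$variation_rate <- 1
  b3a <- bin_by_variation(ps3, 100L); b3b <- bin_by_variation(ps3, 100L)
  expect_identical(b3a, b3b)
  expect_equal(b3a$protein, sort(ps3$protein))
  expect_error(bin_by_variation(ps[1:50, ], 100L), "fewer proteins")
})

test_that("ka/ks handles zero-site and zero-variant strata", {
  # Met-only sequence: no synonymous sites -> ratio undefined
  st <- codon_site_table()
  met <- st[st$codon == "ATG", ]
  expect_equal(met$syn_sites, 0)
  expect_equal(met$nonsyn_sites, 3)
  kk <- ka_ks(2, 0, nonsyn_sites = 3, syn_sites = 0)
  expect_true(is.na(kk$ka_ks))
  # single GGG codon: 1 synonymous site; one observed syn variant -> ks = 1
  ggg <- st[st$codon == "GGG", ]
  expect_equal(ggg$syn_sites, 1)
  kk2 <- ka_ks(0, 1, ggg$nonsyn_sites, ggg$syn_sites)
  expect_equal(kk2$ks, 1)
  # zero variants: ka = ks = 0, ratio undefined
  kk3 <- ka_ks(0, 0, 2, 1)
  expect_equal(c(kk3$ka, kk3$ks), c(0, 0))
  expect_true(is.na(kk3$ka_ks))
})

test_that("paired signed-rank test matches brute-force sign enumeration", {
  # d = (+1, +2, -1): enumerate all 2^3 sign assignments of tied ranks
  p <- paired_bin_test(c(2, 3, 0), c(1, 1, 1), "greater", min_pairs = 3L)
  d <- c(1, 2, -1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:7, function(m) {
    signs <- as.integer(intToBits(m))[1:3]
    sum(r[signs == 1L])
  }, 0)
  expect_equal(p$p_value, mean(vs >= v_obs))
  # a larger tie-free case against wilcox.test's exact null
  set.seed(77)
  x <- rnorm(12); y <- rnorm(12)
  keep <- x != y
  ours <- paired_bin_test(x, y, "greater")
  ref <- stats::wilcox.test(x[keep], y[keep], paired = TRUE,
                            alternative = "greater", exact = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate pairings are reported, extreme ones reject strongly", {
  expect_warning(res <- paired_bin_test(rep(1, 10), rep(1, 10)), "informative")
  expect_true(is.na(res$p_value))
  expect_equal(res$n_informative, 0L)
  # PTM side above non-PTM in all 100 bins
  res2 <- paired_bin_test(seq(0.5, 0.6, length.out = 100),
                          seq(0.4, 0.5, length.out = 100) - 0.01, "greater")
  expect_lt(res2$p_value, 1e-10)
})

test_that("stratified summaries partition substitution counts", {
  ch <- small_cohort(seed = 31L, n = 50L)
  ann <- classify_rare(filter_codon_conflicts(annotate_variants(ch$variants, ch$gene_models)))
  rg <- build_regions(ch$ptm_sites, ch$proteins)
  pp <- per_protein_selection(ch, ann, rg)
  sm <- stratified_summaries(pp)
  all_cells <- sm[sm$structure == "all", ]
  expect_equal(sum(all_cells$n_nonsyn), sum(ann$status == "nonsyn"))
  expect_equal(sum(all_cells$n_syn), sum(ann$status == "syn"))
  # structured + disordered = all, per region class
  for (reg in c("ptm", "nonptm")) {
    expect_equal(sum(sm$n_nonsyn[sm$structure != "all" & sm$region == reg]),
                 sm$n_nonsyn[sm$structure == "all" & sm$region == reg])
  }
  # site totals equal whole-protein site totals
  st <- codon_site_table()
  total_sites <- sum(pp$syn_sites) + sum(pp$nonsyn_sites)
  expected <- sum(vapply(names(ch$proteins), function(p) {
    L <- nchar(ch$proteins[[p]])
    cdn <- substring(ch$gene_models[[p]], seq(1, 3 * L, 3), seq(3, 3 * L, 3))
    m <- match(cdn, st$codon)
    sum(st$syn_sites[m]) + sum(st$nonsyn_sites[m])
  }, 0))
  expect_equal(total_sites, expected, tolerance = 1e-9)
})

test_that("overall rare fraction equals the variant-weighted mean of bin fractions", {
  ch <- small_cohort(seed = 32L, n = 120L)
  ann <- classify_rare(filter_codon_conflicts(annotate_variants(ch$variants, ch$gene_models)))
  rg <- build_regions(ch$ptm_sites, ch$proteins)
  sel <- selection_analysis(ch, ann, rg, n_bins = 20L)
  bt <- sel$bin_table
  ok <- !is.na(bt$rare_fraction)
  pooled <- sum(bt$rare_fraction[ok] * bt$n_nonsyn[ok]) / sum(bt$n_nonsyn[ok])
  overall <- sum(bt$n_rare) / sum(bt$n_nonsyn)
  expect_equal(pooled, overall, tolerance = 1e-12)
})

test_that("planted constraint is detected and the null is level, across seeds", {
  # scaled-down replicate check (the acceptance suite runs the full design)
  hits <- 0L
  for (s in 1:5) {
    ch <- generate_cohort(simulation_config(n_proteins = 300,
                                            ptm_constraint_effect = 3,
                                            seed = 500L + s))
    ann <- classify_rare(filter_codon_conflicts(annotate_variants(ch$variants, ch$gene_models)))
    rg <- build_regions(ch$ptm_sites, ch$proteins)
    sel <- selection_analysis(ch, ann, rg, n_bins = 50L)
    if (sel$tests$rare_fraction$p_value < 0.05) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})
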