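# Region construction: peptide matching, +/-7 window union with merging,
# zone and cluster labelling, support filtering.

test_that("peptides match at every exact occurrence and type mismatches are rejected", {
  proteome <- c(P1 = paste0("MM", "AAAAAAASAAAAAAA", "GG", "AAAAAAASAAAAAAA"),
                P2 = "AAAAAAASAAAAAAA")
  peptides <- data.frame(peptide = c("AAAAAAASAAAAAAA", "AAAAAAAKAAAAAAA",
                                     "WWWWWWWSWWWWWWW"),
                         ptm_type = c("phospho", "phospho", "phospho"),
                         stringsAsFactors = FALSE)
  res <- match_peptides(peptides, proteome)
  # peptide 1 occurs twice in P1 and once in P2, centre S at offset 8
  expect_equal(nrow(res$sites), 3L)
  expect_setequal(res$sites$position[res$sites$protein == "P1"], c(10L, 27L))
  expect_equal(res$sites$position[res$sites$protein == "P2"], 8L)
  expect_true(all(res$sites$residue == "S"))
  expect_equal(nrow(res$rejected), 1L)  # K centre typed phospho
  expect_match(res$rejected$reason, "incompatible")
  expect_equal(nrow(res$unmatched), 1L)
})

test_that("regions are clipped, merged window unions", {
  proteome <- toy_proteome(100L)
  # single interior site
  r1 <- build_regions(toy_sites(50L), proteome)
  expect_equal(c(r1$start, r1$end), c(43L, 57L))
  expect_equal(r1$end - r1$start + 1L, 15L)
  # overlapping windows merge
  r2 <- build_regions(toy_sites(c(50L, 60L)), proteome)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(43L, 67L))
  expect_equal(r2$n_sites, 2L)
  # terminus clipping
  r3 <- build_regions(toy_sites(3L), proteome)
  expect_equal(c(r3$start, r3$end), c(1L, 10L))
  # strictly adjacent-but-disjoint windows stay separate
  r4 <- build_regions(toy_sites(c(20L, 35L)), proteome)
  expect_equal(nrow(r4), 2L)
})

test_that("region coverage equals the brute-force window union on random inputs", {
  set.seed(401)
  proteome <- toy_proteome(120L)
  for (rep in 1:20) {
    pos <- sort(sample.int(120L, sample(1:8, 1)))
    rg <- build_regions(toy_sites(pos), proteome)
    covered <- unlist(mapply(seq.int, rg$start, rg$end, SIMPLIFY = FALSE))
    expect_equal(sort(covered), brute_window_union(pos, 120L))
    # regions are disjoint (adjacent-but-disjoint windows may touch)
    if (nrow(rg) > 1L) expect_true(all(rg$start[-1] > rg$end[-nrow(rg)]))
  }
})

test_that("rebuilding regions from their own site lists is idempotent", {
  set.seed(402)
  proteome <- toy_proteome(150L, n = 3L)
  sites <- do.call(rbind, lapply(names(proteome), function(p)
    toy_sites(sort(sample.int(150L, 6L)), protein = p, proteome = proteome)))
  r1 <- build_regions(sites, proteome)
  r2 <- build_regions(sites, proteome)
  expect_identical(r1, r2)
})

test_that("multi-type residues count once and pool their types", {
  proteome <- toy_proteome(100L)
  sites <- rbind(toy_sites(52L, type = "phospho"), toy_sites(52L, type = "ubiq"))
  rg <- build_regions(sites, proteome)
  expect_equal(rg$n_sites, 1L)
  expect_equal(rg$types, "phospho,ubiq")
})

test_that("zones reflect distance to the nearest modified residue", {
  proteome <- toy_proteome(100L)
  z1 <- classify_zones(build_regions(toy_sites(50L), proteome), toy_sites(50L))
  zs <- stats::setNames(z1$zone, z1$position)
  expect_equal(unname(zs[c("50", "51", "54")]), c("DI", "N1", "N2"))
  # nearest of two sites governs
  s2 <- toy_sites(c(50L, 53L))
  z2 <- classify_zones(build_regions(s2, proteome), s2)
  expect_equal(z2$zone[z2$position == 51L], "N1")
  # equidistant case
  s3 <- toy_sites(c(50L, 52L))
  z3 <- classify_zones(build_regions(s3, proteome), s3)
  expect_equal(z3$zone[z3$position == 51L], "N1")
})

test_that("zones agree with brute-force minimum distance and tile each region", {
  set.seed(403)
  proteome <- toy_proteome(200L)
  for (rep in 1:10) {
    pos <- sort(sample.int(200L, sample(2:9, 1)))
    sites <- toy_sites(pos)
    rg <- build_regions(sites, proteome)
    zz <- classify_zones(rg, sites)
    d_brute <- vapply(zz$position, function(q) min(abs(q - pos)), 0L)
    z_brute <- ifelse(d_brute == 0L, "DI", ifelse(d_brute <= 2L, "N1", "N2"))
    expect_equal(zz$zone, z_brute)
    # partition: zone labels cover exactly the region residues
    covered <- unlist(mapply(seq.int, rg$start, rg$end, SIMPLIFY = FALSE))
    expect_setequal(zz$position, covered)
    expect_equal(nrow(zz), length(covered))
  }
})

test_that("cluster bins count adjacent sites within +/-7 and cap at 5+", {
  proteome <- toy_proteome(100L)
  s1 <- toy_sites(50L)
  c1 <- cluster_bins(build_regions(s1, proteome), s1)
  expect_true(all(c1$cluster_bin == "1"))
  s3 <- toy_sites(c(50L, 51L, 52L))
  c3 <- cluster_bins(build_regions(s3, proteome), s3)
  expect_equal(c3$cluster_bin[c3$position == 50L], "3")
  # brute-force count check
  pos <- c(40L, 42L, 44L, 50L, 51L, 52L, 55L)
  s <- toy_sites(pos)
  cb <- cluster_bins(build_regions(s, proteome), s)
  n_brute <- vapply(cb$position, function(q) sum(abs(pos - q) <= 7L), 0L)
  expect_equal(cb$n_adjacent, n_brute)
  s6 <- toy_sites(c(50L, 51L, 52L, 53L, 54L, 55L))
  c6 <- cluster_bins(build_regions(s6, proteome), s6)
  expect_equal(c6$cluster_bin[c6$position == 52L], "5+")
})

test_that("support filtering keeps sites at or above the publication cutoff", {
  sites <- toy_sites(c(10L, 30L, 50L))
  sites$n_pubs <- c(1L, 2L, 3L)
  expect_identical(filter_by_support(sites, 1L), sites)
  expect_equal(nrow(filter_by_support(sites, 2L)), 2L)
  expect_warning(out <- filter_by_support(sites, 9L), "no sites")
  expect_equal(nrow(out), 0L)
})
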