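# Codon-level annotation: single-edit translation, degeneracy, the
# same-codon filter, DAF classes, GC windows and nearest-locus lookup.

test_that("single-nucleotide edits translate per the standard code", {
  gm <- c(G1 = "ATG", G2 = "GGG", G3 = "TAC")
  v <- data.frame(chrom = c("G1", "G2", "G3"), pos = c(3L, 3L, 3L),
                  ref = c("G", "G", "C"), alt = c("A", "A", "G"),
                  daf = 0.01)
  out <- annotate_variants(v, gm)
  expect_equal(out$status, c("nonsyn", "syn", "rejected"))
  expect_equal(out$ref_aa[1:2], c("M", "G"))
  expect_equal(out$alt_aa[1:2], c("I", "G"))
  expect_equal(out$reason[3], "stop-gain")
})

test_that("malformed and mismatching records are rejected with reasons", {
  gm <- c(G1 = "ATGGCT")
  v <- data.frame(chrom = c("G1", "G1", "G1", "GX"),
                  pos = c(10L, 2L, 4L, 1L),
                  ref = c("A", "C", "GT", "A"),
                  alt = c("C", "A", "A", "C"), daf = 0.1)
  out <- annotate_variants(v, gm)
  expect_equal(out$status, rep("rejected", 4))
  expect_equal(out$reason,
               c("position outside CDS", "reference base mismatch",
                 "not a simple SNV", "unknown gene model"))
})

test_that("annotation agrees with brute-force translation on all 64 x 9 edits", {
  codons <- names(oracle_code)
  rows <- list()
  for (cdn in codons) {
    for (pos in 1:3) {
      ref <- substr(cdn, pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        rows[[length(rows) + 1L]] <- data.frame(
          codon = cdn, pos = pos, ref = ref, alt = alt,
          stringsAsFactors = FALSE)
      }
    }
  }
  edits <- do.call(rbind, rows)
  gm <- stats::setNames(codons, paste0("C_", codons))
  v <- data.frame(chrom = paste0("C_", edits$codon), pos = edits$pos,
                  ref = edits$ref, alt = edits$alt, daf = 0.1)
  out <- annotate_variants(v, gm)
  # oracle: translate both codons directly
  mut <- edits$codon
  substr(mut, edits$pos, edits$pos) <- edits$alt
  ref_aa <- unname(oracle_code[edits$codon])
  alt_aa <- unname(oracle_code[mut])
  expected <- ifelse(ref_aa == "*", "rejected",  # ref codon is a stop: no residue
                     ifelse(alt_aa == "*", "rejected",
                            ifelse(alt_aa == ref_aa, "syn", "nonsyn")))
  # stop-reference codons have no valid protein residue; the annotator sees
  # a CDS whose translation contains '*' only at stop codons, which our
  # synthetic models never produce. Restrict to sense reference codons.
  sense <- ref_aa != "*"
  expect_equal(out$status[sense], expected[sense])
  expect_equal(out$alt_aa[sense & expected != "rejected"],
               alt_aa[sense & expected != "rejected"])
})

test_that("codon degeneracy matches the code and rejects unknown symbols", {
  expect_equal(codon_degeneracy(c("L", "M", "W", "R", "S")),
               c(6L, 1L, 1L, 6L, 6L))
  expect_error(codon_degeneracy("B"), "unknown amino acid")
})

test_that("fractional site counts conserve 3 sites per codon minus stop edits", {
  st <- codon_site_table()
  sense <- !is.na(st$syn_sites)
  for (i in which(sense)) {
    cdn <- st$codon[i]
    syn <- nonsyn <- stopn <- 0
    for (pos in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), substr(cdn, pos, pos))) {
        mut <- cdn
        substr(mut, pos, pos) <- alt
        aa <- oracle_code[[mut]]
        if (aa == "*") stopn <- stopn + 1 / 3
        else if (aa == oracle_code[[cdn]]) syn <- syn + 1 / 3
        else nonsyn <- nonsyn + 1 / 3
      }
    }
    expect_equal(st$syn_sites[i], syn, tolerance = 1e-12)
    expect_equal(st$nonsyn_sites[i], nonsyn, tolerance = 1e-12)
    expect_equal(syn + nonsyn + stopn, 3, tolerance = 1e-12)
  }
})

test_that("same-codon non-synonymous conflicts are removed, idempotently", {
  subs <- data.frame(
    protein = "P1", nt_pos = c(1L, 2L, 3L, 4L, 6L),
    residue_index = c(1L, 1L, 1L, 2L, 2L),
    status = c("nonsyn", "nonsyn", "syn", "nonsyn", "syn"),
    daf = 0.1, stringsAsFactors = FALSE)
  f1 <- filter_codon_conflicts(subs)
  # both nonsyn in codon 1 dropped; its syn partner and codon 2 kept
  expect_equal(f1$nt_pos, c(3L, 4L, 6L))
  expect_identical(filter_codon_conflicts(f1), f1)
  expect_lte(nrow(f1), nrow(subs))
})

test_that("rare classification is inclusive at the threshold and monotone", {
  subs <- data.frame(daf = c(0.004, 0.005, 0.006))
  expect_equal(classify_rare(subs)$is_rare, c(TRUE, TRUE, FALSE))
  expect_error(classify_rare(subs, threshold = 0), "positive")
  r1 <- classify_rare(subs, 0.005)$is_rare
  r2 <- classify_rare(subs, 0.01)$is_rare
  expect_true(all(r2[r1]))  # raising the threshold never un-rares
})

test_that("GC window percentage counts G/C in the clipped 35 bp window", {
  gm <- c(A = strrep("G", 50), B = strrep("AT", 25),
          C = paste0(strrep("GC", 7), strrep("AT", 11), "GCA"))
  expect_equal(gc_window(data.frame(chrom = "A", pos = 25), gm), 100)
  expect_equal(gc_window(data.frame(chrom = "B", pos = 25), gm), 0)
  # 35-mer with 14 G/C -> 40%
  expect_equal(gc_window(data.frame(chrom = "C", pos = 18), gm), 40)
})

test_that("nearest recombination locus resolves distance ties to the lower coordinate", {
  track <- data.frame(protein = "P1", pos = c(10L, 20L, 30L),
                      rate = c(1, 2, 3))
  v <- function(p) data.frame(chrom = "P1", pos = p)
  expect_equal(nearest_recomb(v(20L), track), 2)   # exact hit
  expect_equal(nearest_recomb(v(13L), track), 1)   # d=3 vs d=7
  expect_equal(nearest_recomb(v(25L), track), 2)   # equidistant -> lower
  expect_error(nearest_recomb(v(1L), track[0, ]), "empty")
})
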