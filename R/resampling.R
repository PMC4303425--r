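# Amino-acid-weighted permutation null. Observed rare fractions in a residue
# subset (zone, PTM type, cluster bin, motif-breaker set) are compared with
# the same statistic over residue sets sampled without replacement from a
# background, matching the test set's amino-acid composition exactly, so
# codon-redundancy differences between residue types cannot masquerade as
# selection.

#' Per-residue substitution counts
#'
#' One row per residue of the chosen proteins, with the number of
#' non-synonymous substitutions and rare substitutions observed there; the
#' sampling frame for the permutation tests.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param subs Annotated, rare-classified substitutions.
#' @param proteins Protein identifiers to include (default all).
#' @return data.frame `protein`, `position`, `aa`, `n_subs`, `n_rare`.
#' @export
residue_substitution_table <- function(cohort, subs, proteins = NULL) {
  if (is.null(proteins)) proteins <- names(cohort$proteins)
  seqs <- cohort$proteins[proteins]
  lens <- nchar(seqs)
  res <- data.frame(
    protein = rep(proteins, lens),
    position = unlist(lapply(lens, seq_len), use.names = FALSE),
    aa = unlist(strsplit(paste(seqs, collapse = ""), ""), use.names = FALSE),
    stringsAsFactors = FALSE)
  res$n_subs <- 0L
  res$n_rare <- 0L
  ns <- subs[subs$status == "nonsyn" & subs$protein %in% proteins, , drop = FALSE]
  if (nrow(ns)) {
    key <- paste(ns$protein, ns$residue_index)
    agg <- rowsum(cbind(1L, as.integer(ns$is_rare)), key)
    hit <- match(rownames(agg), paste(res$protein, res$position))
    res$n_subs[hit] <- agg[, 1]
    res$n_rare[hit] <- agg[, 2]
  }
  res
}

#' Rare fraction statistic over residue rows
#'
#' @param rows Rows of a [residue_substitution_table()].
#' @return `sum(n_rare) / sum(n_subs)`, `NA` when no substitutions.
#' @export
rare_fraction_stat <- function(rows) {
  tot <- sum(rows$n_subs)
  if (tot == 0L) NA_real_ else sum(rows$n_rare) / tot
}

#' Amino-acid-matched sample from a background
#'
#' Draws, without replacement and excluding the test set itself, a residue
#' set whose per-amino-acid counts equal the test set's exactly.
#'
#' @param residues Residue table ([residue_substitution_table()]).
#' @param test_idx Row indices of the test set.
#' @param background_idx Row indices of the eligible background (default:
#'   everything outside the test set).
#' @return Integer row indices of the sampled set.
#' @export
aa_weighted_sample <- function(residues, test_idx,
                               background_idx = setdiff(seq_len(nrow(residues)), test_idx)) {
  background_idx <- setdiff(background_idx, test_idx)
  need <- table(residues$aa[test_idx])
  bg_by_aa <- split(background_idx, residues$aa[background_idx])
  out <- integer(0)
  for (a in names(need)) {
    pool <- bg_by_aa[[a]]
    k <- need[[a]]
    if (is.null(pool) || length(pool) < k) {
      stop("insufficient background for amino acid ", a, ": need ", k,
           ", have ", length(pool))
    }
    out <- c(out, pool[sample.int(length(pool), k)])
  }
  out
}

#' Amino-acid-weighted permutation test
#'
#' Compares the observed statistic on the test set with its distribution
#' over `n_perm` amino-acid-matched samples from the background, using the
#' add-one p-value estimator `(1 + #{at least as extreme}) / (n_perm + 1)`.
#'
#' @inheritParams aa_weighted_sample
#' @param statistic Function of residue rows returning a scalar (default
#'   [rare_fraction_stat()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed for this test's sampling.
#' @param alternative `"greater"` or `"less"` (one-sided direction).
#' @return List of class `ptmvar_permutation`: `observed`, `expected_mean`,
#'   `expected_sd`, `n_perm`, `p_value`, `n_test_residues`. `p_value` is
#'   `NA` (flagged) when the observed statistic is undefined.
#' @export
permutation_test <- function(residues, test_idx,
                             background_idx = setdiff(seq_len(nrow(residues)), test_idx),
                             statistic = rare_fraction_stat,
                             n_perm = 1000L, seed = NULL,
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  observed <- statistic(residues[test_idx, , drop = FALSE])
  background_idx <- setdiff(background_idx, test_idx)
  # pre-split the background by amino acid once
  need <- table(residues$aa[test_idx])
  bg_by_aa <- split(background_idx, residues$aa[background_idx])
  for (a in names(need)) {
    if (length(bg_by_aa[[a]]) < need[[a]]) {
      stop("insufficient background for amino acid ", a, ": need ", need[[a]],
           ", have ", length(bg_by_aa[[a]]))
    }
  }
  fast <- identical(statistic, rare_fraction_stat)
  ns <- residues$n_subs; nr <- residues$n_rare
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- unlist(lapply(names(need), function(a) {
      pool <- bg_by_aa[[a]]
      pool[sample.int(length(pool), need[[a]])]
    }), use.names = FALSE)
    perm[b] <- if (fast) {
      tot <- sum(ns[idx]); if (tot == 0L) NA_real_ else sum(nr[idx]) / tot
    } else statistic(residues[idx, , drop = FALSE])
  }
  ok <- !is.na(perm)
  res <- list(observed = observed,
              expected_mean = mean(perm[ok]),
              expected_sd = stats::sd(perm[ok]),
              n_perm = n_perm,
              p_value = NA_real_,
              n_test_residues = length(test_idx),
              permuted = perm)
  if (!is.na(observed)) {
    extreme <- if (alternative == "greater") sum(perm[ok] >= observed) else
      sum(perm[ok] <= observed)
    res$p_value <- (1 + extreme) / (sum(ok) + 1)
  }
  class(res) <- "ptmvar_permutation"
  res
}

#' @export
print.ptmvar_permutation <- function(x, ...) {
  cat(sprintf("permutation test: observed %.4f, expected %.4f +/- %.4f, p = %.4g (n_perm = %d)\n",
              x$observed, x$expected_mean, x$expected_sd, x$p_value, x$n_perm))
  invisible(x)
}

#' Zone-wise permutation analysis of rare substitutions
#'
#' Tests the DI (modified residue), N1 (proximal flank) and N2 (distal
#' flank) zones for enrichment of rare substitutions against amino-acid
#' matched background residues. The sampling universe is restricted to
#' proteins carrying the tested PTM type; flank-zone backgrounds exclude
#' modified residues.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param subs Annotated, rare-classified substitutions.
#' @param ptm_type One of phospho/ubiq/acet/methyl, or `NULL` for all types
#'   combined.
#' @param n_perm Permutations per zone.
#' @param seed Seed.
#' @return data.frame: one row per zone with observed, expected, sd, p.
#' @export
zone_permutation_analysis <- function(cohort, subs, ptm_type = NULL,
                                      n_perm = 1000L, seed = 1L) {
  sites <- cohort$ptm_sites
  if (!is.null(ptm_type)) sites <- sites[sites$ptm_type == ptm_type, , drop = FALSE]
  if (nrow(sites) == 0L) return(NULL)
  prots <- unique(sites$protein)
  regions <- build_regions(sites, cohort$proteins[prots])
  zones <- classify_zones(regions, sites)
  residues <- residue_substitution_table(cohort, subs, prots)
  zkey <- paste(zones$protein, zones$position)
  rkey <- paste(residues$protein, residues$position)
  zone_of <- zones$zone[match(rkey, zkey)]
  di_idx <- which(!is.na(zone_of) & zone_of == "DI")
  set.seed(seed)
  out <- lapply(c("DI", "N1", "N2"), function(z) {
    test_idx <- which(!is.na(zone_of) & zone_of == z)
    if (!length(test_idx)) return(NULL)
    bg <- seq_len(nrow(residues))
    if (z != "DI") bg <- setdiff(bg, di_idx)  # flank tests exclude central residues
    pt <- permutation_test(residues, test_idx, background_idx = bg,
                           n_perm = n_perm, alternative = "greater")
    data.frame(stratum = z, ptm_type = ptm_type %||% "all",
               observed = pt$observed, expected_mean = pt$expected_mean,
               expected_sd = pt$expected_sd, p = pt$p_value,
               n_test_residues = pt$n_test_residues, stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Cluster-bin permutation analysis
#'
#' Tests residues grouped by the number of adjacent PTM sites (bins 1..4,
#' "5+") for rare-substitution enrichment against amino-acid matched
#' background.
#'
#' @inheritParams zone_permutation_analysis
#' @return data.frame, one row per cluster bin.
#' @export
cluster_permutation_analysis <- function(cohort, subs, n_perm = 1000L, seed = 1L) {
  sites <- cohort$ptm_sites
  if (nrow(sites) == 0L) return(NULL)
  prots <- unique(sites$protein)
  regions <- build_regions(sites, cohort$proteins[prots])
  cb <- cluster_bins(regions, sites)
  residues <- residue_substitution_table(cohort, subs, prots)
  ckey <- paste(cb$protein, cb$position)
  rkey <- paste(residues$protein, residues$position)
  bin_of <- cb$cluster_bin[match(rkey, ckey)]
  set.seed(seed)
  out <- lapply(c("1", "2", "3", "4", "5+"), function(b) {
    test_idx <- which(!is.na(bin_of) & bin_of == b)
    if (length(test_idx) < 5L) return(NULL)
    pt <- permutation_test(residues, test_idx, n_perm = n_perm,
                           alternative = "greater")
    data.frame(stratum = paste0("cluster_", b), observed = pt$observed,
               expected_mean = pt$expected_mean, expected_sd = pt$expected_sd,
               p = pt$p_value, n_test_residues = pt$n_test_residues,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
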