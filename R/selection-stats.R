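# Selection metrics: proportion of rare substitutions and Ka/Ks with
# Nei-Gojobori-style fractional site counting, compared between PTM regions
# and matched non-PTM sequence across 100 variation-matched protein bins
# with paired one-sided Wilcoxon signed-rank tests.

#' Per-protein substitution rates
#'
#' Variation rate = number of substituted residues (any class) divided by
#' protein length; the matching covariate for percentile binning.
#'
#' @param subs Annotated substitutions.
#' @param proteome Named character vector of sequences.
#' @return data.frame `protein`, `length`, `n_sub_residues`, `variation_rate`.
#' @export
protein_variation <- function(subs, proteome) {
  ok <- subs$status %in% c("syn", "nonsyn")
  key <- unique(paste(subs$protein[ok], subs$residue_index[ok]))
  counts <- table(sub(" .*", "", key))
  lens <- nchar(proteome)
  n_sub <- as.integer(counts[names(proteome)])
  n_sub[is.na(n_sub)] <- 0L
  data.frame(protein = names(proteome), length = as.integer(lens),
             n_sub_residues = n_sub, variation_rate = n_sub / lens,
             stringsAsFactors = FALSE)
}

#' Percentile bins of proteins with matched variation
#'
#' Sorts proteins by variation rate (ties broken by identifier) and splits
#' them into `n_bins` contiguous near-equal groups; with remainder `r`, the
#' first `r` bins take one extra protein.
#'
#' @param pstats Output of [protein_variation()].
#' @param n_bins Number of bins (default 100).
#' @return data.frame `protein`, `bin`, `variation_rate`.
#' @export
bin_by_variation <- function(pstats, n_bins = 100L) {
  n <- nrow(pstats)
  if (n < n_bins) stop("fewer proteins (", n, ") than bins (", n_bins, ")")
  ord <- order(pstats$variation_rate, pstats$protein)
  k <- n %/% n_bins; r <- n %% n_bins
  sizes <- rep(k, n_bins) + c(rep(1L, r), rep(0L, n_bins - r))
  data.frame(protein = pstats$protein[ord],
             bin = rep(seq_len(n_bins), sizes),
             variation_rate = pstats$variation_rate[ord],
             stringsAsFactors = FALSE)
}

#' Ka, Ks and their ratio from counts and site totals
#'
#' @param n_nonsyn,n_syn Observed non-synonymous / synonymous variant counts.
#' @param nonsyn_sites,syn_sites Fractional site totals for the stratum.
#' @return List `ka`, `ks`, `ka_ks` (`ka_ks` is `NA` when the synonymous
#'   denominator is zero).
#' @export
ka_ks <- function(n_nonsyn, n_syn, nonsyn_sites, syn_sites) {
  ka <- ifelse(nonsyn_sites > 0, n_nonsyn / nonsyn_sites, NA_real_)
  ks <- ifelse(syn_sites > 0, n_syn / syn_sites, NA_real_)
  ratio <- ifelse(!is.na(ks) & ks > 0, ka / ks, NA_real_)
  list(ka = ka, ks = ks, ka_ks = ratio)
}

#' Per-protein selection components split by PTM region and disorder
#'
#' For every protein, sums fractional synonymous/non-synonymous site counts
#' and observed variant counts within the four cells of
#' PTM-region x disorder, the building blocks for binned and stratified
#' summaries.
#'
#' @param cohort A `ptmvar_cohort` (or list with `proteins`, `gene_models`,
#'   `disorder`).
#' @param subs Annotated, rare-classified substitutions.
#' @param regions Region table.
#' @return Long data.frame: `protein`, `ptm`, `disordered`, `n_residues`,
#'   `syn_sites`, `nonsyn_sites`, `n_syn`, `n_nonsyn`, `n_rare`.
#' @export
per_protein_selection <- function(cohort, subs, regions) {
  st <- codon_site_table()
  pm <- region_masks(regions, cohort$proteins)
  dm <- disorder_masks(cohort$disorder, cohort$proteins)
  lens <- nchar(cohort$proteins)
  subs <- subs[subs$status %in% c("syn", "nonsyn"), , drop = FALSE]
  subs_by_prot <- split(subs, subs$protein)
  out <- vector("list", length(cohort$proteins))
  for (i in seq_along(cohort$proteins)) {
    p <- names(cohort$proteins)[i]
    L <- lens[[p]]
    cdn <- substring(cohort$gene_models[[p]], seq(1L, 3L * L, 3L), seq(3L, 3L * L, 3L))
    m <- match(cdn, st$codon)
    grp <- 1L + pm[[p]] + 2L * dm[[p]]  # 1..4
    sites <- rowsum(cbind(st$syn_sites[m], st$nonsyn_sites[m], 1L), grp)
    g_present <- as.integer(rownames(sites))
    sv <- subs_by_prot[[p]]
    cnt <- matrix(0, nrow = 4, ncol = 3)
    if (!is.null(sv)) {
      sg <- grp[sv$residue_index]
      cnt_df <- rowsum(cbind((sv$status == "syn") + 0,
                             (sv$status == "nonsyn") + 0,
                             (sv$status == "nonsyn" & sv$is_rare) + 0), sg)
      cnt[as.integer(rownames(cnt_df)), ] <- cnt_df
    }
    out[[i]] <- data.frame(
      protein = p,
      ptm = (g_present - 1L) %% 2L == 1L,
      disordered = g_present > 2L,
      n_residues = sites[, 3],
      syn_sites = sites[, 1], nonsyn_sites = sites[, 2],
      n_syn = cnt[g_present, 1], n_nonsyn = cnt[g_present, 2],
      n_rare = cnt[g_present, 3],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# aggregate per-protein components over an index (e.g. bin x ptm)
.aggregate_selection <- function(pp, by) {
  agg <- rowsum(pp[, c("n_residues", "syn_sites", "nonsyn_sites",
                       "n_syn", "n_nonsyn", "n_rare")], by)
  out <- data.frame(stratum = rownames(agg), agg, stringsAsFactors = FALSE)
  out$rare_fraction <- ifelse(out$n_nonsyn > 0, out$n_rare / out$n_nonsyn, NA_real_)
  kk <- ka_ks(out$n_nonsyn, out$n_syn, out$nonsyn_sites, out$syn_sites)
  out$ka <- kk$ka; out$ks <- kk$ks; out$ka_ks <- kk$ka_ks
  rownames(out) <- NULL
  out
}

#' Paired one-sided Wilcoxon signed-rank test over matched bins
#'
#' Tests whether the PTM-side metric systematically exceeds (or falls below)
#' the non-PTM side across bins. Zero or missing differences are dropped;
#' the exact null is used for up to 25 informative pairs, the normal
#' approximation with continuity correction above.
#'
#' @param ptm,nonptm Numeric vectors of per-bin metric values.
#' @param alternative `"greater"` (PTM > non-PTM, e.g. rare fraction) or
#'   `"less"` (e.g. Ka/Ks).
#' @param min_pairs Minimum informative pairs required (default 6).
#' @return List `statistic`, `p_value`, `n_informative` (p is `NA` with a
#'   warning when too few informative pairs remain).
#' @export
paired_bin_test <- function(ptm, nonptm, alternative = c("greater", "less"),
                            min_pairs = 6L) {
  alternative <- match.arg(alternative)
  d <- ptm - nonptm
  d <- d[!is.na(d) & d != 0]
  if (length(d) < min_pairs) {
    warning("only ", length(d), " informative pairs; p-value not computed")
    return(list(statistic = NA_real_, p_value = NA_real_, n_informative = length(d)))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25L) {
    p <- signed_rank_exact_p(r, v, alternative)
  } else {
    wt <- stats::wilcox.test(d, alternative = alternative, exact = FALSE,
                             correct = TRUE)
    p <- wt$p.value
  }
  list(statistic = v, p_value = p, n_informative = n)
}

# exact signed-rank tail by dynamic programming over the 2^n sign
# assignments (handles tied ranks; ranks doubled to stay integral)
signed_rank_exact_p <- function(ranks, v_obs, alternative) {
  g <- as.integer(round(2 * ranks))
  total <- sum(g)
  counts <- numeric(total + 1L)  # counts[s + 1] = #assignments with 2V = s
  counts[1L] <- 1
  for (gi in g) {
    shifted <- c(numeric(gi), counts[seq_len(total + 1L - gi)])
    counts <- counts + shifted
  }
  s_obs <- round(2 * v_obs)
  idx <- seq_along(counts) - 1L
  hits <- if (alternative == "greater") counts[idx >= s_obs] else counts[idx <= s_obs]
  sum(hits) / 2^length(g)
}

#' Selection summaries per structure class and PTM membership
#'
#' @param pp Output of [per_protein_selection()].
#' @return data.frame of the six cells {all, structured, disordered} x
#'   {PTM, non-PTM}.
#' @export
stratified_summaries <- function(pp) {
  cells <- rbind(
    .aggregate_selection(pp, paste0("all|", ifelse(pp$ptm, "ptm", "nonptm"))),
    .aggregate_selection(pp[!pp$disordered, ],
                         paste0("structured|", ifelse(pp$ptm[!pp$disordered], "ptm", "nonptm"))),
    .aggregate_selection(pp[pp$disordered, ],
                         paste0("disordered|", ifelse(pp$ptm[pp$disordered], "ptm", "nonptm"))))
  parts <- strsplit(cells$stratum, "|", fixed = TRUE)
  cells$structure <- vapply(parts, `[[`, "", 1L)
  cells$region <- vapply(parts, `[[`, "", 2L)
  cells
}

#' Binned PTM vs non-PTM selection analysis
#'
#' The module's main entry point: restricts to proteins with PTM sites
#' (unless `include_all`), bins them by matched variation, computes per-bin
#' rare fractions and Ka/Ks for PTM and non-PTM sequence, and runs the
#' paired one-sided tests (rare fraction: PTM > non-PTM; Ka/Ks:
#' PTM < non-PTM).
#'
#' @param cohort A `ptmvar_cohort`.
#' @param subs Annotated, rare-classified substitutions.
#' @param regions Region table.
#' @param n_bins Number of variation-matched bins (default 100).
#' @param include_all Keep proteins without PTM sites (default FALSE).
#' @return List `bin_table` (per bin x side metrics), `tests` (rare and
#'   ka_ks paired tests), `summaries` (structure-split totals),
#'   `per_protein`, `bins`.
#' @export
selection_analysis <- function(cohort, subs, regions, n_bins = 100L,
                               include_all = FALSE) {
  ptm_proteins <- unique(cohort$ptm_sites$protein)
  proteome <- cohort$proteins
  if (!include_all) proteome <- proteome[names(proteome) %in% ptm_proteins]
  pstats <- protein_variation(subs, proteome)
  bins <- bin_by_variation(pstats, n_bins)
  pp <- per_protein_selection(cohort, subs, regions)
  pp <- pp[pp$protein %in% names(proteome), , drop = FALSE]
  pp$bin <- bins$bin[match(pp$protein, bins$protein)]
  bt <- .aggregate_selection(pp, sprintf("%03d|%s", pp$bin,
                                         ifelse(pp$ptm, "ptm", "nonptm")))
  parts <- strsplit(bt$stratum, "|", fixed = TRUE)
  bt$bin <- as.integer(vapply(parts, `[[`, "", 1L))
  bt$region <- vapply(parts, `[[`, "", 2L)
  wide <- function(metric) {
    get <- function(reg) {
      sel <- bt[bt$region == reg, , drop = FALSE]
      sel[[metric]][match(seq_len(n_bins), sel$bin)]
    }
    list(ptm = get("ptm"), nonptm = get("nonptm"))
  }
  rf <- wide("rare_fraction")
  kk <- wide("ka_ks")
  tests <- list(
    rare_fraction = paired_bin_test(rf$ptm, rf$nonptm, "greater"),
    ka_ks = paired_bin_test(kk$ptm, kk$nonptm, "less"))
  list(bin_table = bt, tests = tests, summaries = stratified_summaries(pp),
       per_protein = pp, bins = bins)
}
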