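# Group-level PTM-constraint tests: per-group logistic LRT with disorder as
# confounder, tissue / pathway gene sets, expression- and conservation-
# binned trends, disease-gene overlap, and enrichment-map export tables.

#' Disorder-adjusted LRT for PTM constraint within a protein group
#'
#' Null model: rare ~ disorder; alternative: rare ~ disorder + PTM flag.
#' One-degree likelihood-ratio chi-square; direction from the PTM
#' coefficient sign.
#'
#' @param features Feature-table rows (substitutions) of the group.
#' @param min_subs Minimum substitutions required (default 20).
#' @return List `p_value`, `direction` (`negative` = rare enrichment in PTM
#'   regions, i.e. constraint), `n_ptm_subs`, `n_nonptm_subs`, or `NULL`
#'   with a message when the group is degenerate.
#' @export
group_lrt <- function(features, min_subs = 20L) {
  f <- features
  if (nrow(f) < min_subs ||
      length(unique(f$is_rare)) < 2L || length(unique(f$in_ptm_region)) < 2L) {
    return(NULL)
  }
  df <- data.frame(y = as.integer(f$is_rare),
                   dis = as.integer(f$in_disorder),
                   ptm = as.integer(f$in_ptm_region))
  null_fit <- stats::glm(y ~ dis, family = stats::binomial(), data = df)
  alt_fit <- stats::glm(y ~ dis + ptm, family = stats::binomial(), data = df)
  lr <- lrt_pvalue(null_fit, alt_fit)
  coef_ptm <- stats::coef(alt_fit)[["ptm"]]
  list(p_value = lr$p_value,
       direction = if (coef_ptm >= 0) "negative" else "positive",
       n_ptm_subs = sum(df$ptm == 1L), n_nonptm_subs = sum(df$ptm == 0L))
}

#' PTM-constraint tests across gene sets
#'
#' Applies [group_lrt()] to each gene set's substitutions and BH-adjusts
#' across tested sets. (`direction = "negative"` means negative selection:
#' relatively more rare substitutions in PTM regions.)
#'
#' @param features Full feature table.
#' @param gene_sets Named list of protein-id vectors.
#' @param min_subs Passed to [group_lrt()].
#' @return data.frame per tested group with `p`, `q`, `direction`, counts;
#'   skipped groups are absent (reported via the `skipped` attribute).
#' @export
run_group_tests <- function(features, gene_sets, min_subs = 20L) {
  rows <- list(); skipped <- character(0)
  for (g in names(gene_sets)) {
    f <- features[features$protein %in% gene_sets[[g]], , drop = FALSE]
    r <- group_lrt(f, min_subs)
    if (is.null(r)) { skipped <- c(skipped, g); next }
    rows[[g]] <- data.frame(group = g, n_proteins = length(gene_sets[[g]]),
                            n_ptm_subs = r$n_ptm_subs,
                            n_nonptm_subs = r$n_nonptm_subs,
                            direction = r$direction, lrt_p = r$p_value,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  res$q <- stats::p.adjust(res$lrt_p, method = "BH")
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Ubiquitous and tissue-specific protein sets from expression
#'
#' A gene is called highly expressed in a tissue when its robust z-score
#' across tissues, `(x - median) / (1.4826 * MAD)`, is at least `z_cut`;
#' ubiquitous genes are high in `min_tissues` or more tissues and are
#' removed from every tissue-specific set. Numbered tissue replicates
#' (`name_1`, `name_2`, ...) are merged. Genes with MAD zero (constant
#' expression) are excluded and reported.
#'
#' @param expression Gene x tissue numeric matrix.
#' @param z_cut Robust z threshold (default 2).
#' @param min_tissues Tissues required for ubiquity (default 18).
#' @return List `ubiquitous` (gene ids), `tissue_sets` (named list),
#'   `excluded` (MAD-zero genes).
#' @export
define_ubiquitous <- function(expression, z_cut = 2, min_tissues = 18L) {
  if (ncol(expression) < min_tissues) stop("need at least ", min_tissues, " tissues")
  med <- apply(expression, 1, stats::median)
  madv <- apply(expression, 1, stats::mad)  # mad() scales by 1.4826
  excluded <- rownames(expression)[madv == 0]
  keep <- madv > 0
  z <- (expression[keep, , drop = FALSE] - med[keep]) / madv[keep]
  high <- z >= z_cut
  n_high <- rowSums(high)
  ubiquitous <- rownames(high)[n_high >= min_tissues]
  tissue <- sub("_[0-9]+$", "", colnames(expression))
  tissue_sets <- lapply(unique(tissue), function(t) {
    cols <- which(tissue == t)
    genes <- rownames(high)[rowSums(high[, cols, drop = FALSE]) > 0]
    setdiff(genes, ubiquitous)
  })
  names(tissue_sets) <- unique(tissue)
  list(ubiquitous = ubiquitous, tissue_sets = tissue_sets, excluded = excluded)
}

#' Binned trend of PTM rare-substitution enrichment along a covariate
#'
#' Bins proteins into `n_bins` equal-size groups by a per-protein covariate
#' (median expression or conservation), computes per bin the log2 ratio of
#' the observed PTM rare fraction over the disorder-model expectation (with
#' the model-prediction standard error), and correlates enrichment with the
#' per-bin median covariate (Pearson).
#'
#' @param features Feature table.
#' @param covariate Named numeric vector (per protein).
#' @param n_bins Number of bins (default 100).
#' @return List `bin_table`, `r`, `p_value`, `n_bins_used`.
#' @export
binned_trend <- function(features, covariate, n_bins = 100L) {
  covariate <- covariate[!is.na(covariate)]
  if (stats::sd(covariate) == 0) stop("constant covariate: correlation undefined")
  prots <- intersect(unique(features$protein), names(covariate))
  if (length(prots) < n_bins) stop("fewer proteins with covariate (",
                                   length(prots), ") than bins")
  cv <- sort(covariate[prots])
  bins <- data.frame(protein = names(cv),
                     bin = ceiling(seq_along(cv) / (length(cv) / n_bins)),
                     stringsAsFactors = FALSE)
  f <- features[features$protein %in% prots, , drop = FALSE]
  f$bin <- bins$bin[match(f$protein, bins$protein)]
  rows <- lapply(seq_len(n_bins), function(b) {
    fb <- f[f$bin == b, , drop = FALSE]
    ptm <- fb$in_ptm_region
    if (sum(ptm) == 0L || length(unique(fb$is_rare)) < 2L) return(NULL)
    fit <- stats::glm(is_rare ~ in_disorder, family = stats::binomial(), data = fb)
    pred <- stats::predict(fit, newdata = fb[ptm, , drop = FALSE],
                           type = "response", se.fit = TRUE)
    observed <- mean(fb$is_rare[ptm])
    expected <- mean(pred$fit)
    data.frame(bin = b,
               covariate_median = stats::median(cv[bins$bin == b]),
               observed = observed, expected = expected,
               expected_se = mean(pred$se.fit),
               log2_enrichment = log2(pmax(observed, 1e-6) / pmax(expected, 1e-6)),
               n_ptm_subs = sum(ptm), stringsAsFactors = FALSE)
  })
  bt <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(bt) || nrow(bt) < 3L) stop("too few informative bins")
  ct <- stats::cor.test(bt$covariate_median, bt$log2_enrichment)
  list(bin_table = bt, r = unname(ct$estimate), p_value = ct$p.value,
       n_bins_used = nrow(bt), n_bins_dropped = n_bins - nrow(bt))
}

#' Disease-gene overlap of significant groups
#'
#' Per significant group, a hypergeometric (Fisher) test of overlap with
#' disease genes over the tested-protein universe, BH-adjusted.
#'
#' @param group_results Output of [run_group_tests()].
#' @param gene_sets The gene sets tested.
#' @param disease_genes Disease genes with PTM-related substitutions.
#' @param universe Protein universe.
#' @param q_threshold Group-significance gate (default 0.05).
#' @return data.frame with per-group overlap p and q.
#' @export
disease_overlap <- function(group_results, gene_sets, disease_genes, universe,
                            q_threshold = 0.05) {
  if (!length(universe)) stop("empty protein universe")
  sig <- group_results[group_results$q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(NULL)
  dg <- intersect(disease_genes, universe)
  rows <- lapply(sig$group, function(g) {
    members <- intersect(gene_sets[[g]], universe)
    if (!length(members)) return(NULL)
    a <- length(intersect(members, dg))
    tb <- matrix(c(a, length(members) - a,
                   length(dg) - a,
                   length(universe) - length(members) - length(dg) + a),
                 nrow = 2, byrow = TRUE)
    data.frame(group = g, n_members = length(members), n_disease_overlap = a,
               p = stats::fisher.test(tb, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) return(NULL)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Enrichment-map export of significant groups
#'
#' Node table (one row per significant group with direction and disease
#' flags) and edge table (Jaccard overlap of member sets at or above the
#' cutoff), consumable by network visualization tools.
#'
#' @param group_results Output of [run_group_tests()].
#' @param gene_sets The gene sets tested.
#' @param overlap Optional [disease_overlap()] result for disease flags.
#' @param q_threshold Significance gate.
#' @param jaccard_cutoff Minimum Jaccard index for an edge (default 0.25).
#' @return List `nodes`, `edges`.
#' @export
enrichment_map_export <- function(group_results, gene_sets, overlap = NULL,
                                  q_threshold = 0.05, jaccard_cutoff = 0.25) {
  sig <- group_results[group_results$q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) return(list(nodes = NULL, edges = NULL))
  nodes <- sig[, c("group", "direction", "lrt_p", "q")]
  nodes$disease_enriched <- FALSE
  if (!is.null(overlap)) {
    nodes$disease_enriched <- nodes$group %in% overlap$group[overlap$q < 0.01]
  }
  gs <- gene_sets[nodes$group]
  edges <- list()
  if (length(gs) > 1L) {
    cmb <- utils::combn(names(gs), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- gs[[cmb[1, k]]]; b <- gs[[cmb[2, k]]]
      j <- length(intersect(a, b)) / length(union(a, b))
      if (j >= jaccard_cutoff) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = cmb[1, k], to = cmb[2, k], jaccard = j,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(nodes = nodes, edges = if (length(edges)) do.call(rbind, edges) else NULL)
}

#' Disease-label frequency table (word-cloud input)
#'
#' @param disease Disease annotation table.
#' @param proteins Optional protein subset.
#' @return data.frame `disease`, `n_annotations`, sorted decreasing.
#' @export
disease_word_frequencies <- function(disease, proteins = NULL) {
  d <- disease
  if (!is.null(proteins)) d <- d[d$protein %in% proteins, , drop = FALSE]
  agg <- rowsum(d$n_records, d$disease)
  out <- data.frame(disease = rownames(agg), n_annotations = agg[, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_annotations, out$disease), ]
  rownames(out) <- NULL
  out
}
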