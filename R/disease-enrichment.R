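# Disease-mutation enrichment in PTM regions: exact residue-level Fisher
# tests split by structure class, a Poisson test on annotation totals
# (multiplicities included), amino-acid-matched central-residue binomial
# tests, a per-gene Poisson-regression mutation-hotspot model, and cancer
# gene overlap.

#' Residue-level Fisher enrichment of disease annotations in PTM regions
#'
#' 2x2 of (residue disease-annotated?) x (residue in PTM region?) over the
#' residues of proteins with at least one PTM site, tested separately for
#' structured and disordered sequence. The odds ratio reported is the sample
#' cross-product ratio; p is the exact hypergeometric tail.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param regions Region table.
#' @return data.frame, one row per structure class.
#' @export
region_enrichment_fisher <- function(cohort, regions) {
  prots <- unique(cohort$ptm_sites$protein)
  pm <- region_masks(regions, cohort$proteins)
  dm <- disorder_masks(cohort$disorder, cohort$proteins)
  dkey <- unique(paste(cohort$disease$protein, cohort$disease$position))
  out <- lapply(c(structured = FALSE, disordered = TRUE), function(dis) {
    a <- b <- c_ <- d_ <- 0L
    for (p in prots) {
      sel <- dm[[p]] == dis
      if (!any(sel)) next
      pos <- which(sel)
      ann <- paste(p, pos) %in% dkey
      inr <- pm[[p]][pos]
      a <- a + sum(ann & inr); b <- b + sum(ann & !inr)
      c_ <- c_ + sum(!ann & inr); d_ <- d_ + sum(!ann & !inr)
    }
    tb <- matrix(c(a, b, c_, d_), nrow = 2, byrow = TRUE)
    p <- stats::fisher.test(tb, alternative = "greater")$p.value
    or <- if (b > 0 && c_ > 0) (a * d_) / (b * c_) else NA_real_
    data.frame(stratum = if (dis) "disordered" else "structured",
               observed = a, n_region_residues = a + c_,
               n_annotated = a + b, n_residues = a + b + c_ + d_,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Poisson test on total disease annotations in PTM regions
#'
#' Counts annotations with multiplicity (`n_records`); expected = total
#' annotations x (region residues / total residues); p is the upper Poisson
#' tail including the observed value; `expected_sd = sqrt(expected)`.
#'
#' @inheritParams region_enrichment_fisher
#' @return One-row data.frame `observed`, `expected`, `expected_sd`, `p`.
#' @export
region_enrichment_poisson <- function(cohort, regions) {
  prots <- unique(cohort$ptm_sites$protein)
  pm <- region_masks(regions, cohort$proteins)
  d <- cohort$disease[cohort$disease$protein %in% prots, , drop = FALSE]
  total <- sum(d$n_records)
  if (total == 0L) stop("no disease annotations in PTM proteins")
  in_reg <- mapply(function(p, i) pm[[p]][i], d$protein, d$position)
  observed <- sum(d$n_records[in_reg])
  reg_res <- sum(vapply(pm[prots], sum, 0))
  tot_res <- sum(nchar(cohort$proteins[prots]))
  expected <- total * reg_res / tot_res
  if (expected == 0) {
    return(data.frame(observed = observed, expected = 0, expected_sd = 0,
                      p = NA_real_, degenerate = TRUE))
  }
  data.frame(observed = observed, expected = expected,
             expected_sd = sqrt(expected),
             p = stats::ppois(observed - 1, expected, lower.tail = FALSE),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

#' Central-residue disease enrichment per PTM type
#'
#' Binomial test of disease annotation of directly modified residues against
#' the annotation rate among amino-acid-matched residues (S/T/Y for
#' phosphorylation, K for ubiquitination/acetylation, K/R for methylation)
#' of proteins carrying that PTM type.
#'
#' @param cohort A `ptmvar_cohort`.
#' @return data.frame, one row per PTM type present.
#' @export
central_residue_enrichment <- function(cohort) {
  dkey <- unique(paste(cohort$disease$protein, cohort$disease$position))
  out <- lapply(PTM_TYPES, function(t) {
    st <- cohort$ptm_sites[cohort$ptm_sites$ptm_type == t, , drop = FALSE]
    if (nrow(st) == 0L) return(NULL)
    prots <- unique(st$protein)
    aa_ok <- PTM_ALLOWED_AA[[t]]
    n_matched <- ann_matched <- 0L
    skey <- paste(st$protein, st$position)
    for (p in prots) {
      chars <- strsplit(cohort$proteins[[p]], "")[[1]]
      pos <- which(chars %in% aa_ok)
      key <- paste(p, pos)
      bg <- !(key %in% skey)
      n_matched <- n_matched + sum(bg)
      ann_matched <- ann_matched + sum(bg & key %in% dkey)
    }
    if (n_matched == 0L) stop("no matched background residues for ", t)
    n_sites <- nrow(unique(st[, c("protein", "position")]))
    ann_sites <- sum(unique(skey) %in% dkey)
    rate <- ann_matched / n_matched
    p <- stats::pbinom(ann_sites - 1L, n_sites, rate, lower.tail = FALSE)
    data.frame(ptm_type = t, n_sites = n_sites, observed = ann_sites,
               expected = n_sites * rate, expected_sd = sqrt(n_sites * rate * (1 - rate)),
               background_rate = rate, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  res
}

# mid-p upper tail of Poisson: P[X > obs] + 0.5 P[X = obs]; calibrated
# (approximately uniform under the null) unlike the inclusive tail
poisson_midp <- function(obs, lambda) {
  stats::ppois(obs, lambda, lower.tail = FALSE) +
    0.5 * stats::dpois(obs, lambda)
}

#' Per-gene PTM mutation-hotspot model
#'
#' For each protein with PTM regions and disease mutations, fits per-residue
#' mutation-record counts with a Poisson log-linear model carrying protein
#' disorder as confounder, computes per-region mid-p upper tails of the
#' observed region totals against the model-expected totals, and aggregates
#' region p-values to a gene-level p with Fisher's combined probability
#' method; genes are BH-adjusted.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param regions Region table.
#' @return data.frame per gene: `protein`, `n_regions`, `n_records`,
#'   `top_region`, `top_region_p`, `gene_p`, `gene_q`; the per-region test
#'   table is attached as attribute `region_table`.
#' @export
active_driver <- function(cohort, regions) {
  dm <- disorder_masks(cohort$disorder, cohort$proteins)
  d_by_prot <- split(cohort$disease, cohort$disease$protein)
  reg_by_prot <- split(regions, regions$protein)
  prots <- intersect(names(reg_by_prot), names(d_by_prot))
  out <- vector("list", length(prots))
  for (i in seq_along(prots)) {
    p <- prots[i]
    L <- nchar(cohort$proteins[[p]])
    y <- integer(L)
    dd <- d_by_prot[[p]]
    agg <- rowsum(dd$n_records, dd$position)
    y[as.integer(rownames(agg))] <- agg[, 1]
    dis <- as.integer(dm[[p]])
    fit <- tryCatch(
      stats::glm(y ~ dis, family = stats::poisson()),
      error = function(e) NULL, warning = function(w) NULL)
    mu <- if (!is.null(fit) && fit$converged) stats::fitted(fit) else
      rep(mean(y), L)  # intercept-only fallback for degenerate proteins
    rg <- reg_by_prot[[p]]
    # mid-p for every region, including zero-mutation regions (their mid-p
    # sits just below 1, so they can never rank as hotspots, and the
    # gene-level aggregate stays calibrated under the null)
    region_p <- vapply(seq_len(nrow(rg)), function(k) {
      idx <- rg$start[k]:rg$end[k]
      poisson_midp(sum(y[idx]), sum(mu[idx]))
    }, 0)
    # Fisher's combined probability over region p-values
    stat <- -2 * sum(log(pmax(region_p, 1e-300)))
    gene_p <- stats::pchisq(stat, df = 2L * nrow(rg), lower.tail = FALSE)
    out[[i]] <- list(
      gene = data.frame(
        protein = p, n_regions = nrow(rg), n_records = sum(y),
        top_region = rg$region_id[which.min(region_p)],
        top_region_p = min(region_p), gene_p = gene_p,
        stringsAsFactors = FALSE),
      regions = data.frame(
        protein = p, region_id = rg$region_id,
        observed = vapply(seq_len(nrow(rg)), function(k)
          sum(y[rg$start[k]:rg$end[k]]), 0),
        expected = vapply(seq_len(nrow(rg)), function(k)
          sum(mu[rg$start[k]:rg$end[k]]), 0),
        p = region_p, stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, lapply(out, `[[`, "gene"))
  if (is.null(res)) return(NULL)
  res$gene_q <- stats::p.adjust(res$gene_p, method = "BH")
  rownames(res) <- NULL
  region_tab <- do.call(rbind, lapply(out, `[[`, "regions"))
  rownames(region_tab) <- NULL
  attr(res, "region_table") <- region_tab
  res
}

#' Cancer-gene enrichment among hotspot-significant genes
#'
#' Fisher's exact test of the overlap between significant genes and a
#' cancer gene list over the tested-gene universe.
#'
#' @param significant,cancer_genes,universe Character vectors of gene ids.
#' @return List `table`, `odds_ratio` (sample OR; `NA` on empty margins),
#'   `p_value`.
#' @export
cancer_gene_enrichment <- function(significant, cancer_genes, universe) {
  if (!length(universe)) stop("empty gene universe")
  sig <- universe %in% significant
  can <- universe %in% cancer_genes
  tb <- matrix(c(sum(sig & can), sum(sig & !can),
                 sum(!sig & can), sum(!sig & !can)), nrow = 2, byrow = TRUE)
  or <- if (tb[1, 2] > 0 && tb[2, 1] > 0) (tb[1, 1] * tb[2, 2]) / (tb[1, 2] * tb[2, 1]) else
    NA_real_
  list(table = tb, odds_ratio = or,
       p_value = stats::fisher.test(tb, alternative = "greater")$p.value)
}
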