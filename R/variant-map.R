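# Coding-variant annotation: nucleotide SNVs on single-exon gene models are
# translated to protein substitutions via direct codon mapping, classified
# synonymous / non-synonymous / stop-gain, and decorated with the per-variant
# covariates used by the selection models (GC window, codon degeneracy,
# recombination rate, conservation, disorder, PTM-region membership).

#' Annotate coding SNVs against gene models
#'
#' Translates the reference and alternate codon of every single-nucleotide
#' variant. Stop-gain changes, indel-like records and reference mismatches
#' are rejected with a reason; synonymous and non-synonymous substitutions
#' are returned with their protein coordinates.
#'
#' @param variants data.frame with columns `chrom` (protein/gene id), `pos`
#'   (1-based position within the CDS), `ref`, `alt`, and optionally `daf`,
#'   `depth`.
#' @param gene_models Named character vector of CDS nucleotide strings, one
#'   per protein, in frame (codon k encodes residue k).
#' @return data.frame with `protein`, `nt_pos`, `residue_index`, `ref`,
#'   `alt`, `ref_aa`, `alt_aa`, `daf`, `depth`, `status`
#'   (`nonsyn`/`syn`/`rejected`) and `reason` for rejections.
#' @export
annotate_variants <- function(variants, gene_models) {
  n <- nrow(variants)
  daf <- if (is.null(variants$daf)) rep(NA_real_, n) else variants$daf
  depth <- if (is.null(variants$depth)) rep(NA_real_, n) else variants$depth
  out <- data.frame(protein = as.character(variants$chrom),
                    nt_pos = as.integer(variants$pos),
                    residue_index = NA_integer_,
                    ref = as.character(variants$ref),
                    alt = as.character(variants$alt),
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    daf = daf, depth = depth,
                    status = NA_character_, reason = NA_character_,
                    stringsAsFactors = FALSE)

  reject <- function(i, why) {
    out$status[i] <<- "rejected"; out$reason[i] <<- why
  }
  known <- out$protein %in% names(gene_models)
  if (any(!known)) reject(which(!known), "unknown gene model")
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% BASES & out$alt %in% BASES & out$ref != out$alt
  if (any(!snv & known)) reject(which(!snv & known), "not a simple SNV")

  cand <- which(known & snv)
  if (length(cand)) {
    cds_len <- nchar(gene_models)[out$protein[cand]]
    inside <- out$nt_pos[cand] >= 1L & out$nt_pos[cand] <= cds_len
    reject(cand[!inside], "position outside CDS")
    cand <- cand[inside]
  }
  if (length(cand)) {
    obs_ref <- substring(gene_models[out$protein[cand]], out$nt_pos[cand], out$nt_pos[cand])
    okref <- obs_ref == out$ref[cand]
    reject(cand[!okref], "reference base mismatch")
    cand <- cand[okref]
  }
  if (length(cand)) {
    codon_idx <- (out$nt_pos[cand] - 1L) %/% 3L + 1L
    cstart <- (codon_idx - 1L) * 3L + 1L
    codon <- substring(gene_models[out$protein[cand]], cstart, cstart + 2L)
    off <- out$nt_pos[cand] - cstart + 1L
    mut <- codon
    substr(mut, off, off) <- out$alt[cand]  # substr<- is vectorized
    tab <- .codon_table()
    raa <- unname(tab[codon]); maa <- unname(tab[mut])
    out$residue_index[cand] <- codon_idx
    out$ref_aa[cand] <- raa
    out$alt_aa[cand] <- maa
    stopg <- maa == "*"
    reject(cand[stopg], "stop-gain")
    syn <- !stopg & maa == raa
    out$status[cand[syn]] <- "syn"
    out$status[cand[!stopg & !syn]] <- "nonsyn"
  }
  out
}

#' Remove non-synonymous substitutions sharing a codon
#'
#' Non-synonymous substitutions whose codon carries another non-synonymous
#' substitution are dropped (allele frequencies at such codons are ambiguous
#' at the protein level). Synonymous partners are kept. Idempotent.
#'
#' @param subs Annotated substitution table from [annotate_variants()].
#' @export
filter_codon_conflicts <- function(subs) {
  ns <- subs$status == "nonsyn"
  key <- paste(subs$protein, subs$residue_index)
  dupkey <- unique(key[ns][duplicated(key[ns])])
  drop <- ns & key %in% dupkey
  out <- subs[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag rare substitutions by derived allele frequency
#'
#' @param subs Substitution table with a `daf` column.
#' @param threshold Inclusive DAF cutoff defining "rare" (default 0.005,
#'   i.e. 0.5%).
#' @export
classify_rare <- function(subs, threshold = 0.005) {
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  subs$is_rare <- subs$daf <= threshold
  subs
}

#' GC content of the sequence window around each variant
#'
#' Percentage of G/C bases in the window of `2 * halfwidth + 1` nucleotides
#' centred on the variant, clipped at the CDS boundaries.
#'
#' @param variants data.frame with `chrom` and `pos` (CDS coordinates).
#' @param gene_models Named character vector of CDS strings.
#' @param halfwidth Window half-width in bp (default 17, i.e. a 35 bp window).
#' @return Numeric vector of GC percentages.
#' @export
gc_window <- function(variants, gene_models, halfwidth = 17L) {
  prot <- as.character(variants$chrom)
  pos <- as.integer(variants$pos)
  lens <- nchar(gene_models)[prot]
  lo <- pmax(1L, pos - halfwidth)
  hi <- pmin(lens, pos + halfwidth)
  win <- substring(gene_models[prot], lo, hi)
  gc <- nchar(gsub("[^GC]", "", win))
  unname(100 * gc / nchar(win))
}

#' Recombination rate of the nearest measured locus
#'
#' @param variants data.frame with `chrom` and `pos`.
#' @param track data.frame with `protein`, `pos`, `rate`; ties in distance
#'   resolve to the lower coordinate.
#' @return Numeric vector of rates.
#' @export
nearest_recomb <- function(variants, track) {
  if (nrow(track) == 0L) stop("empty recombination track")
  out <- rep(NA_real_, nrow(variants))
  tr_by <- split(track[order(track$pos), c("pos", "rate")], track$protein[order(track$pos)])
  idx_by <- split(seq_len(nrow(variants)), as.character(variants$chrom))
  for (p in names(idx_by)) {
    tr <- tr_by[[p]]
    if (is.null(tr) || nrow(tr) == 0L) stop("no recombination loci for ", p)
    idx <- idx_by[[p]]
    pos <- as.integer(variants$pos[idx])
    i <- findInterval(pos, tr$pos)
    lo_i <- pmax(i, 1L); hi_i <- pmin(i + 1L, nrow(tr))
    d_lo <- ifelse(i >= 1L, abs(pos - tr$pos[lo_i]), Inf)
    d_hi <- ifelse(i < nrow(tr), abs(tr$pos[hi_i] - pos), Inf)
    pick <- ifelse(d_lo <= d_hi, lo_i, hi_i)  # tie -> lower coordinate
    out[idx] <- tr$rate[pick]
  }
  out
}

# disorder intervals -> per-protein logical masks
disorder_masks <- function(disorder, proteome) {
  masks <- lapply(nchar(proteome), function(L) logical(L))
  for (i in seq_len(nrow(disorder))) {
    p <- disorder$protein[i]
    masks[[p]][disorder$start[i]:disorder$end[i]] <- TRUE
  }
  masks
}

#' Assemble the per-substitution feature table
#'
#' Joins annotated non-synonymous substitutions with the covariates used by
#' the confounder-adjusted models: conservation, codon degeneracy, GC
#' content, sequencing depth (if present), recombination rate, disorder and
#' PTM-region membership, plus the zone label where applicable.
#'
#' @param cohort A synthetic cohort (see [generate_cohort()]) or any list
#'   with `proteins`, `gene_models`, `conservation`, `disorder`, `recomb`.
#' @param subs Annotated substitutions ([annotate_variants()]), already
#'   DAF-classified ([classify_rare()]).
#' @param regions Region table ([build_regions()]).
#' @param zones Optional zone table ([classify_zones()]).
#' @return data.frame, one row per non-synonymous substitution.
#' @export
build_feature_table <- function(cohort, subs, regions, zones = NULL) {
  ns <- subs[subs$status == "nonsyn", , drop = FALSE]
  dm <- disorder_masks(cohort$disorder, cohort$proteins)
  feat <- data.frame(
    protein = ns$protein,
    residue_index = ns$residue_index,
    ref_aa = ns$ref_aa, alt_aa = ns$alt_aa,
    daf = ns$daf, is_rare = ns$is_rare,
    conservation = mapply(function(p, i) cohort$conservation[[p]][i],
                          ns$protein, ns$residue_index),
    degeneracy = codon_degeneracy(ns$ref_aa),
    gc_content = gc_window(data.frame(chrom = ns$protein, pos = ns$nt_pos),
                           cohort$gene_models),
    depth = ns$depth,
    recomb_rate = nearest_recomb(data.frame(chrom = ns$protein, pos = ns$nt_pos),
                                 cohort$recomb),
    in_disorder = mapply(function(p, i) dm[[p]][i], ns$protein, ns$residue_index),
    stringsAsFactors = FALSE)
  feat$in_ptm_region <- in_ptm_region(feat$protein, feat$residue_index, regions)
  if (!is.null(zones)) {
    key <- paste(feat$protein, feat$residue_index)
    zkey <- paste(zones$protein, zones$position)
    feat$zone <- zones$zone[match(key, zkey)]
  }
  rownames(feat) <- NULL
  feat
}
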