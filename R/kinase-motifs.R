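# Kinase PWM scanning of phosphosite flanks. A site is predicted bound when
# its 15-mer window score (product of per-position probabilities,
# pseudocounted) clears both calibration thresholds: the 10th percentile of
# positive-control scores and the 90th percentile of negative controls drawn
# from non-phosphorylated S/T/Y centres. Exhaustive substitution of bound
# windows yields motif-breaker residues (>= 4-fold score loss).

PWM_PSEUDOCOUNT <- 1e-3
PAD_SYMBOL <- "X"  # terminal padding; scores the column mean (1/20)

# pseudocounted probability matrix (rows = offsets -7..7, cols = AA + pad)
pwm_probs <- function(pwm, pseudocount = PWM_PSEUDOCOUNT) {
  m <- pwm$matrix + pseudocount
  m <- m / rowSums(m)
  cbind(m, X = rowMeans(m))
}

#' Extract 15-mer windows around protein positions
#'
#' Windows extending past a terminus are padded with the neutral symbol
#' `X`, which scores the column mean.
#'
#' @param proteome Named character vector of sequences.
#' @param protein,position Parallel vectors locating the centres.
#' @return Character vector of 15-character windows.
#' @export
flank_windows <- function(proteome, protein, position) {
  lens <- nchar(proteome)[protein]
  lo <- position - 7L
  hi <- position + 7L
  core <- substring(proteome[protein], pmax(1L, lo), pmin(lens, hi))
  left <- strrep(PAD_SYMBOL, pmax(0L, 1L - lo))
  right <- strrep(PAD_SYMBOL, pmax(0L, hi - lens))
  paste0(left, core, right)
}

#' Score 15-mer windows against a PWM
#'
#' Score = product over the 15 positions of the (pseudocounted) probability
#' of the observed residue; computed in log space.
#'
#' @param pwm A `ptmvar_pwm`.
#' @param windows Character vector of 15-character windows (pad symbol `X`
#'   allowed).
#' @return Numeric vector of scores.
#' @export
score_windows <- function(pwm, windows) {
  stopifnot(all(nchar(windows) == 15L))
  pm <- pwm_probs(pwm)
  lp <- log(pm)
  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = 15L)
  bad <- !(chars %in% colnames(pm))
  if (any(bad)) stop("non-amino-acid symbol in window: ",
                     paste(unique(chars[bad]), collapse = ","))
  tot <- numeric(length(windows))
  for (k in 1:15) {
    tot <- tot + lp[k, chars[k, ]]
  }
  exp(tot)
}

#' Score a single site window
#' @inheritParams score_windows
#' @param flank15 One 15-character window.
#' @export
score_site <- function(pwm, flank15) score_windows(pwm, flank15)

#' Calibrate PWM decision thresholds
#'
#' `pos10` is the 10th percentile of positive-control scores and `neg90` the
#' 90th percentile of negative-control scores (type-7 quantiles); a site is
#' predicted bound iff its score is at least `max(pos10, neg90)`.
#'
#' @param pwm A `ptmvar_pwm`.
#' @param positives,negatives Character vectors of 15-mer control windows.
#' @param min_pos,min_neg Minimum control counts (default 10 / 100).
#' @return The PWM with a `thresholds` element (`pos10`, `neg90`, `cutoff`).
#' @export
calibrate_pwm <- function(pwm, positives, negatives,
                          min_pos = 10L, min_neg = 100L) {
  if (length(positives) < min_pos) stop("too few positive controls: ", length(positives))
  if (length(negatives) < min_neg) stop("too few negative controls: ", length(negatives))
  sp <- score_windows(pwm, positives)
  sn <- score_windows(pwm, negatives)
  pos10 <- stats::quantile(sp, 0.10, type = 7, names = FALSE)
  neg90 <- stats::quantile(sn, 0.90, type = 7, names = FALSE)
  pwm$thresholds <- c(pos10 = pos10, neg90 = neg90, cutoff = max(pos10, neg90))
  pwm
}

#' Enumerate motif-breaker residues of bound sites
#'
#' For every flank position (offsets -7..+7 excluding the phosphoacceptor)
#' of each bound window, all 19 substitutions are evaluated; the residue is
#' a breaker when some substitution reduces the window score at least
#' 4-fold (boundary inclusive). One record per residue carries the maximal
#' fold change.
#'
#' @param pwm Calibrated `ptmvar_pwm`.
#' @param bound data.frame with `protein`, `position` (phosphosite) and
#'   `window` (15-mer).
#' @param min_fold Fold-change threshold (default 4).
#' @return data.frame `protein`, `position` (breaker residue), `kinase`,
#'   `phosphosite`, `offset`, `wt_score`, `mut_score`, `fold_change`.
#' @export
find_breakers <- function(pwm, bound, min_fold = 4) {
  if (nrow(bound) == 0L) return(NULL)
  pm <- pwm_probs(pwm)
  aa_cols <- AA_ALPHABET
  min_col <- apply(pm[, aa_cols], 1, min)
  chars <- matrix(unlist(strsplit(bound$window, ""), use.names = FALSE), nrow = 15L)
  rows <- vector("list", 0L)
  wt_scores <- score_windows(pwm, bound$window)
  for (k in setdiff(1:15, 8L)) {
    wt_p <- pm[k, chars[k, ]]
    # worst substitution at this position: lowest column probability among
    # the other 19 residues (if wt is itself the minimum, use the runner-up)
    alt_min <- vapply(seq_len(ncol(chars)), function(j) {
      v <- pm[k, setdiff(aa_cols, chars[k, j])]
      min(v)
    }, 0)
    fold <- wt_p / alt_min
    hit <- which(fold >= min_fold & chars[k, ] != PAD_SYMBOL)
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein = bound$protein[hit],
        position = bound$position[hit] + (k - 8L),
        kinase = pwm$kinase,
        phosphosite = bound$position[hit],
        offset = k - 8L,
        wt_score = wt_scores[hit],
        mut_score = wt_scores[hit] / fold[hit],
        fold_change = fold[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a cohort's phosphosites for kinase motifs
#'
#' Calibrates each PWM against positives (flanks of phosphosites annotated
#' with that kinase) and shared negatives (windows centred on
#' non-phosphorylated S/T/Y residues), predicts bound sites among all
#' phosphosites, and enumerates motif-breaker residues. Kinases with too
#' few positive controls are skipped and reported.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param n_negatives Number of negative-control windows (default 300).
#' @param seed Seed for negative-control sampling.
#' @return List `bound` (kinase-site predictions), `breakers`,
#'   `pwms` (calibrated), `skipped` (kinase ids).
#' @export
scan_kinase_motifs <- function(cohort, n_negatives = 300L, seed = 1L) {
  set.seed(seed)
  ph <- cohort$ptm_sites[cohort$ptm_sites$ptm_type == "phospho", , drop = FALSE]
  if (nrow(ph) == 0L) stop("cohort has no phosphosites")
  ph$window <- flank_windows(cohort$proteins, ph$protein, ph$position)

  # negatives: S/T/Y residues that are not phosphosites
  res <- residue_substitution_table(cohort, data.frame(
    protein = character(), residue_index = integer(), status = character(),
    is_rare = logical()), unique(ph$protein))
  sty <- res[res$aa %in% c("S", "T", "Y"), c("protein", "position")]
  phkey <- paste(ph$protein, ph$position)
  sty <- sty[!(paste(sty$protein, sty$position) %in% phkey), , drop = FALSE]
  neg_idx <- sample.int(nrow(sty), min(n_negatives, nrow(sty)))
  negatives <- flank_windows(cohort$proteins, sty$protein[neg_idx],
                             sty$position[neg_idx])

  bound_all <- vector("list", 0L)
  breakers_all <- vector("list", 0L)
  calibrated <- list()
  skipped <- character(0)
  for (kin in names(cohort$pwms)) {
    positives <- ph$window[!is.na(ph$enzyme) & ph$enzyme == kin]
    if (length(positives) < 10L) { skipped <- c(skipped, kin); next }
    pw <- calibrate_pwm(cohort$pwms[[kin]], positives, negatives,
                        min_neg = min(100L, length(negatives)))
    calibrated[[kin]] <- pw
    sc <- score_windows(pw, ph$window)
    is_bound <- sc >= pw$thresholds[["cutoff"]]
    if (!any(is_bound)) next
    bnd <- data.frame(kinase = kin, protein = ph$protein[is_bound],
                      position = ph$position[is_bound],
                      score = sc[is_bound], window = ph$window[is_bound],
                      stringsAsFactors = FALSE)
    bound_all[[kin]] <- bnd
    br <- find_breakers(pw, bnd)
    if (!is.null(br)) breakers_all[[kin]] <- br
  }
  list(bound = do.call(rbind, bound_all),
       breakers = do.call(rbind, breakers_all),
       pwms = calibrated, skipped = skipped)
}

#' Kinase-level selection and disease tests of motif-breaker sites
#'
#' Per kinase: (a) amino-acid-weighted permutation test of the rare fraction
#' at breaker residues against the phosphoprotein residue background,
#' (b) Fisher's exact test of disease annotation of breaker residues vs
#' other residues, BH-adjusted across kinases.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param subs Annotated, rare-classified substitutions.
#' @param breakers Breaker table from [scan_kinase_motifs()].
#' @param n_perm Permutations per kinase (default 200).
#' @param seed Seed.
#' @return data.frame, one row per tested kinase: permutation p, Fisher OR,
#'   p and BH q; kinases with no breaker substitutions carry `NA`
#'   permutation p.
#' @export
kinase_level_tests <- function(cohort, subs, breakers, n_perm = 200L, seed = 1L) {
  if (is.null(breakers) || nrow(breakers) == 0L) return(NULL)
  set.seed(seed)
  ph_prots <- unique(cohort$ptm_sites$protein[cohort$ptm_sites$ptm_type == "phospho"])
  residues <- residue_substitution_table(cohort, subs, ph_prots)
  rkey <- paste(residues$protein, residues$position)
  dkey <- unique(paste(cohort$disease$protein, cohort$disease$position))
  annotated <- rkey %in% dkey
  out <- lapply(split(breakers, breakers$kinase), function(br) {
    bkey <- unique(paste(br$protein, br$position))
    test_idx <- which(rkey %in% bkey)
    if (!length(test_idx)) return(NULL)
    perm_p <- obs <- exp_mean <- NA_real_
    if (sum(residues$n_subs[test_idx]) > 0L) {
      pt <- permutation_test(residues, test_idx, n_perm = n_perm,
                             alternative = "greater")
      perm_p <- pt$p_value; obs <- pt$observed; exp_mean <- pt$expected_mean
    }
    tb <- matrix(c(sum(annotated[test_idx]), sum(!annotated[test_idx]),
                   sum(annotated[-test_idx]), sum(!annotated[-test_idx])),
                 nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tb, alternative = "greater")
    data.frame(kinase = br$kinase[1], n_breaker_residues = length(test_idx),
               rare_observed = obs, rare_expected = exp_mean,
               permutation_p = perm_p,
               disease_or = (tb[1, 1] * tb[2, 2]) / max(1, tb[1, 2] * tb[2, 1]),
               fisher_p = ft$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res)) return(NULL)
  res$fisher_q <- stats::p.adjust(res$fisher_p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Kinase-substrate network and disease-gene degree test
#'
#' Builds the bipartite kinase-substrate graph from bound-site predictions
#' and compares substrate degree (number of distinct bound kinases) between
#' disease genes and other substrates with a one-sided rank-sum test.
#'
#' @param bound Bound-site table from [scan_kinase_motifs()].
#' @param disease_genes Character vector of disease gene identifiers.
#' @return List `edges` (kinase, substrate, phosphosite), `degrees`
#'   (per-substrate), `test` (`p_value`, `n_disease`, `n_other`; p is `NA`
#'   when no disease genes are present, 1 when degrees are constant).
#' @export
build_kinase_network <- function(bound, disease_genes = character(0)) {
  if (is.null(bound) || nrow(bound) == 0L) {
    return(list(edges = NULL, degrees = NULL,
                test = list(p_value = NA_real_, n_disease = 0L, n_other = 0L)))
  }
  edges <- unique(bound[, c("kinase", "protein", "position")])
  names(edges) <- c("kinase", "substrate", "phosphosite")
  deg <- tapply(edges$kinase, edges$substrate, function(k) length(unique(k)))
  degrees <- data.frame(substrate = names(deg), degree = as.integer(deg),
                        is_disease = names(deg) %in% disease_genes,
                        stringsAsFactors = FALSE)
  test <- list(p_value = NA_real_, n_disease = sum(degrees$is_disease),
               n_other = sum(!degrees$is_disease))
  if (test$n_disease > 0L && test$n_other > 0L) {
    if (stats::var(degrees$degree) == 0) {
      test$p_value <- 1
    } else {
      wt <- stats::wilcox.test(degrees$degree[degrees$is_disease],
                               degrees$degree[!degrees$is_disease],
                               alternative = "greater", exact = FALSE,
                               correct = TRUE)
      test$p_value <- wt$p.value
    }
  }
  list(edges = edges, degrees = degrees, test = test)
}
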