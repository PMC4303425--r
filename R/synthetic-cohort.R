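# Synthetic study cohorts with known planted effects. The generator emulates
# the statistical structure the downstream analyses assume: a proteome with
# realistic amino-acid composition, disordered segments, PTM sites placed
# preferentially in disorder, codon-resolved single-exon gene models, coding
# SNVs whose probability of being rare (DAF <= 0.5%) is multiplied on the
# odds scale inside PTM regions, disease annotations with an analogous
# planted odds effect, kinase PWMs with planted specificity, a gene-by-tissue
# expression matrix, and drug-enzyme link tables. Every quantity is a
# function of the config seed alone.

DISEASE_VOCAB <- c(
  "cardiomyopathy", "diabetes", "deafness", "retinitis", "epilepsy",
  "anemia", "neuropathy", "myopathy", "nephropathy", "ichthyosis",
  "cystic_fibrosis", "migraine", "hypertension", "immunodeficiency",
  "leukemia", "carcinoma", "ataxia", "dystonia", "osteopetrosis", "glaucoma")

#' Human-like amino-acid background frequencies
#' @return Named numeric 20-vector summing to 1 (order of [AA_ALPHABET]).
#' @export
default_aa_freqs <- function() {
  f <- c(A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, Q = 0.047,
         E = 0.071, G = 0.066, H = 0.026, I = 0.043, L = 0.102, K = 0.058,
         M = 0.021, F = 0.036, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
         Y = 0.027, V = 0.060)
  f / sum(f)
}

#' Simulation configuration
#'
#' Validated parameter set for [generate_cohort()]. Defaults define the
#' package's reference study conditions; rates are chosen to mirror the scale
#' of human PTM proteomics and exome cohorts (about 2 PTM sites and 8
#' substitutions per 100 residues, phosphorylation at 72% of sites, PTM
#' sites enriched in disorder at odds 2).
#'
#' @param n_proteins Number of proteins.
#' @param length_dist Mean and sd of protein length (residues).
#' @param aa_freqs Amino-acid background frequencies (20-vector summing to 1).
#' @param ptm_site_rate Expected PTM sites per 100 residues.
#' @param ptm_type_mix Proportions over phospho/ubiq/acet/methyl (sum 1).
#' @param disorder_fraction Fraction of residues in disordered intervals.
#' @param disorder_ptm_odds Odds multiplier for placing PTM sites in disorder.
#' @param variant_rate Expected substitutions per residue.
#' @param rare_fraction_base Probability a non-PTM substitution is rare.
#' @param ptm_constraint_effect Odds multiplier on the rare probability for
#'   non-synonymous substitutions inside PTM regions (1 = null).
#' @param conservation_beta Log-odds of rareness per SD of conservation
#'   (0 = conservation is a correlated but inert covariate).
#' @param disease_rate_base Per-residue probability of a disease annotation
#'   outside PTM regions.
#' @param disease_ptm_effect Odds multiplier on the disease-annotation
#'   probability inside PTM regions.
#' @param n_pwms Number of kinase PWMs.
#' @param pwm_sharpness Probability mass on the preferred residue in
#'   informative PWM columns.
#' @param enzyme_rate Fraction of phosphosites annotated with an upstream
#'   kinase (their flanks are drawn from that kinase's PWM).
#' @param n_tissues Number of tissues in the expression matrix.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `ptmvar_config`.
#' @export
simulation_config <- function(n_proteins = 300,
                              length_dist = c(mean = 400, sd = 120),
                              aa_freqs = default_aa_freqs(),
                              ptm_site_rate = 2,
                              ptm_type_mix = c(phospho = 0.72, ubiq = 0.12,
                                               acet = 0.10, methyl = 0.06),
                              disorder_fraction = 0.35,
                              disorder_ptm_odds = 2.0,
                              variant_rate = 0.08,
                              rare_fraction_base = 0.4,
                              ptm_constraint_effect = 1.5,
                              conservation_beta = 0,
                              disease_rate_base = 0.005,
                              disease_ptm_effect = 1.2,
                              n_pwms = 6,
                              pwm_sharpness = 0.8,
                              enzyme_rate = 0.3,
                              n_tissues = 40,
                              seed = 1L) {
  chk <- function(ok, field, why) if (!ok) stop("invalid config field '", field, "': ", why)
  chk(is.numeric(n_proteins) && n_proteins >= 1, "n_proteins", "must be >= 1")
  chk(length(length_dist) == 2 && length_dist[1] > 0, "length_dist", "mean must be positive")
  chk(length(aa_freqs) == 20 && abs(sum(aa_freqs) - 1) < 1e-9 && all(aa_freqs >= 0),
      "aa_freqs", "must be a 20-vector of proportions summing to 1")
  chk(abs(sum(ptm_type_mix) - 1) < 1e-9 && all(ptm_type_mix >= 0) &&
        setequal(names(ptm_type_mix), PTM_TYPES),
      "ptm_type_mix", "must be proportions over phospho/ubiq/acet/methyl summing to 1")
  chk(ptm_site_rate >= 0, "ptm_site_rate", "must be non-negative")
  chk(disorder_fraction >= 0 && disorder_fraction <= 1, "disorder_fraction", "must be in [0,1]")
  chk(disorder_ptm_odds > 0, "disorder_ptm_odds", "must be positive")
  chk(variant_rate >= 0, "variant_rate", "must be non-negative")
  chk(rare_fraction_base > 0 && rare_fraction_base < 1, "rare_fraction_base", "must be in (0,1)")
  chk(ptm_constraint_effect > 0, "ptm_constraint_effect", "must be positive")
  chk(disease_rate_base > 0 && disease_rate_base < 1, "disease_rate_base", "must be in (0,1)")
  chk(disease_ptm_effect > 0, "disease_ptm_effect", "must be positive")
  chk(n_pwms >= 1, "n_pwms", "must be >= 1")
  chk(pwm_sharpness > 0 && pwm_sharpness < 1, "pwm_sharpness", "must be in (0,1)")
  chk(enzyme_rate >= 0 && enzyme_rate <= 1, "enzyme_rate", "must be in [0,1]")
  chk(n_tissues >= 18, "n_tissues", "must be >= 18")
  cfg <- list(n_proteins = as.integer(n_proteins), length_dist = length_dist,
              aa_freqs = aa_freqs, ptm_site_rate = ptm_site_rate,
              ptm_type_mix = ptm_type_mix[PTM_TYPES],
              disorder_fraction = disorder_fraction,
              disorder_ptm_odds = disorder_ptm_odds,
              variant_rate = variant_rate,
              rare_fraction_base = rare_fraction_base,
              ptm_constraint_effect = ptm_constraint_effect,
              conservation_beta = conservation_beta,
              disease_rate_base = disease_rate_base,
              disease_ptm_effect = disease_ptm_effect,
              n_pwms = as.integer(n_pwms), pwm_sharpness = pwm_sharpness,
              enzyme_rate = enzyme_rate, n_tissues = as.integer(n_tissues),
              seed = as.integer(seed))
  class(cfg) <- "ptmvar_config"
  cfg
}

# odds-scale transform: rare probability inside PTM regions
odds_shift <- function(p, mult) stats::plogis(stats::qlogis(p) + log(mult))

.blosum_env <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .blosum_env$m
}

# expected BLOSUM62 score of aa against a random background residue,
# with a 5% gap fraction scored -10 (as in alignment-column conservation)
.mismatch_expectation <- function(aa_freqs) {
  B <- blosum62()
  exp_scores <- as.vector(B %*% aa_freqs[AA_ALPHABET])
  names(exp_scores) <- AA_ALPHABET
  0.95 * exp_scores + 0.05 * (-10)
}

make_pwm <- function(kinase, aa_freqs, sharpness) {
  bg <- aa_freqs[AA_ALPHABET]
  m <- matrix(rep(bg, 15), nrow = 15, byrow = TRUE,
              dimnames = list(as.character(-7:7), AA_ALPHABET))
  acc <- sample(c("S", "T", "Y"), 1, prob = c(0.5, 0.35, 0.15))
  centre <- stats::setNames(rep(0.02 / 17, 20), AA_ALPHABET)
  centre[c("S", "T", "Y")] <- 0.04
  centre[acc] <- 0.90
  m["0", ] <- centre / sum(centre)
  inf_off <- sort(sample(setdiff(-5:5, 0), 4))
  pref <- sample(setdiff(AA_ALPHABET, c("C", "W")), 4, replace = FALSE)
  for (k in seq_along(inf_off)) {
    v <- (1 - sharpness) * bg
    v[pref[k]] <- v[pref[k]] + sharpness
    m[as.character(inf_off[k]), ] <- v / sum(v)
  }
  structure(list(kinase = kinase, matrix = m, informative = inf_off,
                 preferred = stats::setNames(pref, as.character(inf_off)),
                 acceptor = acc),
            class = "ptmvar_pwm")
}

#' Consensus 15-mer of a PWM
#' @param pwm A `ptmvar_pwm`.
#' @return Character vector of 15 residues (positions -7..+7).
#' @export
pwm_consensus <- function(pwm) {
  colnames(pwm$matrix)[apply(pwm$matrix, 1, which.max)]
}

# PTM windows (+/-7, clipped, merged) as a logical mask over one protein
ptm_mask_from_positions <- function(site_pos, L, flank = 7L) {
  mask <- logical(L)
  for (p in site_pos) mask[max(1L, p - flank):min(L, p + flank)] <- TRUE
  mask
}

#' Generate a synthetic cohort
#'
#' Draws a full set of study inputs from a [simulation_config()]. The planted
#' effects recorded in `cohort$truth` are the targets the downstream modules
#' must recover: the odds multiplier on rare substitutions in PTM regions,
#' the disease-annotation odds multiplier, and the PWM specificities.
#'
#' @param config A `ptmvar_config`.
#' @return Object of class `ptmvar_cohort`: a list with `proteins` (named
#'   character), `gene_models`, `ptm_sites`, `disorder`, `conservation`
#'   (per-protein numeric vectors), `recomb`, `variants`, `disease`,
#'   `gene_sets`, `expression`, `pwms`, `drug_links`, `truth`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ptmvar_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  prot_ids <- sprintf("P%04d", seq_len(n))

  lens <- pmax(60L, as.integer(round(stats::rnorm(n, config$length_dist[1],
                                                  config$length_dist[2]))))
  names(lens) <- prot_ids
  seq_chars <- lapply(lens, function(L)
    sample(AA_ALPHABET, L, replace = TRUE, prob = config$aa_freqs))

  # --- disordered intervals ---------------------------------------------
  disorder_list <- vector("list", n)
  dis_masks <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    target <- config$disorder_fraction * L
    mask <- logical(L)
    guard <- 0L
    while (sum(mask) < target && guard < 200L) {
      w <- 5L + stats::rgeom(1, 1 / 25)
      s <- sample.int(max(1L, L - w + 1L), 1)
      mask[s:min(L, s + w - 1L)] <- TRUE
      guard <- guard + 1L
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    disorder_list[[i]] <- if (any(keep))
      data.frame(protein = prot_ids[i], start = starts[keep], end = ends[keep],
                 stringsAsFactors = FALSE) else NULL
    dis_masks[[i]] <- mask
  }
  names(dis_masks) <- prot_ids
  disorder <- do.call(rbind, disorder_list[!vapply(disorder_list, is.null, TRUE)])
  if (is.null(disorder))
    disorder <- data.frame(protein = character(), start = integer(),
                           end = integer(), stringsAsFactors = FALSE)

  # --- PWMs (needed before site flanks are written) ----------------------
  kin_ids <- sprintf("KIN%02d", seq_len(config$n_pwms))
  pwms <- lapply(kin_ids, make_pwm, aa_freqs = config$aa_freqs,
                 sharpness = config$pwm_sharpness)
  names(pwms) <- kin_ids

  # --- PTM sites ---------------------------------------------------------
  s_prot <- s_pos <- s_type <- vector("list", n)
  for (i in seq_len(n)) {
    L <- lens[i]
    k <- stats::rpois(1, config$ptm_site_rate / 100 * L)
    if (k == 0L) next
    types <- sample(PTM_TYPES, k, replace = TRUE, prob = config$ptm_type_mix)
    taken <- integer(0)
    pos_acc <- integer(0); type_acc <- character(0)
    for (t in PTM_TYPES) {
      kt <- sum(types == t)
      if (kt == 0L) next
      cand <- setdiff(which(seq_chars[[i]] %in% PTM_ALLOWED_AA[[t]]), taken)
      if (!length(cand)) next
      w <- ifelse(dis_masks[[i]][cand], config$disorder_ptm_odds, 1)
      kt <- min(kt, length(cand))
      pos <- cand[sample.int(length(cand), kt, prob = w)]
      taken <- c(taken, pos)
      pos_acc <- c(pos_acc, pos); type_acc <- c(type_acc, rep(t, kt))
    }
    s_prot[[i]] <- rep(prot_ids[i], length(pos_acc))
    s_pos[[i]] <- pos_acc; s_type[[i]] <- type_acc
  }
  s_prot <- unlist(s_prot); s_pos <- unlist(s_pos); s_type <- unlist(s_type)
  ptm_sites <- data.frame(
    protein = s_prot %||% character(0),
    position = s_pos %||% integer(0),
    residue = if (length(s_prot)) mapply(function(p, q) seq_chars[[p]][q],
                                         s_prot, s_pos, USE.NAMES = FALSE) else character(0),
    ptm_type = s_type %||% character(0),
    n_pubs = 1L + stats::rpois(length(s_prot), 0.8),
    enzyme = rep(NA_character_, length(s_prot)),
    stringsAsFactors = FALSE)

  # --- kinase assignment + motif-shaped flanks ---------------------------
  is_ph <- ptm_sites$ptm_type == "phospho"
  assign <- is_ph & stats::runif(nrow(ptm_sites)) < config$enzyme_rate
  ptm_sites$enzyme[assign] <- sample(kin_ids, sum(assign), replace = TRUE)
  site_pos_by_prot <- split(ptm_sites$position, ptm_sites$protein)
  for (j in which(assign)) {
    p <- ptm_sites$protein[j]; pos <- ptm_sites$position[j]
    L <- lens[[p]]
    pw <- pwms[[ptm_sites$enzyme[j]]]$matrix
    other_sites <- setdiff(site_pos_by_prot[[p]], pos)
    for (off in setdiff(-7:7, 0)) {
      q <- pos + off
      if (q < 1L || q > L || q %in% other_sites) next
      seq_chars[[p]][q] <- sample(AA_ALPHABET, 1, prob = pw[as.character(off), ])
    }
  }
  # refresh residue field in case a site's own residue was never touched
  # (site positions are skipped above, so residues still match)

  proteins <- vapply(seq_chars, paste, "", collapse = "")

  # --- PTM-region masks --------------------------------------------------
  ptm_masks <- lapply(prot_ids, function(p) {
    ptm_mask_from_positions(site_pos_by_prot[[p]], lens[[p]])
  })
  names(ptm_masks) <- prot_ids

  # --- gene models (codons sampled per amino acid, globally) -------------
  by_aa <- .codons_for_aa()
  aa_all <- unlist(seq_chars, use.names = FALSE)
  cdn_all <- character(length(aa_all))
  for (a in sort(unique(aa_all))) {
    idx <- which(aa_all == a)
    choices <- by_aa[[a]]
    cdn_all[idx] <- choices[sample.int(length(choices), length(idx), replace = TRUE)]
  }
  codon_list <- split(cdn_all, rep(seq_len(n), lens))
  names(codon_list) <- prot_ids
  gene_models <- vapply(codon_list, paste, "", collapse = "")

  # --- conservation track ------------------------------------------------
  B <- blosum62()
  self_score <- diag(B)[AA_ALPHABET]
  mis <- .mismatch_expectation(config$aa_freqs)
  conservation <- vector("list", n)
  for (i in seq_len(n)) {
    aa <- seq_chars[[i]]
    p_match <- ifelse(dis_masks[[i]],
                      stats::rbeta(lens[i], 4, 6),
                      stats::rbeta(lens[i], 8, 2))
    conservation[[i]] <- p_match * self_score[aa] + (1 - p_match) * mis[aa] +
      stats::rnorm(lens[i], 0, 0.5)
  }
  names(conservation) <- prot_ids

  # --- recombination track ----------------------------------------------
  loci_list <- lapply(lens, function(L) seq(1L, 3L * L, by = 150L))
  n_loci <- lengths(loci_list)
  recomb <- data.frame(protein = rep(prot_ids, n_loci),
                       pos = unlist(loci_list, use.names = FALSE),
                       rate = stats::rexp(sum(n_loci), 1 / 1.5),
                       stringsAsFactors = FALSE)

  # --- variants ----------------------------------------------------------
  tab <- .codon_table()
  p_rare_base <- config$rare_fraction_base
  # alternatives to each reference base, for vectorized alt sampling
  alt_mat <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  m_p <- stats::rgamma(n, shape = 4, rate = 4)
  nv <- pmin(stats::rpois(n, config$variant_rate * m_p * lens), 3L * lens)
  v_prot_i <- rep(seq_len(n), nv)
  ntpos <- unlist(lapply(seq_len(n), function(i)
    if (nv[i] > 0L) sort(sample.int(3L * lens[i], nv[i])) else integer(0)),
    use.names = FALSE)
  codon_idx <- (ntpos - 1L) %/% 3L + 1L
  off <- ntpos - (codon_idx - 1L) * 3L
  # flatten codons / masks / conservation over all proteins
  glob_off <- cumsum(c(0L, lens[-n]))
  flat_idx <- glob_off[v_prot_i] + codon_idx
  cdn <- unlist(codon_list, use.names = FALSE)[flat_idx]
  ref <- substring(cdn, off, off)
  alt <- alt_mat[cbind(match(ref, BASES), sample.int(3L, length(ref), replace = TRUE))]
  mut <- cdn
  substr(mut, off, off) <- alt
  raa <- unname(tab[cdn]); maa <- unname(tab[mut])
  keep <- maa != "*"
  v_prot_i <- v_prot_i[keep]; ntpos <- ntpos[keep]; codon_idx <- codon_idx[keep]
  ref <- ref[keep]; alt <- alt[keep]
  nonsyn <- maa[keep] != raa[keep]
  ptm_flat <- unlist(ptm_masks, use.names = FALSE)[glob_off[v_prot_i] + codon_idx]
  consv_flat <- unlist(conservation, use.names = FALSE)
  consv_std_all <- (consv_flat - mean(consv_flat)) / max(stats::sd(consv_flat), 1e-6)
  consv_std <- consv_std_all[glob_off[v_prot_i] + codon_idx]
  lp <- stats::qlogis(p_rare_base) +
    ifelse(nonsyn & ptm_flat, log(config$ptm_constraint_effect), 0) +
    ifelse(nonsyn, config$conservation_beta * consv_std, 0)
  rare <- stats::runif(length(lp)) < stats::plogis(lp)
  daf <- ifelse(rare, stats::runif(length(lp), 1e-6, 0.005),
                stats::runif(length(lp), 0.0051, 0.5))
  variants <- data.frame(
    chrom = prot_ids[v_prot_i], pos = ntpos, ref = ref, alt = alt,
    daf = daf, depth = 1L + stats::rnbinom(length(lp), mu = 60, size = 10),
    stringsAsFactors = FALSE)

  # --- disease annotations ----------------------------------------------
  ptm_flat_all <- unlist(ptm_masks, use.names = FALSE)
  p_dis <- ifelse(ptm_flat_all,
                  odds_shift(config$disease_rate_base, config$disease_ptm_effect),
                  config$disease_rate_base)
  hit <- which(stats::runif(length(p_dis)) < p_dis)
  prot_of_res <- rep(seq_len(n), lens)
  disease <- data.frame(
    protein = prot_ids[prot_of_res[hit]],
    position = hit - glob_off[prot_of_res[hit]],
    disease = sample(DISEASE_VOCAB, length(hit), replace = TRUE),
    n_records = 1L + stats::rpois(length(hit), 0.4),
    stringsAsFactors = FALSE)

  # --- gene sets ---------------------------------------------------------
  n_sets <- max(10L, n %/% 15L)
  gene_sets <- lapply(seq_len(n_sets), function(k) {
    sz <- sample(5:min(60L, max(6L, n %/% 3L)), 1)
    sort(sample(prot_ids, sz))
  })
  names(gene_sets) <- sprintf("SET%03d", seq_len(n_sets))

  # --- expression matrix -------------------------------------------------
  tissues <- c(sprintf("tissue_%02d", seq_len(config$n_tissues - 4L)),
               "skin_1", "skin_2", "uterus_1", "uterus_2")
  expr <- matrix(stats::rnorm(n * config$n_tissues, 6, 0.3), nrow = n,
                 dimnames = list(prot_ids, tissues))
  cls <- sample(c("flat", "specific", "broad"), n, replace = TRUE,
                prob = c(0.70, 0.20, 0.10))
  for (i in seq_len(n)) {
    if (cls[i] == "specific") {
      expr[i, sample.int(config$n_tissues, sample(1:3, 1))] <-
        expr[i, 1] + 4 + stats::rnorm(1, 0, 0.3)
    } else if (cls[i] == "broad") {
      k <- sample(18:min(25L, config$n_tissues - 8L), 1)
      expr[i, sample.int(config$n_tissues, k)] <- 10 + stats::rnorm(k, 0, 0.3)
    }
  }

  # --- drug links --------------------------------------------------------
  drug_ids <- sprintf("DRUG%02d", seq_len(max(4L, config$n_pwms)))
  drug_links <- unique(data.frame(
    drug = sample(drug_ids, 2L * config$n_pwms, replace = TRUE),
    enzyme = sample(kin_ids, 2L * config$n_pwms, replace = TRUE),
    stringsAsFactors = FALSE))

  truth <- list(
    ptm_constraint_effect = config$ptm_constraint_effect,
    rare_fraction_base = config$rare_fraction_base,
    disease_ptm_effect = config$disease_ptm_effect,
    expression_class = stats::setNames(cls, prot_ids),
    planted_motifs = NULL,
    planted_hotspots = NULL)

  structure(list(proteins = proteins, gene_models = gene_models,
                 ptm_sites = ptm_sites, disorder = disorder,
                 conservation = conservation, recomb = recomb,
                 variants = variants, disease = disease,
                 gene_sets = gene_sets, expression = expr, pwms = pwms,
                 drug_links = drug_links, truth = truth, config = config),
            class = "ptmvar_cohort")
}

#' Embed a kinase's consensus motif at phosphosite flanks
#'
#' Rewrites the +/-7 flank of `n_sites` phosphosites to the PWM's consensus
#' sequence (central residue untouched), updates the gene models and drops
#' variants whose codons were rewritten, and records the planted sites in
#' `truth$planted_motifs`. Candidate sites are interior phosphosites whose
#' window contains no other PTM site; selection is deterministic (protein
#' order).
#'
#' @param cohort A `ptmvar_cohort`.
#' @param pwm_id Kinase identifier present in `cohort$pwms`.
#' @param n_sites Number of sites to plant.
#' @return The modified cohort.
#' @export
plant_motif_breakers <- function(cohort, pwm_id, n_sites) {
  stopifnot(inherits(cohort, "ptmvar_cohort"))
  if (!pwm_id %in% names(cohort$pwms)) stop("unknown PWM: ", pwm_id)
  if (n_sites < 0) stop("n_sites must be non-negative")
  ph <- cohort$ptm_sites[cohort$ptm_sites$ptm_type == "phospho", , drop = FALSE]
  lens <- nchar(cohort$proteins)
  site_pos_by_prot <- split(cohort$ptm_sites$position, cohort$ptm_sites$protein)
  interior <- ph$position >= 8L & ph$position <= lens[ph$protein] - 7L
  clean <- vapply(seq_len(nrow(ph)), function(j) {
    others <- setdiff(site_pos_by_prot[[ph$protein[j]]], ph$position[j])
    !any(abs(others - ph$position[j]) <= 7L)
  }, TRUE)
  cand <- ph[interior & clean, , drop = FALSE]
  cand <- cand[order(cand$protein, cand$position), , drop = FALSE]
  if (n_sites > nrow(cand)) {
    stop("not enough eligible phosphosites: need ", n_sites, ", have ", nrow(cand))
  }
  planted <- cand[seq_len(n_sites), , drop = FALSE]
  cons <- pwm_consensus(cohort$pwms[[pwm_id]])
  names(cons) <- as.character(-7:7)
  by_aa <- .codons_for_aa()
  dropped_variants <- 0L
  for (j in seq_len(nrow(planted))) {
    p <- planted$protein[j]; pos <- planted$position[j]
    s <- strsplit(cohort$proteins[[p]], "")[[1]]
    cd <- substring(cohort$gene_models[[p]],
                    seq(1L, 3L * lens[[p]], 3L), seq(3L, 3L * lens[[p]], 3L))
    changed <- integer(0)
    for (off in setdiff(-7:7, 0)) {
      q <- pos + off
      newaa <- cons[[as.character(off)]]
      if (s[q] != newaa) {
        s[q] <- newaa
        cd[q] <- by_aa[[newaa]][1]
        changed <- c(changed, q)
      }
    }
    cohort$proteins[[p]] <- paste(s, collapse = "")
    cohort$gene_models[[p]] <- paste(cd, collapse = "")
    if (length(changed) && !is.null(cohort$variants)) {
      v_idx <- which(cohort$variants$chrom == p &
                       ((cohort$variants$pos - 1L) %/% 3L + 1L) %in% changed)
      if (length(v_idx)) {
        cohort$variants <- cohort$variants[-v_idx, , drop = FALSE]
        dropped_variants <- dropped_variants + length(v_idx)
      }
    }
  }
  rec <- data.frame(pwm = rep(pwm_id, nrow(planted)),
                    protein = planted$protein,
                    position = planted$position,
                    informative_offsets = rep(
                      paste(cohort$pwms[[pwm_id]]$informative, collapse = ","),
                      nrow(planted)),
                    stringsAsFactors = FALSE)
  cohort$truth$planted_motifs <- rbind(cohort$truth$planted_motifs, rec)
  cohort$truth$dropped_variants <- (cohort$truth$dropped_variants %||% 0L) + dropped_variants
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant a disease-mutation hotspot into one PTM region
#'
#' Adds disease records to a chosen protein's largest PTM region until the
#' region's record count reaches `multiplier` times the count expected from
#' the protein-wide average density, and records the planted gene in
#' `truth$planted_hotspots`. Used for hotspot-model parameter recovery.
#'
#' @param cohort A `ptmvar_cohort`.
#' @param protein Target protein (default: the protein with the largest PTM
#'   region).
#' @param multiplier Density multiplier (default 5).
#' @return The modified cohort.
#' @export
plant_mutation_hotspot <- function(cohort, protein = NULL, multiplier = 5) {
  regions <- build_regions(cohort$ptm_sites, cohort$proteins)
  if (nrow(regions) == 0L) stop("cohort has no PTM regions")
  regions$width <- regions$end - regions$start + 1L
  if (is.null(protein)) {
    protein <- regions$protein[which.max(regions$width)]
  }
  rg <- regions[regions$protein == protein, , drop = FALSE]
  if (nrow(rg) == 0L) stop("protein has no PTM region: ", protein)
  rg <- rg[which.max(rg$width), , drop = FALSE]
  L <- nchar(cohort$proteins[[protein]])
  d <- cohort$disease
  prot_records <- sum(d$n_records[d$protein == protein])
  base_density <- max(prot_records / L, 1 / L)
  target <- ceiling(multiplier * base_density * rg$width)
  in_reg <- d$protein == protein & d$position >= rg$start & d$position <= rg$end
  have <- sum(d$n_records[in_reg])
  add <- max(0L, target - have)
  if (add > 0L) {
    pos <- sample(rg$start:rg$end, add, replace = TRUE)
    cohort$disease <- rbind(d, data.frame(
      protein = protein, position = pos,
      disease = sample(DISEASE_VOCAB, add, replace = TRUE),
      n_records = 1L, stringsAsFactors = FALSE))
  }
  cohort$truth$planted_hotspots <- rbind(
    cohort$truth$planted_hotspots,
    data.frame(protein = protein, region_id = rg$region_id,
               multiplier = multiplier, added = add, stringsAsFactors = FALSE))
  cohort
}
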