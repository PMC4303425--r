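# Binomial logistic modelling of rare vs common substitutions. The null
# model carries the six confounders (conservation, codon degeneracy, GC
# content, sequencing depth when present, recombination rate, disorder) with
# interactions up to a configurable order; the alternative model adds the
# PTM-region flag and its interactions. PTM significance is the
# likelihood-ratio chi-square between the two fits; other predictors are
# ranked by single-term-deletion deviance.

CONFOUNDER_VARS <- c("conservation", "degeneracy", "gc_content", "depth",
                     "recomb_rate", "in_disorder")

# standardize continuous predictors; binary flags to 0/1
prepare_features <- function(features, use_depth = TRUE) {
  df <- features
  if (!use_depth || all(is.na(df$depth))) df$depth <- NULL
  for (v in intersect(c("conservation", "degeneracy", "gc_content", "depth",
                        "recomb_rate"), names(df))) {
    s <- stats::sd(df[[v]])
    df[[v]] <- if (is.na(s) || s == 0) 0 else (df[[v]] - mean(df[[v]])) / s
  }
  df$in_disorder <- as.integer(df$in_disorder)
  df$in_ptm_region <- as.integer(df$in_ptm_region)
  df$is_rare <- as.integer(df$is_rare)
  df
}

#' Fit null and alternative rare-substitution models
#'
#' @param features Feature table from [build_feature_table()].
#' @param max_interaction_order Interaction order among predictors
#'   (1 = main effects only; default 2).
#' @param use_depth Include sequencing depth (dropped automatically when the
#'   column is absent or all-missing, as for cohorts without depth data).
#' @return List `null` and `alt` glm fits, plus `data` (the prepared table)
#'   and `terms_added` (the PTM terms distinguishing the fits).
#' @export
fit_rare_models <- function(features, max_interaction_order = 2L,
                            use_depth = TRUE) {
  stopifnot(is.data.frame(features), "is_rare" %in% names(features))
  df <- prepare_features(features, use_depth)
  if (min(table(df$is_rare)) < 50L) {
    stop("need at least 50 substitutions in each response class")
  }
  conf <- intersect(CONFOUNDER_VARS, names(df))
  ord <- max(1L, as.integer(max_interaction_order))
  rhs_null <- if (ord == 1L) paste(conf, collapse = " + ") else
    sprintf("(%s)^%d", paste(conf, collapse = " + "), ord)
  rhs_alt <- if (ord == 1L) paste(c(conf, "in_ptm_region"), collapse = " + ") else
    sprintf("(%s)^%d", paste(c(conf, "in_ptm_region"), collapse = " + "), ord)
  fit_with_data <- function(rhs) {
    fit <- stats::glm(stats::as.formula(paste("is_rare ~", rhs)),
                      family = stats::binomial(), data = df)
    # embed the data in the call so step()/update()/drop1() can re-evaluate
    # it outside this frame
    fit$call$data <- df
    fit
  }
  null_fit <- fit_with_data(rhs_null)
  alt_fit <- fit_with_data(rhs_alt)
  for (f in list(null_fit, alt_fit)) {
    if (!f$converged) {
      bad <- names(stats::coef(f))[is.na(stats::coef(f)) |
                                     abs(stats::coef(f)) > 15]
      stop("model did not converge; suspect terms: ",
           paste(bad, collapse = ", "))
    }
  }
  list(null = null_fit, alt = alt_fit, data = df,
       terms_added = setdiff(attr(stats::terms(alt_fit), "term.labels"),
                             attr(stats::terms(null_fit), "term.labels")))
}

#' Backward AIC selection respecting marginality
#'
#' Iteratively removes the term whose deletion most improves AIC until no
#' removal helps. `stats::step()` supplies the machinery; marginality (no
#' main effect dropped while an interaction containing it remains) is its
#' default behaviour.
#'
#' @param fit A glm.
#' @return The reduced glm.
#' @export
backward_select <- function(fit) {
  stats::step(fit, direction = "backward", trace = 0)
}

#' Likelihood-ratio p-value between nested fits
#'
#' @param null_fit,alt_fit Nested glm fits (alt must contain null's terms).
#' @return List `delta_deviance`, `df`, `p_value`.
#' @export
lrt_pvalue <- function(null_fit, alt_fit) {
  dd <- stats::deviance(null_fit) - stats::deviance(alt_fit)
  df <- null_fit$df.residual - alt_fit$df.residual
  if (df < 0 || dd < -1e-8) stop("models are not nested (null within alt)")
  if (df == 0L) stop("zero degrees of freedom between fits")
  list(delta_deviance = dd, df = df,
       p_value = stats::pchisq(max(dd, 0), df, lower.tail = FALSE))
}

#' Deviance ranking of predictors
#'
#' Ranks the alternative model's terms by single-term-deletion deviance
#' (chi-square tests via `drop1`), with the PTM contribution assessed as the
#' likelihood ratio of the alternative over the null model. Effect signs
#' come from the corresponding main-effect coefficients.
#'
#' @param fits Output of [fit_rare_models()] (optionally with `alt` replaced
#'   by a [backward_select()]-reduced fit).
#' @return data.frame `term`, `delta_deviance`, `df`, `p`, `effect_sign`,
#'   `rank` (1 = strongest predictor); the PTM row is labelled
#'   `in_ptm_region (LRT)`.
#' @export
deviance_rank <- function(fits) {
  alt <- fits$alt
  d1 <- stats::drop1(alt, test = "Chisq")
  d1 <- d1[-1, , drop = FALSE]  # remove <none> row
  terms <- rownames(d1)
  keep <- !grepl("in_ptm_region", terms)
  tab <- data.frame(term = terms[keep],
                    delta_deviance = d1$Deviance[keep] - stats::deviance(alt),
                    df = d1$Df[keep],
                    p = d1$`Pr(>Chi)`[keep],
                    stringsAsFactors = FALSE)
  # matched null: the alternative fit with every PTM-containing term removed
  # (robust to backward selection having altered the confounder terms)
  ptm_terms <- grep("in_ptm_region", attr(stats::terms(alt), "term.labels"),
                    value = TRUE)
  matched_null <- if (length(ptm_terms)) {
    stats::update(alt, stats::as.formula(
      paste(". ~ . -", paste(ptm_terms, collapse = " - "))))
  } else alt
  ptm <- if (length(ptm_terms) &&
             alt$df.residual < matched_null$df.residual) {
    lrt_pvalue(matched_null, alt)
  } else {
    # PTM flag constant or aliased: alternative collapses onto the null
    list(delta_deviance = 0, df = NA_integer_, p_value = 1)
  }
  tab <- rbind(tab, data.frame(term = "in_ptm_region (LRT)",
                               delta_deviance = ptm$delta_deviance,
                               df = ptm$df, p = ptm$p_value,
                               stringsAsFactors = FALSE))
  cf <- stats::coef(alt)
  main_of <- function(tr) sub(" \\(LRT\\)$", "", tr)
  tab$effect_sign <- vapply(tab$term, function(tr) {
    v <- main_of(tr)
    if (v %in% names(cf) && !is.na(cf[[v]])) {
      if (cf[[v]] >= 0) "+" else "-"
    } else NA_character_
  }, "")
  tab <- tab[order(-tab$delta_deviance), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
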