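# End-to-end orchestration over a synthetic cohort (or one read from disk).
# Stages run in dependency order with per-stage seeds derived from the
# config seed; every output table carries a provenance header (package
# version, config hash, seed) and reruns with the same config are
# byte-identical.

#' Demo run configuration
#'
#' The bundled synthetic demo: a 300-protein cohort with a modest planted
#' constraint effect, one planted consensus motif and one planted mutation
#' hotspot.
#'
#' @param seed Integer seed.
#' @return A `ptmvar_config`.
#' @export
demo_config <- function(seed = 1L) {
  simulation_config(n_proteins = 300, ptm_constraint_effect = 2.0,
                    disease_rate_base = 0.01, disease_ptm_effect = 1.5,
                    seed = seed)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, builds PTM regions, annotates variants,
#' and runs the selection, confounder-model, permutation, kinase-motif,
#' disease-enrichment, context and drug-network stages, writing one TSV per
#' result under `out_dir`. A stage failure aborts with the stage name.
#'
#' @param config A `ptmvar_config`, or a `ptmvar_cohort` to skip generation.
#' @param out_dir Output directory.
#' @param n_bins Variation-matched bins for the selection stage.
#' @param n_perm Permutations for the resampling stages.
#' @param trend_bins Bins for expression/conservation trends.
#' @param fdr Gene/group FDR threshold (default 0.05).
#' @param write_cohort_files Also write the cohort itself (default TRUE).
#' @return Invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, n_bins = 100L, n_perm = 200L,
                         trend_bins = 50L, fdr = 0.05,
                         write_cohort_files = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (inherits(config, "ptmvar_cohort")) {
    cohort <- config
    cfg <- cohort$config
  } else {
    cfg <- config
    cohort <- stage("simulate", generate_cohort(cfg))
  }
  seed0 <- as.integer(cfg$seed)
  cfg_json <- tempfile(fileext = ".json")
  cfg_plain <- cfg; class(cfg_plain) <- NULL
  jsonlite::write_json(cfg_plain, cfg_json, auto_unbox = TRUE, digits = NA)
  prov <- c(tool = paste0("ptmvar ", as.character(utils::packageVersion("ptmvar"))),
            config_hash = unname(tools::md5sum(cfg_json)),
            seed = seed0)
  unlink(cfg_json)
  emit <- function(x, f) if (!is.null(x) && nrow(x) > 0)
    write_tsv(x, file.path(out_dir, f), provenance = prov)

  if (write_cohort_files) stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))
  message("cohort: ", length(cohort$proteins), " proteins, ",
          nrow(cohort$variants), " variants")

  res <- list(cohort = cohort)
  res$regions <- stage("regions", build_regions(cohort$ptm_sites, cohort$proteins))
  res$zones <- stage("regions", classify_zones(res$regions, cohort$ptm_sites))
  res$clusters <- stage("regions", cluster_bins(res$regions, cohort$ptm_sites))
  emit(res$regions, "regions.tsv")
  message("regions: ", nrow(res$regions), " merged PTM regions")

  res$subs <- stage("annotate", {
    ann <- annotate_variants(cohort$variants, cohort$gene_models)
    classify_rare(filter_codon_conflicts(ann))
  })
  res$features <- stage("annotate",
                        build_feature_table(cohort, res$subs, res$regions, res$zones))
  emit(res$subs[res$subs$status != "rejected", ], "substitutions.tsv")
  message("annotate: ", sum(res$subs$status == "nonsyn"), " non-synonymous, ",
          sum(res$subs$status == "syn"), " synonymous, ",
          sum(res$subs$status == "rejected"), " rejected")

  res$selection <- stage("selection",
                         selection_analysis(cohort, res$subs, res$regions, n_bins))
  emit(res$selection$bin_table, "selection_bins.tsv")
  emit(res$selection$summaries, "selection_summaries.tsv")
  emit(data.frame(metric = names(res$selection$tests),
                  p = vapply(res$selection$tests, `[[`, 0, "p_value"),
                  n_informative = vapply(res$selection$tests, `[[`, 0L, "n_informative")),
       "selection_tests.tsv")

  res$model <- stage("model", {
    fits <- fit_rare_models(res$features, max_interaction_order = 2L)
    fits$alt <- backward_select(fits$alt)
    fits$deviance_table <- deviance_rank(fits)
    fits
  })
  emit(res$model$deviance_table, "deviance_table.tsv")

  res$permutation <- stage("permute", {
    zp <- do.call(rbind, lapply(list(NULL, "phospho", "ubiq", "acet", "methyl"),
                                function(t) zone_permutation_analysis(
                                  cohort, res$subs, t, n_perm, seed0 + 11L)))
    cp <- cluster_permutation_analysis(cohort, res$subs, n_perm, seed0 + 12L)
    list(zones = zp, clusters = cp)
  })
  emit(res$permutation$zones, "permutation_zones.tsv")
  emit(res$permutation$clusters, "permutation_clusters.tsv")

  res$motifs <- stage("motifs", {
    sc <- scan_kinase_motifs(cohort, seed = seed0 + 21L)
    sc$kinase_tests <- kinase_level_tests(cohort, res$subs, sc$breakers,
                                          n_perm = n_perm, seed = seed0 + 22L)
    disease_in_regions <- unique(cohort$disease$protein[
      in_ptm_region(cohort$disease$protein, cohort$disease$position, res$regions)])
    sc$network <- build_kinase_network(sc$bound, disease_in_regions)
    sc
  })
  emit(res$motifs$breakers, "motif_breakers.tsv")
  emit(res$motifs$kinase_tests, "kinase_tests.tsv")
  emit(res$motifs$network$edges, "kinase_network_edges.tsv")
  if (!is.null(res$motifs$breakers))
    message("motifs: ", nrow(unique(res$motifs$breakers[, c("protein", "position")])),
            " motif-breaker residues")

  res$disease <- stage("disease", {
    pad <- active_driver(cohort, res$regions)
    cancer <- unique(cohort$disease$protein[
      cohort$disease$disease %in% c("leukemia", "carcinoma")])
    list(fisher = region_enrichment_fisher(cohort, res$regions),
         poisson = region_enrichment_poisson(cohort, res$regions),
         central = central_residue_enrichment(cohort),
         pad = pad,
         cancer = if (!is.null(pad))
           cancer_gene_enrichment(pad$protein[pad$gene_q < fdr], cancer,
                                  pad$protein))
  })
  emit(res$disease$fisher, "disease_fisher.tsv")
  emit(res$disease$poisson, "disease_poisson.tsv")
  emit(res$disease$central, "disease_central_residues.tsv")
  emit(res$disease$pad, "active_driver.tsv")

  res$context <- stage("context", {
    ub <- define_ubiquitous(cohort$expression)
    sets <- c(cohort$gene_sets,
              list(ubiquitous = ub$ubiquitous),
              ub$tissue_sets[lengths(ub$tissue_sets) >= 5])
    gt <- run_group_tests(res$features, sets)
    disease_genes <- unique(cohort$disease$protein[
      in_ptm_region(cohort$disease$protein, cohort$disease$position, res$regions)])
    universe <- unique(res$features$protein)
    ov <- if (!is.null(gt)) disease_overlap(gt, sets, disease_genes, universe, fdr)
    expr_med <- apply(cohort$expression, 1, stats::median)
    consv_med <- vapply(cohort$conservation, stats::median, 0)
    list(groups = gt, overlap = ov,
         map = if (!is.null(gt)) enrichment_map_export(gt, sets, ov, fdr),
         expression_trend = tryCatch(
           binned_trend(res$features, expr_med, trend_bins), error = function(e) NULL),
         conservation_trend = tryCatch(
           binned_trend(res$features, consv_med, trend_bins), error = function(e) NULL),
         words = disease_word_frequencies(cohort$disease, disease_genes))
  })
  emit(res$context$groups, "context_groups.tsv")
  emit(res$context$overlap, "context_disease_overlap.tsv")
  emit(res$context$map$nodes, "enrichment_map_nodes.tsv")
  emit(res$context$map$edges, "enrichment_map_edges.tsv")
  emit(res$context$words, "disease_word_frequencies.tsv")
  if (!is.null(res$context$expression_trend))
    emit(res$context$expression_trend$bin_table, "expression_trend.tsv")
  if (!is.null(res$context$conservation_trend))
    emit(res$context$conservation_trend$bin_table, "conservation_trend.tsv")

  res$drugnet <- stage("drugnet", {
    dn <- assemble_drug_network(res$disease$pad, cohort$ptm_sites,
                                cohort$drug_links, cohort$disease, fdr)
    dn$pairs <- pair_summary(dn$paths)
    dn
  })
  emit(res$drugnet$paths, "drug_disease_paths.tsv")
  emit(res$drugnet$pairs, "drug_disease_pairs.tsv")
  message("pipeline complete: ", out_dir)
  invisible(res)
}
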