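# On-disk representation of a cohort: plain-text FASTA/TSV/GMT/JSON files
# with fixed formatting, so identical configs produce byte-identical trees.

#' Write a cohort to a directory
#'
#' @param cohort A `ptmvar_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_fasta_proteins(cohort$proteins, fp("proteins.fasta"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$gene_models),
                              fp("gene_models.fasta"), width = 70L)
  write_tsv(cohort$ptm_sites, fp("ptm_sites.tsv"))
  write_tsv(cohort$disorder, fp("disorder.tsv"))
  consv <- data.frame(
    protein = rep(names(cohort$conservation), lengths(cohort$conservation)),
    position = unlist(lapply(cohort$conservation, seq_along), use.names = FALSE),
    score = round(unlist(cohort$conservation, use.names = FALSE), 4))
  write_tsv(consv, fp("conservation.tsv"))
  write_tsv(cohort$recomb, fp("recomb.tsv"))
  write_tsv(cohort$variants, fp("variants.tsv"))
  write_tsv(cohort$disease, fp("disease.tsv"))
  write_gmt(cohort$gene_sets, fp("gene_sets.gmt"))
  expr <- data.frame(protein = rownames(cohort$expression),
                     round(cohort$expression, 4), check.names = FALSE)
  write_tsv(expr, fp("expression.tsv"))
  write_pwms(cohort$pwms, fp("pwms.tsv"))
  write_tsv(cohort$drug_links, fp("drug_links.tsv"))
  jsonlite::write_json(cohort$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, fp("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `ptmvar_cohort` (PWM planting metadata lives in `truth.json`).
#' @export
read_cohort <- function(dir) {
  fp <- function(f) file.path(dir, f)
  proteins <- read_fasta_proteins(fp("proteins.fasta"))
  gm <- Biostrings::readDNAStringSet(fp("gene_models.fasta"))
  gene_models <- stats::setNames(as.character(gm), names(gm))
  consv_df <- read_tsv(fp("conservation.tsv"))
  conservation <- split(consv_df$score, consv_df$protein)
  conservation <- conservation[names(proteins)]
  expr_df <- read_tsv(fp("expression.tsv"))
  expr <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expr) <- expr_df$protein
  cfg <- jsonlite::read_json(fp("config.json"), simplifyVector = TRUE)
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  structure(list(proteins = proteins, gene_models = gene_models,
                 ptm_sites = read_tsv(fp("ptm_sites.tsv")),
                 disorder = read_tsv(fp("disorder.tsv")),
                 conservation = conservation,
                 recomb = read_tsv(fp("recomb.tsv")),
                 variants = read_tsv(fp("variants.tsv")),
                 disease = read_tsv(fp("disease.tsv")),
                 gene_sets = load_gene_sets(fp("gene_sets.gmt"), 1, Inf),
                 expression = expr,
                 pwms = read_pwms(fp("pwms.tsv")),
                 drug_links = read_tsv(fp("drug_links.tsv")),
                 truth = truth, config = cfg),
            class = "ptmvar_cohort")
}

#' Write kinase PWMs as TSV
#'
#' Stacked layout: columns `kinase`, `offset` (-7..7) and the 20 amino acids.
#' @param pwms Named list of `ptmvar_pwm`.
#' @param path Output file.
#' @export
write_pwms <- function(pwms, path) {
  rows <- lapply(pwms, function(pw) {
    data.frame(kinase = pw$kinase, offset = as.integer(rownames(pw$matrix)),
               round(pw$matrix, 6), check.names = FALSE)
  })
  write_tsv(do.call(rbind, rows), path)
  invisible(path)
}

#' Read kinase PWMs from TSV
#' @param path File written by [write_pwms()].
#' @return Named list of `ptmvar_pwm`.
#' @export
read_pwms <- function(path) {
  df <- read_tsv(path)
  out <- lapply(split(df, df$kinase), function(d) {
    d <- d[order(d$offset), ]
    m <- as.matrix(d[, AA_ALPHABET])
    rownames(m) <- as.character(d$offset)
    structure(list(kinase = d$kinase[1], matrix = m), class = "ptmvar_pwm")
  })
  out[unique(df$kinase)]
}

#' @export
print.ptmvar_cohort <- function(x, ...) {
  cat("ptmvar synthetic cohort:", length(x$proteins), "proteins,",
      nrow(x$ptm_sites), "PTM sites,", nrow(x$variants), "variants,",
      nrow(x$disease), "disease annotations,", length(x$pwms), "PWMs\n")
  invisible(x)
}
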