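# Genetic-code utilities shared by the variant annotation and Ka/Ks code.
# The standard nuclear code from Biostrings is the single source of truth;
# everything here is derived from it once at load time.

BASES <- c("A", "C", "G", "T")

#' Amino-acid alphabet (20 standard residues)
#'
#' One-letter codes in the column order used by PWM tables.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Residues each PTM type can occur on.
PTM_TYPES <- c("phospho", "ubiq", "acet", "methyl")
PTM_ALLOWED_AA <- list(
  phospho = c("S", "T", "Y"),
  ubiq    = "K",
  acet    = "K",
  methyl  = c("K", "R")
)

.codon_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.codon_env$tab)) {
    tab <- Biostrings::GENETIC_CODE
    # reorder key alphabet to ACGT for positional arithmetic
    keys <- names(tab)
    keys <- chartr("U", "T", keys)
    names(tab) <- keys
    .codon_env$tab <- tab
  }
  .codon_env$tab
}

#' Translate a coding sequence
#'
#' Translates an in-frame CDS string with the standard genetic code.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string (stop codons rendered as `*`).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3: ", n)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(unname(.codon_table()[codons]), collapse = "")
}

#' Codon degeneracy of an amino acid
#'
#' Number of nucleotide triplets coding for an amino acid under the standard
#' code (used as the codon-usage covariate in the variation models).
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Integer vector of codon counts (e.g. Leu = 6, Met = Trp = 1).
#' @export
codon_degeneracy <- function(aa) {
  tab <- .codon_table()
  counts <- table(tab[tab != "*"])
  bad <- !(aa %in% names(counts))
  if (any(bad)) stop("unknown amino acid symbol: ", paste(unique(aa[bad]), collapse = ","))
  as.integer(counts[aa])
}

.codons_for_aa <- function() {
  if (is.null(.codon_env$by_aa)) {
    tab <- .codon_table()
    .codon_env$by_aa <- split(names(tab), unname(tab))
  }
  .codon_env$by_aa
}

# Per-codon fractional synonymous / non-synonymous site counts
# (Nei-Gojobori-style): each of the 9 single-nucleotide changes contributes
# 1/3 site to the class of its translated effect; changes creating a stop
# codon are excluded from both classes. Stop codons themselves carry NA.
codon_site_table <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  tab <- .codon_table()
  codons <- names(tab)
  syn <- nonsyn <- numeric(length(codons))
  for (i in seq_along(codons)) {
    cdn <- codons[i]
    aa <- tab[[cdn]]
    if (aa == "*") { syn[i] <- NA_real_; nonsyn[i] <- NA_real_; next }
    for (pos in 1:3) {
      ref <- substr(cdn, pos, pos)
      for (alt in setdiff(BASES, ref)) {
        mut <- cdn
        substr(mut, pos, pos) <- alt
        maa <- tab[[mut]]
        if (maa == "*") next
        if (maa == aa) syn[i] <- syn[i] + 1 / 3 else nonsyn[i] <- nonsyn[i] + 1 / 3
      }
    }
  }
  out <- data.frame(codon = codons, aa = unname(tab),
                    syn_sites = syn, nonsyn_sites = nonsyn,
                    stringsAsFactors = FALSE)
  .codon_env$sites <- out
  out
}
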