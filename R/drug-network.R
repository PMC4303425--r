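# Directed drug -> PTM enzyme -> disease gene -> disease network. Paths are
# the relational join of: drugs targeting an enzyme, enzymes experimentally
# annotated on PTM sites of hotspot-significant genes where the site's
# region carries disease mutations, and the disease labels of those
# mutations.

#' Assemble the drug-disease path network
#'
#' One path per satisfiable (drug, enzyme, gene, disease) chain: the gene is
#' hotspot-significant (`gene_q < fdr`), the cited PTM site lies in a
#' significantly mutated region (`region_p < region_alpha`) and carries the
#' enzyme as annotated upstream binder, the region holds disease
#' annotations, and the drug targets the enzyme. Dangling identifiers are
#' reported, not fatal.
#'
#' @param pad [active_driver()] result (with its `region_table` attribute).
#' @param ptm_sites PTM site table (enzyme column = upstream binder).
#' @param drug_links data.frame `drug`, `enzyme`.
#' @param disease Disease annotation table.
#' @param fdr Gene-level FDR gate (default 0.05).
#' @param region_alpha Region-level p gate (default 0.05).
#' @return List `paths` (deduplicated path table), `dangling` (enzyme ids
#'   without drugs), `nodes`, `edges` (graph export).
#' @export
assemble_drug_network <- function(pad, ptm_sites, drug_links, disease,
                                  fdr = 0.05, region_alpha = 0.05) {
  empty <- list(paths = NULL, dangling = character(0), nodes = NULL, edges = NULL)
  if (is.null(pad)) return(empty)
  sig <- pad[pad$gene_q < fdr, , drop = FALSE]
  if (nrow(sig) == 0L) return(empty)
  reg_tab <- attr(pad, "region_table")
  sig_regions <- reg_tab[reg_tab$protein %in% sig$protein &
                           reg_tab$p < region_alpha, , drop = FALSE]
  if (nrow(sig_regions) == 0L) return(empty)

  # sites with known enzymes inside significant regions
  st <- ptm_sites[!is.na(ptm_sites$enzyme) &
                    ptm_sites$protein %in% sig_regions$protein, , drop = FALSE]
  if (nrow(st) == 0L) return(empty)
  bounds <- regmatches(sig_regions$region_id,
                       regexec(":([0-9]+)-([0-9]+)$", sig_regions$region_id))
  sig_regions$start <- as.integer(vapply(bounds, `[[`, "", 2L))
  sig_regions$end <- as.integer(vapply(bounds, `[[`, "", 3L))
  paths <- list()
  dangling <- character(0)
  for (i in seq_len(nrow(st))) {
    rg <- sig_regions[sig_regions$protein == st$protein[i] &
                        sig_regions$start <= st$position[i] &
                        sig_regions$end >= st$position[i], , drop = FALSE]
    if (nrow(rg) == 0L) next
    dd <- disease[disease$protein == st$protein[i] &
                    disease$position >= rg$start[1] &
                    disease$position <= rg$end[1], , drop = FALSE]
    if (nrow(dd) == 0L) next
    drugs <- drug_links$drug[drug_links$enzyme == st$enzyme[i]]
    if (!length(drugs)) { dangling <- c(dangling, st$enzyme[i]); next }
    for (dr in unique(drugs)) {
      paths[[length(paths) + 1L]] <- data.frame(
        drug = dr, enzyme = st$enzyme[i], gene = st$protein[i],
        disease = unique(dd$disease), site = st$position[i],
        n_records = sum(dd$n_records), stringsAsFactors = FALSE)
    }
  }
  if (!length(paths)) return(list(paths = NULL, dangling = unique(dangling),
                                  nodes = NULL, edges = NULL))
  paths <- do.call(rbind, paths)
  paths <- paths[!duplicated(paths[, c("drug", "enzyme", "gene", "disease")]), ,
                 drop = FALSE]
  rownames(paths) <- NULL
  nodes <- unique(rbind(
    data.frame(id = paths$drug, type = "drug", stringsAsFactors = FALSE),
    data.frame(id = paths$enzyme, type = "enzyme", stringsAsFactors = FALSE),
    data.frame(id = paths$gene, type = "gene", stringsAsFactors = FALSE),
    data.frame(id = paths$disease, type = "disease", stringsAsFactors = FALSE)))
  edges <- unique(rbind(
    stats::setNames(paths[, c("drug", "enzyme")], c("from", "to")),
    stats::setNames(paths[, c("enzyme", "gene")], c("from", "to")),
    stats::setNames(paths[, c("gene", "disease")], c("from", "to"))))
  rownames(nodes) <- rownames(edges) <- NULL
  list(paths = paths, dangling = unique(dangling), nodes = nodes, edges = edges)
}

#' Distinct drug-disease pairs with supporting path counts
#'
#' @param paths Path table from [assemble_drug_network()].
#' @return data.frame `drug`, `disease`, `n_paths` (counts conserved:
#'   `sum(n_paths) == nrow(paths)`).
#' @export
pair_summary <- function(paths) {
  if (is.null(paths) || nrow(paths) == 0L) {
    return(data.frame(drug = character(), disease = character(),
                      n_paths = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(paths$drug, paths$disease, sep = "\r")
  agg <- rowsum(rep(1L, nrow(paths)), key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(drug = vapply(parts, `[[`, "", 1L),
                    disease = vapply(parts, `[[`, "", 2L),
                    n_paths = as.integer(agg[, 1]), stringsAsFactors = FALSE)
  out <- out[order(out$drug, out$disease), ]
  rownames(out) <- NULL
  out
}
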