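# PTM site mapping and region construction. A PTM region is the union of
# +/-`flank` windows around modified residues, clipped to the protein and
# merged when windows share at least one residue. Residues inside regions are
# labelled by zone (DI = modified residue itself, N1 = 1-2 residues away,
# N2 = 3-7 residues away) and by the number of modified residues within +/-7
# (cluster bins 1..4, "5+").

#' Validate a PTM site table against a proteome
#'
#' Checks that each site's residue matches the protein sequence and is
#' allowed for its modification type (S/T/Y phosphorylation; K ubiquitination
#' and acetylation; K/R methylation).
#'
#' @param sites data.frame with columns `protein`, `position`, `residue`,
#'   `ptm_type`.
#' @param proteome Named character vector of protein sequences.
#' @return `sites`, invisibly, if valid; otherwise an error naming offenders.
#' @export
validate_sites <- function(sites, proteome) {
  stopifnot(all(c("protein", "position", "residue", "ptm_type") %in% names(sites)))
  missing <- setdiff(unique(sites$protein), names(proteome))
  if (length(missing)) stop("sites reference unknown proteins: ",
                            paste(utils::head(missing, 5), collapse = ","))
  seq_aa <- substring(proteome[sites$protein], sites$position, sites$position)
  bad <- which(seq_aa != sites$residue)
  if (length(bad)) stop("site residue does not match sequence at rows: ",
                        paste(utils::head(bad, 5), collapse = ","))
  allowed <- PTM_ALLOWED_AA[sites$ptm_type]
  ok <- mapply(function(r, a) r %in% a, sites$residue, allowed)
  if (!all(ok)) stop("site residue incompatible with PTM type at rows: ",
                     paste(utils::head(which(!ok), 5), collapse = ","))
  invisible(sites)
}

#' Match PTM peptides onto a proteome
#'
#' Locates every exact occurrence of each peptide (up to 15-mer with a
#' defined central modified residue) in every protein, allowing multiple
#' matches per sequence. Peptides whose central residue is incompatible with
#' the stated modification type are rejected with a reason; peptides with no
#' occurrence are reported as unmatched.
#'
#' @param peptides data.frame with columns `peptide`, `ptm_type` and
#'   optionally `center` (1-based index of the modified residue within the
#'   peptide; default is the middle position) and `n_pubs`.
#' @param proteome Named character vector of protein sequences.
#' @return List with `sites` (PTM site table), `unmatched` (peptide rows with
#'   no hit) and `rejected` (rows with a `reason` column).
#' @export
match_peptides <- function(peptides, proteome) {
  stopifnot(all(c("peptide", "ptm_type") %in% names(peptides)))
  if (is.null(peptides$center)) {
    peptides$center <- (nchar(peptides$peptide) + 1L) %/% 2L
  }
  if (is.null(peptides$n_pubs)) peptides$n_pubs <- 1L
  if (any(nchar(peptides$peptide) > 15L)) stop("peptides longer than 15 residues")

  centre_aa <- substring(peptides$peptide, peptides$center, peptides$center)
  ok_type <- mapply(function(a, t) a %in% PTM_ALLOWED_AA[[t]],
                    centre_aa, peptides$ptm_type)
  rejected <- peptides[!ok_type, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- sprintf("central residue %s incompatible with %s",
                               centre_aa[!ok_type], rejected$ptm_type[!ok_type])
  }
  keep <- peptides[ok_type, , drop = FALSE]
  centre_aa <- centre_aa[ok_type]

  hits <- vector("list", nrow(keep))
  matched <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    pat <- keep$peptide[i]
    starts <- gregexpr(pat, proteome, fixed = TRUE)
    rows <- list()
    for (p in seq_along(proteome)) {
      s <- starts[[p]]
      if (s[1] == -1L) next
      pos <- as.integer(s) + keep$center[i] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        protein = names(proteome)[p], position = pos,
        residue = centre_aa[i], ptm_type = keep$ptm_type[i],
        n_pubs = keep$n_pubs[i], stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      hits[[i]] <- do.call(rbind, rows)
      matched[i] <- TRUE
    }
  }
  sites <- if (any(matched)) do.call(rbind, hits[matched]) else
    data.frame(protein = character(), position = integer(), residue = character(),
               ptm_type = character(), n_pubs = integer(), stringsAsFactors = FALSE)
  # one DI residue per position even if hit by several peptides of one type
  sites <- unique(sites)
  rownames(sites) <- NULL
  list(sites = sites,
       unmatched = keep[!matched, , drop = FALSE],
       rejected = rejected)
}

#' Keep PTM sites with sufficient independent support
#'
#' @param sites PTM site table with an `n_pubs` column.
#' @param min_pubs Minimum number of independent supporting datasets.
#' @export
filter_by_support <- function(sites, min_pubs) {
  out <- sites[sites$n_pubs >= min_pubs, , drop = FALSE]
  if (nrow(out) == 0L && nrow(sites) > 0L) {
    warning("no sites reach min_pubs = ", min_pubs)
  }
  rownames(out) <- NULL
  out
}

#' Build merged PTM regions
#'
#' Each modified residue contributes a closed interval `[pos - flank,
#' pos + flank]` clipped to `[1, protein length]`; intervals sharing at least
#' one residue are merged (strictly adjacent but disjoint windows stay
#' separate).
#'
#' @param sites PTM site table.
#' @param proteome Named character vector of protein sequences (used for
#'   lengths and clipping).
#' @param flank Flank width in residues (default 7).
#' @return data.frame with columns `protein`, `start`, `end`, `region_id`,
#'   `n_sites`, `types` (comma-collapsed PTM types present).
#' @export
build_regions <- function(sites, proteome, flank = 7L) {
  lens <- nchar(proteome)
  empty <- data.frame(protein = character(), start = integer(), end = integer(),
                      region_id = character(), n_sites = integer(),
                      types = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  # lay proteins out on one disjoint global axis so a single reduce() call
  # merges all windows at once
  prots <- sort(unique(sites$protein))
  plen <- lens[prots]
  offset <- stats::setNames(cumsum(c(0, as.numeric(plen[-length(plen)]))) +
                              seq(0, by = 10, length.out = length(prots)),
                            prots)
  pos <- sites$position
  off <- offset[sites$protein]
  g_start <- off + pmax(1L, pos - flank)
  g_end <- off + pmin(lens[sites$protein], pos + flank)
  # min.gapwidth = 0: merge only windows sharing >= 1 residue; strictly
  # adjacent windows stay separate
  red <- IRanges::reduce(IRanges::IRanges(g_start, g_end), min.gapwidth = 0L)
  gs <- IRanges::start(red); ge <- IRanges::end(red)
  block <- findInterval(gs, unname(offset))
  prot_of <- prots[block]
  st <- as.integer(gs - offset[prot_of])
  en <- as.integer(ge - offset[prot_of])
  idx <- findInterval(off + pos, gs)
  # count unique modified positions: a residue carrying two PTM types is
  # still one site
  upos <- !duplicated(paste(sites$protein, pos, idx))
  n_sites <- tabulate(idx[upos], nbins = length(gs))
  types <- vapply(split(sites$ptm_type, factor(idx, levels = seq_along(gs))),
                  function(t) paste(sort(unique(t)), collapse = ","), "")
  res <- data.frame(protein = prot_of, start = st, end = en,
                    region_id = sprintf("%s:%d-%d", prot_of, st, en),
                    n_sites = n_sites, types = unname(types),
                    stringsAsFactors = FALSE)
  res <- res[order(res$protein, res$start), ]
  rownames(res) <- NULL
  res
}

# Residues covered by regions, per protein, as a named list of logical masks.
region_masks <- function(regions, proteome) {
  lens <- nchar(proteome)
  masks <- lapply(lens, function(L) logical(L))
  for (i in seq_len(nrow(regions))) {
    p <- regions$protein[i]
    masks[[p]][regions$start[i]:regions$end[i]] <- TRUE
  }
  masks
}

#' Test protein residues for PTM-region membership
#'
#' @param protein,position Parallel vectors of protein identifiers and
#'   1-based residue indices.
#' @param regions Region table from [build_regions()].
#' @return Logical vector.
#' @export
in_ptm_region <- function(protein, position, regions) {
  out <- logical(length(protein))
  if (nrow(regions) == 0L) return(out)
  by_prot <- split(seq_along(protein), protein)
  reg_by_prot <- split(regions, regions$protein)
  for (p in names(by_prot)) {
    rg <- reg_by_prot[[p]]
    if (is.null(rg)) next
    idx <- by_prot[[p]]
    q <- IRanges::IRanges(position[idx], width = 1L)
    s <- IRanges::IRanges(rg$start, rg$end)
    out[idx] <- IRanges::overlapsAny(q, s)
  }
  out
}

#' Zone labels for residues in PTM regions
#'
#' Assigns each region residue the zone of its distance to the nearest
#' modified residue: 0 = `DI`, 1-2 = `N1`, 3-7 = `N2`.
#'
#' @param regions Region table from [build_regions()].
#' @param sites PTM site table used to build the regions.
#' @return data.frame `protein`, `position`, `region_id`, `dist`, `zone`.
#' @export
classify_zones <- function(regions, sites) {
  out <- vector("list", 0L)
  site_by_prot <- split(sites$position, sites$protein)
  for (p in unique(regions$protein)) {
    rg <- regions[regions$protein == p, , drop = FALSE]
    sp <- sort(unique(site_by_prot[[p]]))
    pos <- unlist(mapply(seq.int, rg$start, rg$end, SIMPLIFY = FALSE))
    rid <- rep(rg$region_id, rg$end - rg$start + 1L)
    d <- nearest_distance(pos, sp)
    zone <- ifelse(d == 0L, "DI", ifelse(d <= 2L, "N1", "N2"))
    out[[length(out) + 1L]] <- data.frame(
      protein = p, position = pos, region_id = rid, dist = d, zone = zone,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# minimal |pos - s| over sorted site positions s (vectorized)
nearest_distance <- function(pos, sorted_sites) {
  i <- findInterval(pos, sorted_sites)
  lo <- ifelse(i >= 1L, sorted_sites[pmax(i, 1L)], NA_integer_)
  hi <- ifelse(i < length(sorted_sites), sorted_sites[pmin(i + 1L, length(sorted_sites))],
               NA_integer_)
  pmin(abs(pos - lo), abs(hi - pos), na.rm = TRUE)
}

#' Cluster bins for residues in PTM regions
#'
#' Each region residue is binned by the number of modified residues within
#' +/-7 positions, capped at 5 ("5+").
#'
#' @inheritParams classify_zones
#' @param window Half-width of the counting window (default 7).
#' @return data.frame `protein`, `position`, `region_id`, `n_adjacent`,
#'   `cluster_bin` (character, `"1".."4","5+"`).
#' @export
cluster_bins <- function(regions, sites, window = 7L) {
  out <- vector("list", 0L)
  site_by_prot <- split(sites$position, sites$protein)
  for (p in unique(regions$protein)) {
    rg <- regions[regions$protein == p, , drop = FALSE]
    sp <- sort(unique(site_by_prot[[p]]))
    pos <- unlist(mapply(seq.int, rg$start, rg$end, SIMPLIFY = FALSE))
    rid <- rep(rg$region_id, rg$end - rg$start + 1L)
    n_adj <- findInterval(pos + window, sp) - findInterval(pos - window - 1L, sp)
    bin <- ifelse(n_adj >= 5L, "5+", as.character(n_adj))
    out[[length(out) + 1L]] <- data.frame(
      protein = p, position = pos, region_id = rid,
      n_adjacent = n_adj, cluster_bin = bin, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
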