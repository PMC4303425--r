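# File-format helpers. All tables are plain TSV with a '#'-prefixed header
# block carrying provenance (package version, config hash, seed) so pipeline
# outputs are self-describing and byte-reproducible.

#' Write a result table as TSV
#'
#' @param x data.frame.
#' @param path Output path.
#' @param provenance Optional named character vector written as `# key=value`
#'   comment lines above the header.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s=%s", names(provenance), unname(provenance)), con)
  }
  utils::write.table(format_df(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Deterministic numeric formatting (15 significant digits, C locale style)
format_df <- function(x) {
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]]) && !is.integer(x[[j]])) {
      x[[j]] <- formatC(x[[j]], digits = 15, format = "g")
    }
  }
  x
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @return data.frame (provenance comment lines are skipped).
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' member identifiers. Malformed lines (fewer than 3 fields) are reported
#' with their line numbers.
#'
#' @param path GMT file.
#' @param min_size,max_size Inclusive size bounds on retained sets.
#' @return Named list of character vectors.
#' @export
load_gene_sets <- function(path, min_size = 5, max_size = 1000) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) {
    stop("malformed GMT lines (need name, description, >=1 member): ",
         paste(bad, collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sizes <- lengths(sets)
  sets[sizes >= min_size & sizes <= max_size]
}

write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

read_fasta_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

write_fasta_proteins <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 70L)
  invisible(path)
}
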