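# Shared fixtures: tiny deterministic cohorts and hand-built inputs.

small_cohort <- function(seed = 11L, n = 40L, effect = 1.5, ...) {
  generate_cohort(simulation_config(
    n_proteins = n, length_dist = c(mean = 200, sd = 40),
    ptm_constraint_effect = effect, seed = seed, ...))
}

# a minimal hand-built proteome + sites for region/zone arithmetic
toy_proteome <- function(len = 100L, n = 1L) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(rep(c("A", "S", "K", "R", "T", "G", "L", "Y", "E", "V"),
              length.out = len), collapse = "")
  }, "")
  stats::setNames(seqs, sprintf("T%02d", seq_len(n)))
}

toy_sites <- function(positions, protein = "T01", type = "phospho",
                      proteome = toy_proteome()) {
  data.frame(protein = protein, position = positions,
             residue = substring(proteome[protein], positions, positions),
             ptm_type = type, n_pubs = 1L, enzyme = NA_character_,
             stringsAsFactors = FALSE)
}

# brute-force interval union of +/-flank windows, as a sorted position set
brute_window_union <- function(positions, L, flank = 7L) {
  sort(unique(unlist(lapply(positions, function(p)
    max(1L, p - flank):min(L, p + flank)))))
}

# test-local genetic code oracle, independent of the package's tables
oracle_code <- local({
  tab <- Biostrings::GENETIC_CODE
  names(tab) <- chartr("U", "T", names(tab))
  tab
})
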