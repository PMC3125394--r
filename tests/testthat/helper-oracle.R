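# Independent brute-force oracle for amino-acid codon distances:
# plain triple loop over all sense-codon pairs, no shared code with the
# package implementation.
oracle_aa_distance <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  ca <- names(sense)[sense == a]
  cb <- names(sense)[sense == b]
  best <- 3L
  for (x in ca) {
    for (y in cb) {
      d <- 0L
      for (p in 1:3) if (substr(x, p, p) != substr(y, p, p)) d <- d + 1L
      if (d < best) best <- d
    }
  }
  best
}

# build an alignment from a taxa x states specification: `states` is a
# named list taxon -> character vector of residues (one per column)
toy_alignment <- function(states, gene_id = "toy") {
  rows <- vapply(states, paste, character(1), collapse = "")
  rgc_alignment(gene_id, rows)
}

# alignment in which every taxon carries `base` everywhere except the
# overrides: a list of list(column, taxa, residue)
pattern_alignment <- function(taxa, ncol, base = "A", overrides = list(),
                              gene_id = "toy") {
  m <- matrix(base, nrow = length(taxa), ncol = ncol,
              dimnames = list(taxa, NULL))
  for (ov in overrides) m[ov$taxa, ov$column] <- ov$residue
  structure(list(gene_id = gene_id, aa = m, codons = NULL),
            class = "rgc_alignment")
}

toy_roles <- function(n_in = 10, n_out = 10) {
  taxon_roles(study_time_tree()$tip.label[seq_len(n_in)],
              paste0("P", seq_len(n_out)))
}

study_taxa <- function() c(study_time_tree()$tip.label, paste0("P", 1:10))

# a counted tree with prescribed per-edge counts (fabricated for unit
# tests of the dating arithmetic; list layout documented in ?branch_lengths)
fabricate_counts <- function(tree, counts) {
  x <- branch_lengths(
    data.frame(gene_id = character(), derived_taxa = character(),
               stringsAsFactors = FALSE), tree)
  stopifnot(length(counts) == nrow(tree$edge))
  x$counts <- counts
  x$summary <- list(total = sum(counts), compatible = sum(counts),
                    incompatible = 0L, homoplasy_fraction = 0)
  x
}

# calibrations at every labelled internal node of an ultrametric tree,
# with interval midpoints equal to the true node ages
all_node_calibrations <- function(tree, half_width = 10) {
  ages <- node_ages(tree)
  lapply(names(ages), function(nm) {
    tips <- clade_tips(tree, resolve_node(tree, nm))
    calibration(nm, tips[c(1, length(tips))], ages[[nm]],
                ages[[nm]] + c(-half_width, half_width))
  })
}
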