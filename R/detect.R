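AMBIGUOUS_AA <- c("X", "B", "Z", "J", "U", "O", "*", "?", ".")

#' Detection parameters
#'
#' @param mode `"rgc_ca"` accepts replacements needing 1-3 nucleotide
#'   substitutions; `"rgc_cam"` is the stricter variant accepting only
#'   classes 2-3.
#' @param max_derived_fraction Largest allowed fraction of the ingroup
#'   carrying the derived state. The default 1 accepts any nonempty strict
#'   subset of the ingroup (polarisation is by the outgroup alone); set to
#'   0.5 to require a strict minority.
#' @param outgroup_quorum Fraction of outgroup taxa that must share the
#'   ancestral state; 1 (default) requires unanimity. With a relaxed
#'   quorum, the dissenting outgroup taxa are ignored at that column.
#' @param codon_strict If TRUE and a codon layer is present, the
#'   substitution class is the observed Hamming distance between a derived
#'   taxon's codon and an ancestral taxon's codon, instead of the code-wide
#'   minimum.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(mode = c("rgc_ca", "rgc_cam"),
                             max_derived_fraction = 1,
                             outgroup_quorum = 1,
                             codon_strict = FALSE) {
  mode <- match.arg(mode)
  stopifnot(max_derived_fraction > 0, max_derived_fraction <= 1,
            outgroup_quorum > 0, outgroup_quorum <= 1)
  structure(list(mode = mode,
                 max_derived_fraction = max_derived_fraction,
                 outgroup_quorum = outgroup_quorum,
                 codon_strict = codon_strict),
            class = "detection_params")
}

# canonical key for a taxon set: sorted, comma-joined
taxa_key <- function(taxa) paste(sort(taxa), collapse = ",")

#' Detect RGC_CA characters in one or more alignments
#'
#' Scans the reliable positions of each alignment for columns where
#' (i) the outgroup is unanimous on one amino acid, the ancestral state;
#' (ii) the ingroup carries exactly two states, the ancestral one and a
#' single derived residue; and (iii) the derived-state taxa form a
#' nonempty strict subset of the ingroup. Columns containing gaps or
#' ambiguity symbols in any analysed taxon, and columns with more than two
#' ingroup states, emit nothing (the latter are visible through
#' [count_state_distribution()]).
#'
#' @param alns An `rgc_alignment` or a list of them (excluded alignments
#'   are skipped).
#' @param roles A [taxon_roles()] object.
#' @param params A [detection_params()] object.
#' @param flank Reliable-window flank passed to [reliable_positions()].
#' @return data.frame of class `rgc_characters`, one row per character:
#'   `gene_id`, `column` (1-based), `ancestral`, `derived`, `sub_class`,
#'   `n_states`, `n_derived`, `derived_taxa` (comma-joined, sorted).
#' @export
detect_characters <- function(alns, roles, params = detection_params(),
                              flank = 5L) {
  if (inherits(alns, "rgc_alignment")) alns <- list(alns)
  alns <- usable_alignments(alns)
  res <- lapply(alns, detect_one, roles = roles, params = params,
                flank = flank)
  out <- do.call(rbind, c(res, list(empty_characters())))
  rownames(out) <- NULL
  class(out) <- c("rgc_characters", "data.frame")
  out
}

empty_characters <- function() {
  data.frame(gene_id = character(), column = integer(),
             ancestral = character(), derived = character(),
             sub_class = integer(), n_states = integer(),
             n_derived = integer(), derived_taxa = character(),
             stringsAsFactors = FALSE)
}

# candidate columns of one alignment: reliable, unambiguous, outgroup at
# quorum on one state, ingroup variable; returns per-column bookkeeping
candidate_columns <- function(aln, roles, outgroup_quorum = 1, flank = 5L) {
  missing <- setdiff(c(roles$ingroup, roles$outgroup), rownames(aln$aa))
  if (length(missing) > 0L)
    stop("alignment ", aln$gene_id, " lacks declared taxa: ",
         paste(missing, collapse = ","))
  rel <- reliable_positions(aln, flank)
  if (length(rel) == 0L) return(NULL)
  sub <- aln$aa[c(roles$ingroup, roles$outgroup), rel, drop = FALSE]
  amb <- colSums(matrix(sub %in% AMBIGUOUS_AA | sub == "-", nrow = nrow(sub))) > 0L
  rel <- rel[!amb]
  if (length(rel) == 0L) return(NULL)
  og <- aln$aa[roles$outgroup, rel, drop = FALSE]
  ig <- aln$aa[roles$ingroup, rel, drop = FALSE]
  n_og <- length(roles$outgroup)
  if (outgroup_quorum >= 1) {
    # fast path: strict unanimity
    anc <- og[1L, ]
    ok <- colSums(og != og[rep(1L, n_og), , drop = FALSE]) == 0L
  } else {
    # modal outgroup state per column and its support
    anc <- character(length(rel)); support <- integer(length(rel))
    for (j in seq_along(rel)) {
      tab <- table(og[, j])
      anc[j] <- names(tab)[which.max(tab)]
      support[j] <- max(tab)
    }
    ok <- support >= ceiling(outgroup_quorum * n_og)
  }
  variable <- colSums(ig != ig[rep(1L, nrow(ig)), , drop = FALSE]) > 0L
  keep <- ok & variable
  list(columns = rel[keep], anc = anc[keep],
       ingroup = ig[, keep, drop = FALSE])
}

detect_one <- function(aln, roles, params, flank) {
  cand <- candidate_columns(aln, roles, params$outgroup_quorum, flank)
  if (is.null(cand) || length(cand$columns) == 0L) return(empty_characters())
  rows <- vector("list", length(cand$columns))
  n_in <- length(roles$ingroup)
  for (j in seq_along(cand$columns)) {
    states <- cand$ingroup[, j]
    anc <- cand$anc[j]
    uniq <- unique(states)
    if (length(uniq) != 2L || !(anc %in% uniq)) next
    der <- setdiff(uniq, anc)
    der_taxa <- roles$ingroup[states == der]
    if (length(der_taxa) == 0L || length(der_taxa) == n_in) next
    if (length(der_taxa) / n_in > params$max_derived_fraction) next
    cls <- character_class(aln, cand$columns[j], anc, der, der_taxa,
                           roles, params)
    if (params$mode == "rgc_cam" && cls < 2L) next
    rows[[j]] <- data.frame(
      gene_id = aln$gene_id, column = cand$columns[j], ancestral = anc,
      derived = der, sub_class = cls, n_states = 2L,
      n_derived = length(der_taxa), derived_taxa = taxa_key(der_taxa),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(Filter(Negate(is.null), rows), list(empty_characters())))
}

character_class <- function(aln, column, anc, der, der_taxa, roles, params) {
  if (isTRUE(params$codon_strict) && !is.null(aln$codons)) {
    anc_taxon <- setdiff(roles$ingroup, der_taxa)[1]
    observed_codon_distance(aln$codons[anc_taxon, column],
                            aln$codons[der_taxa[1], column])
  } else {
    substitution_class(anc, der)
  }
}

#' Distribution of ingroup state counts at candidate columns
#'
#' Counts, over all reliable columns where the outgroup is unanimous and
#' the ingroup variable, how many columns carry k = 2, 3, ... distinct
#' ingroup amino acids. The k = 2 fraction is the proportion of candidate
#' sites that behave as true two-state rare changes.
#'
#' @inheritParams detect_characters
#' @return data.frame with columns `n_states`, `n_columns`, `fraction`
#'   (fractions sum to 1 when any candidate column exists).
#' @export
count_state_distribution <- function(alns, roles, flank = 5L) {
  if (inherits(alns, "rgc_alignment")) alns <- list(alns)
  alns <- usable_alignments(alns)
  ks <- unlist(lapply(alns, function(aln) {
    cand <- candidate_columns(aln, roles, 1, flank)
    if (is.null(cand) || length(cand$columns) == 0L) return(integer(0))
    apply(cand$ingroup, 2, function(s) length(unique(s)))
  }))
  tab <- table(factor(ks, levels = if (length(ks)) sort(unique(ks)) else 2L))
  data.frame(n_states = as.integer(names(tab)),
             n_columns = as.integer(tab),
             fraction = if (sum(tab) > 0) as.numeric(tab) / sum(tab) else NA_real_)
}

#' Write a character table as TSV
#' @param chars `rgc_characters` data.frame.
#' @param path Output path.
#' @export
write_character_table <- function(chars, path) {
  utils::write.table(chars, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a character table written by [write_character_table()]
#' @param path TSV path.
#' @return `rgc_characters` data.frame.
#' @export
read_character_table <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("rgc_characters", "data.frame")
  out
}
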