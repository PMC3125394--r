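#' Taxon roles: ingroup and outgroup
#'
#' Declares which taxa form the ingroup (the clade being dated, here
#' eukaryotes) and which form the polarising outgroup (prokaryotes).
#' Every analysed alignment must contain all declared taxa.
#'
#' @param ingroup Character vector of ingroup taxon ids.
#' @param outgroup Character vector of outgroup taxon ids (length >= 1).
#' @return Object of class `taxon_roles`.
#' @export
taxon_roles <- function(ingroup, outgroup) {
  ingroup <- as.character(ingroup); outgroup <- as.character(outgroup)
  if (length(outgroup) < 1L) stop("outgroup must contain at least one taxon")
  if (length(ingroup) < 2L) stop("ingroup must contain at least two taxa")
  if (length(intersect(ingroup, outgroup)) > 0L)
    stop("ingroup and outgroup must be disjoint")
  if (anyDuplicated(c(ingroup, outgroup))) stop("duplicated taxon ids")
  structure(list(ingroup = ingroup, outgroup = outgroup),
            class = "taxon_roles")
}

#' Read taxon roles from a YAML config file
#'
#' Expects top-level keys `ingroup` and `outgroup`, each a list of taxon ids.
#'
#' @param path Path to YAML file.
#' @return A [taxon_roles()] object.
#' @export
read_taxon_roles <- function(path) {
  cfg <- yaml::read_yaml(path)
  taxon_roles(cfg$ingroup, cfg$outgroup)
}

#' Construct a multiple alignment object
#'
#' Container for one gene family's aligned protein sequences, with an
#' optional parallel in-frame codon layer. Rows are stored as a character
#' matrix (taxa x columns) of single residues; gaps are `"-"`.
#'
#' @param gene_id Identifier for the gene family.
#' @param aa Named character vector of aligned amino-acid strings
#'   (equal lengths), or a character matrix of single residues with taxon
#'   rownames.
#' @param codons Optional named character vector of aligned nucleotide
#'   strings, each exactly 3x the protein alignment length, translating to
#'   the protein rows with one `---` triplet per amino-acid gap.
#' @return Object of class `rgc_alignment` with elements `gene_id`, `aa`
#'   (matrix), and `codons` (matrix of codon triplets or NULL).
#' @export
rgc_alignment <- function(gene_id, aa, codons = NULL) {
  aa_mat <- if (is.matrix(aa)) aa else {
    if (is.null(names(aa))) stop("aa sequences must be named by taxon")
    lens <- nchar(aa)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: rows of unequal length in ", gene_id)
    do.call(rbind, strsplit(toupper(aa), ""))
  }
  if (!is.matrix(aa_mat) && is.null(dim(aa_mat)))
    aa_mat <- matrix(aa_mat, nrow = 1)
  if (is.null(rownames(aa_mat)) && !is.matrix(aa)) rownames(aa_mat) <- names(aa)
  if (is.null(rownames(aa_mat))) stop("alignment matrix must have taxon rownames")
  if (anyDuplicated(rownames(aa_mat)))
    stop("duplicate taxon in alignment ", gene_id)
  codon_mat <- NULL
  if (!is.null(codons)) {
    if (is.matrix(codons)) codon_mat <- codons else {
      if (!setequal(names(codons), rownames(aa_mat)))
        stop("codon rows must cover exactly the protein-alignment taxa")
      codons <- toupper(codons[rownames(aa_mat)])
      if (any(nchar(codons) != 3L * ncol(aa_mat)))
        stop("each codon row must be exactly 3x the protein alignment length")
      codon_mat <- t(vapply(codons, function(s) {
        substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
      }, character(ncol(aa_mat))))
      rownames(codon_mat) <- rownames(aa_mat)
    }
    validate_codon_layer(aa_mat, codon_mat, gene_id)
  }
  structure(list(gene_id = gene_id, aa = aa_mat, codons = codon_mat),
            class = "rgc_alignment")
}

validate_codon_layer <- function(aa_mat, codon_mat, gene_id) {
  if (!identical(dim(aa_mat), dim(codon_mat)))
    stop("codon layer dimensions do not match protein alignment in ", gene_id)
  code <- genetic_code()
  is_gap <- aa_mat == "-"
  if (!all(codon_mat[is_gap] == "---"))
    stop("codon gaps must align with amino-acid gaps in ", gene_id)
  res <- codon_mat[!is_gap]
  tr <- unname(code[res])
  exp <- aa_mat[!is_gap]
  chk <- !is.na(tr) & tr == exp
  # ambiguity codes in the protein row cannot be checked against a codon
  chk <- chk | !(exp %in% STANDARD_AA)
  if (!all(chk))
    stop("codon layer does not translate to the protein alignment in ", gene_id)
  invisible(TRUE)
}

#' @export
print.rgc_alignment <- function(x, ...) {
  cat("<rgc_alignment> ", x$gene_id, ": ", nrow(x$aa), " taxa x ",
      ncol(x$aa), " columns",
      if (!is.null(x$codons)) " (+codon layer)", "\n", sep = "")
  invisible(x)
}

#' Read one aligned FASTA file as a validated alignment
#'
#' Reads an aligned protein FASTA, maps headers to taxon ids, and validates
#' coverage of the declared taxa. Headers are matched to taxon ids either
#' exactly or through `name_map`, a named vector of regular expressions
#' (taxon id -> regex matched against the header).
#'
#' An alignment missing any declared taxon is not an error: it is returned
#' with attribute `excluded = TRUE` and `exclusion_reason` set, mirroring
#' the requirement that orthologs from all species be present for a gene
#' to be analysed. Ragged rows and duplicated taxa are hard errors.
#'
#' @param path Path to aligned FASTA.
#' @param roles A [taxon_roles()] object.
#' @param gene_id Gene identifier; defaults to the file name without
#'   extension.
#' @param name_map Optional named character vector of header regexes.
#' @param codon_path Optional path to the parallel in-frame nucleotide
#'   alignment (same headers).
#' @return An `rgc_alignment`, possibly flagged with `excluded`.
#' @export
read_alignment_fasta <- function(path, roles, gene_id = NULL,
                                 name_map = NULL, codon_path = NULL) {
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  strings <- toupper(as.character(seqs))
  names(strings) <- resolve_taxa(headers, roles, name_map)
  lens <- nchar(strings)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment in ", path, ": sequence lengths ",
         paste(unique(lens), collapse = ", "))
  declared <- c(roles$ingroup, roles$outgroup)
  keep <- names(strings) %in% declared
  strings <- strings[keep]
  if (anyDuplicated(names(strings)))
    stop("duplicate taxon in ", path, ": ",
         paste(unique(names(strings)[duplicated(names(strings))]),
               collapse = ", "))
  missing <- setdiff(declared, names(strings))
  codons <- NULL
  if (!is.null(codon_path) && length(missing) == 0L) {
    nt <- Biostrings::readBStringSet(codon_path)
    nts <- toupper(as.character(nt))
    names(nts) <- resolve_taxa(names(nt), roles, name_map)
    codons <- nts[declared]
  }
  aln <- rgc_alignment(gene_id, strings[intersect(declared, names(strings))],
                       codons = codons)
  if (length(missing) > 0L) {
    attr(aln, "excluded") <- TRUE
    attr(aln, "exclusion_reason") <-
      paste0("missing taxa: ", paste(sort(missing), collapse = ","))
  }
  aln
}

resolve_taxa <- function(headers, roles, name_map) {
  ids <- sub("\\s.*$", "", headers)
  if (!is.null(name_map)) {
    for (tax in names(name_map)) {
      hit <- grepl(name_map[[tax]], headers)
      if (sum(hit) > 1L)
        stop("header regex for taxon ", tax, " matches multiple sequences")
      if (any(hit)) ids[hit] <- tax
    }
  }
  ids
}

#' Read a directory of aligned FASTA files
#'
#' @param dir Directory containing `.fa`/`.fasta`/`.faa` files.
#' @inheritParams read_alignment_fasta
#' @return Named list of `rgc_alignment` objects (including excluded ones;
#'   see [exclusion_report()]).
#' @export
read_alignment_dir <- function(dir, roles, name_map = NULL) {
  files <- list.files(dir, pattern = "\\.(fa|fasta|faa)$", full.names = TRUE)
  files <- files[!grepl("\\.nt\\.", basename(files))]  # codon layers
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  alns <- lapply(files, read_alignment_fasta, roles = roles,
                 name_map = name_map)
  names(alns) <- vapply(alns, `[[`, "", "gene_id")
  alns
}

#' Tabulate excluded alignments
#'
#' @param alns List of alignments from [read_alignment_dir()].
#' @return data.frame with columns `gene_id`, `reason` (possibly 0 rows).
#' @export
exclusion_report <- function(alns) {
  if (inherits(alns, "rgc_alignment")) alns <- list(alns)
  excl <- Filter(function(a) isTRUE(attr(a, "excluded")), alns)
  data.frame(
    gene_id = vapply(excl, `[[`, "", "gene_id"),
    reason = vapply(excl, function(a) attr(a, "exclusion_reason"), ""),
    stringsAsFactors = FALSE
  )
}

#' Keep only usable (non-excluded) alignments
#' @param alns List of alignments.
#' @return Filtered list.
#' @export
usable_alignments <- function(alns) {
  if (inherits(alns, "rgc_alignment")) alns <- list(alns)
  Filter(function(a) !isTRUE(attr(a, "excluded")), alns)
}

#' Reliable alignment positions (indel-free window filter)
#'
#' A column is reliable when no analysed taxon has a gap anywhere within
#' `flank` columns on either side of it (the column itself included), and
#' the whole window lies inside the alignment. Windows truncated by the
#' alignment ends disqualify the position, so an alignment of length
#' `<= 2*flank` has no reliable positions.
#'
#' @param aln An `rgc_alignment`.
#' @param flank Number of indel-free columns required on each side
#'   (default 5).
#' @return Strictly increasing integer vector of 1-based column indices.
#' @examples
#' aln <- rgc_alignment("toy", c(a = "AAAAAAAAAAAAA", b = "AAAAAAAAAAAAA"))
#' reliable_positions(aln)  # 6 7 8
#' @export
reliable_positions <- function(aln, flank = 5L) {
  flank <- as.integer(flank)
  if (is.na(flank) || flank < 0L) stop("flank must be a nonnegative integer")
  L <- ncol(aln$aa)
  if (L <= 2L * flank) return(integer(0))
  gapcol <- colSums(aln$aa == "-") > 0L
  # window sum of gap columns via cumulative sums
  cs <- c(0L, cumsum(as.integer(gapcol)))
  p <- (flank + 1L):(L - flank)
  bad_in_window <- cs[p + flank + 1L] - cs[p - flank] > 0L
  p[!bad_in_window]
}
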