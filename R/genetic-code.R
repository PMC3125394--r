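#' The standard genetic code
#'
#' Returns the genetic code as a named character vector mapping each of the
#' 64 codons (3-letter strings over A/C/G/T) to a one-letter amino-acid
#' symbol, with `"*"` marking stop codons. The default is the standard code
#' as shipped with Biostrings; an alternative table can be loaded from a
#' plain-text file with [read_codon_table()].
#'
#' @return Named character vector of length 64 (names are codons).
#' @examples
#' code <- genetic_code()
#' code["ATG"]  # "M"
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  stopifnot(length(code) == 64L)
  c(code)
}

#' Read a codon table from a plain-text file
#'
#' Accepts the NCBI translation-table layout: a line starting with
#' `AAs` giving 64 amino-acid symbols, and lines `Base1`, `Base2`, `Base3`
#' giving the codon positions, e.g.
#' \preformatted{
#'   AAs    = FFLLSSSSYY**CC*W...
#'   Base1  = TTTTTTTTTTTTTTTT...
#'   Base2  = TTTTCCCCAAAAGGGG...
#'   Base3  = TCAGTCAGTCAGTCAG...
#' }
#'
#' @param path Path to the table file.
#' @return Named character vector in the same shape as [genetic_code()].
#' @export
read_codon_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^\\s*", tag, "\\s*="), lines, value = TRUE)
    if (length(ln) != 1L)
      stop("codon table file must contain exactly one '", tag, " =' line")
    chars <- strsplit(sub(".*=\\s*", "", ln), "")[[1]]
    chars[chars != " "]
  }
  aas <- grab("AAs")
  b1 <- grab("Base1"); b2 <- grab("Base2"); b3 <- grab("Base3")
  if (!all(lengths(list(aas, b1, b2, b3)) == 64L))
    stop("codon table must define exactly 64 codons")
  codons <- toupper(paste0(b1, b2, b3))
  if (anyDuplicated(codons)) stop("duplicated codons in table")
  code <- toupper(aas)
  names(code) <- codons
  code
}

# Amino-acid alphabet covered by distance computations (20 standard residues)
STANDARD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Minimal nucleotide-substitution distance matrix between amino acids
#'
#' For every ordered pair of standard amino acids, the minimum Hamming
#' distance over all pairs of sense codons encoding them under `code`.
#' Stop codons are excluded from the minimisation. The result is symmetric
#' with a zero diagonal and off-diagonal values in 1..3.
#'
#' @param code Genetic code as returned by [genetic_code()].
#' @return 20 x 20 integer matrix with amino-acid symbols as dimnames.
#' @export
aa_distance_matrix <- function(code = genetic_code()) {
  sense <- code[code != "*"]
  aas <- sort(unique(sense))
  if (!setequal(aas, STANDARD_AA))
    stop("genetic code must encode exactly the 20 standard amino acids")
  codons <- names(sense)
  bases <- do.call(rbind, strsplit(codons, ""))
  n <- length(codons)
  # pairwise codon Hamming distances, vectorised one position at a time
  ham <- matrix(0L, n, n)
  for (p in 1:3) ham <- ham + outer(bases[, p], bases[, p], "!=")
  d <- matrix(3L, 20L, 20L, dimnames = list(STANDARD_AA, STANDARD_AA))
  for (x in STANDARD_AA) {
    ix <- sense == x
    for (y in STANDARD_AA) {
      d[x, y] <- min(ham[ix, sense == y])
    }
  }
  storage.mode(d) <- "integer"
  d
}

# cache: the standard-code matrix is computed once per session
the <- new.env(parent = emptyenv())

std_aa_distance_matrix <- function() {
  if (is.null(the$aa_dist)) the$aa_dist <- aa_distance_matrix()
  the$aa_dist
}

check_aa_symbols <- function(x, arg) {
  x <- toupper(as.character(x))
  bad <- setdiff(unique(x), STANDARD_AA)
  if (length(bad) > 0L)
    stop("non-standard or ambiguous amino-acid symbol(s) in ", arg, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  x
}

#' Minimal number of nucleotide substitutions between two amino acids
#'
#' The minimum Hamming distance over all pairs of sense codons encoding
#' `aa_from` and `aa_to`. Vectorised over both arguments (recycled).
#' Ambiguity symbols (X, B, Z, ...) are rejected.
#'
#' @param aa_from,aa_to One-letter amino-acid symbols.
#' @param code Genetic code; defaults to the standard code.
#' @return Integer vector of distances in 0..3; 0 iff the residues are equal.
#' @examples
#' min_nt_substitutions("A", "T")  # 1
#' min_nt_substitutions("F", "K")  # 3
#' @export
min_nt_substitutions <- function(aa_from, aa_to, code = NULL) {
  d <- if (is.null(code)) std_aa_distance_matrix() else aa_distance_matrix(code)
  aa_from <- check_aa_symbols(aa_from, "aa_from")
  aa_to <- check_aa_symbols(aa_to, "aa_to")
  d[cbind(aa_from, aa_to)]
}

#' Substitution class of an amino-acid replacement
#'
#' Classifies a replacement by the minimal number of nucleotide
#' substitutions it requires (1, 2 or 3). Class 1 replacements qualify as
#' RGC_CA characters only; classes 2-3 additionally qualify under the
#' stricter RGC_CAM definition. Identical residues are an error: a class-0
#' pair is not a substitution.
#'
#' @inheritParams min_nt_substitutions
#' @param aa_anc,aa_der Ancestral and derived amino-acid symbols.
#' @return Integer vector with values in 1..3.
#' @export
substitution_class <- function(aa_anc, aa_der, code = NULL) {
  cls <- min_nt_substitutions(aa_anc, aa_der, code)
  if (any(cls == 0L))
    stop("identical amino acids do not form a substitution", call. = FALSE)
  cls
}

#' Observed codon distance between two aligned codons
#'
#' Strict-mode alternative to the code-wide minimum: the Hamming distance
#' between the codons actually observed in a codon alignment. Vectorised.
#'
#' @param codon_anc,codon_der 3-letter codon strings.
#' @return Integer vector of distances in 0..3.
#' @export
observed_codon_distance <- function(codon_anc, codon_der) {
  codon_anc <- toupper(codon_anc); codon_der <- toupper(codon_der)
  ok <- function(x) nchar(x) == 3L & !grepl("[^ACGT]", x)
  if (!all(ok(codon_anc) & ok(codon_der)))
    stop("codons must be 3-letter strings over A/C/G/T")
  a <- strsplit(codon_anc, ""); b <- strsplit(codon_der, "")
  as.integer(mapply(function(x, y) sum(x != y), a, b))
}
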