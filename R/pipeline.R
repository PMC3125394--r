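#' Run the detection stage of the pipeline
#'
#' Reads a directory of aligned FASTA files, applies the reliable-position
#' filter and character detection, and writes the character table and
#' exclusion report to `out_dir`.
#'
#' @param alignment_dir Directory of aligned protein FASTA files
#'   (parallel `.nt.fasta` codon alignments are picked up automatically).
#' @param roles_path Path to a taxon-roles YAML file
#'   (see [read_taxon_roles()]).
#' @param out_dir Output directory (created if needed).
#' @param mode Detection mode, `"rgc_ca"` or `"rgc_cam"`.
#' @param flank Reliable-window flank.
#' @return Invisibly, the `rgc_characters` table. Errors if no usable
#'   alignment remains.
#' @export
run_detect <- function(alignment_dir, roles_path, out_dir,
                       mode = "rgc_ca", flank = 5L) {
  roles <- read_taxon_roles(roles_path)
  alns <- read_alignment_dir(alignment_dir, roles)
  usable <- usable_alignments(alns)
  if (length(usable) == 0L)
    stop("no usable alignments: every input lacks declared taxa")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  chars <- detect_characters(usable, roles,
                             detection_params(mode = mode), flank = flank)
  write_character_table(chars, file.path(out_dir, "characters.tsv"))
  utils::write.table(exclusion_report(alns),
                     file.path(out_dir, "exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  states <- count_state_distribution(usable, roles, flank = flank)
  utils::write.table(states, file.path(out_dir, "state_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("detected %d characters in %d alignments (%d excluded)",
                  nrow(chars), length(usable),
                  length(alns) - length(usable)))
  invisible(chars)
}

#' Run the mapping and dating stage of the pipeline
#'
#' Maps a character table onto the species tree, computes branch lengths
#' in RGC_CA units, produces all parsimony age estimates with per-target
#' summaries, cross-validates the calibrations (when at least two are
#' given), and writes clock diagnostics. All outputs are TSV with headers
#' plus a counts-annotated Newick; a run log records the totals at each
#' stage.
#'
#' @param characters_path Path to a character table TSV
#'   (from [run_detect()]).
#' @param tree_path Rooted Newick species tree over the ingroup taxa
#'   (internal node labels honoured).
#' @param calibrations_path Calibration YAML (see [read_calibrations()]).
#' @param out_dir Output directory.
#' @param targets Named list of target nodes; defaults to every labelled
#'   internal node of the tree.
#' @return Invisibly, a list with `counts`, `estimates`, `summaries`,
#'   `xval` (or NULL), `diagnostics`.
#' @export
run_date <- function(characters_path, tree_path, calibrations_path,
                     out_dir, targets = NULL) {
  chars <- read_character_table(characters_path)
  tree <- ape::read.tree(tree_path)
  calibrations <- read_calibrations(calibrations_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)

  counts <- branch_lengths(chars, tree)
  s <- counts$summary
  stopifnot(s$compatible + s$incompatible == s$total)
  logline("characters: total %d, compatible %d, incompatible %d (%.1f%% homoplasy)",
          s$total, s$compatible, s$incompatible,
          100 * ifelse(is.na(s$homoplasy_fraction), 0, s$homoplasy_fraction))
  utils::write.table(as.data.frame(counts),
                     file.path(out_dir, "branch_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_newick(counts, file.path(out_dir, "branch_counts.nwk"))

  if (is.null(targets)) {
    if (is.null(tree$node.label) || !any(nzchar(tree$node.label)))
      stop("no targets given and the tree has no internal node labels")
    labs <- tree$node.label[nzchar(tree$node.label)]
    targets <- stats::setNames(as.list(labs), labs)
  }
  estimates <- all_estimates(counts, calibrations, targets)
  summaries <- summarize_estimates(estimates)
  utils::write.table(estimates, file.path(out_dir, "estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summaries, file.path(out_dir, "estimate_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(summaries)))
    logline("target %s: %d estimates, mean %.0f Mya, median %.0f, sd %.0f",
            summaries$target[i], summaries$n[i], summaries$mean[i],
            summaries$median[i], summaries$sd[i])

  xval <- NULL
  if (length(calibrations) >= 2L) {
    xval <- cross_validate(counts, calibrations, targets)
    utils::write.table(xval, file.path(out_dir, "cross_validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(attr(xval, "pairs"),
                       file.path(out_dir, "xval_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("fewer than two calibrations; cross-validation skipped")
    logline("cross-validation skipped: fewer than two calibrations")
  }

  diagnostics <- tryCatch(clock_diagnostics(counts, calibrations),
                          error = function(e) NULL)
  if (!is.null(diagnostics)) {
    utils::write.table(diagnostics$pairs,
                       file.path(out_dir, "clock_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logline("clock diagnostics: Pearson r = %.3f over %d pairs",
            diagnostics$r, nrow(diagnostics$pairs))
  }
  invisible(list(counts = counts, estimates = estimates,
                 summaries = summaries, xval = xval,
                 diagnostics = diagnostics))
}
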