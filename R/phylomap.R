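#' Tips descending from a node
#'
#' @param tree A rooted `phylo` object.
#' @param node Node number (tips are 1..Ntip).
#' @return Character vector of tip labels in the node's clade.
#' @export
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

#' Resolve a node specification to a node number
#'
#' Accepts a node number, an internal-node label (e.g. `"LECA"`), a tip
#' label, or a length-2 character vector of tip labels whose MRCA is taken.
#'
#' @param tree A rooted `phylo`.
#' @param node Node specification.
#' @return Integer node number.
#' @export
resolve_node <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (node < 1L || node > ntip + tree$Nnode) stop("node number out of range")
    return(node)
  }
  node <- as.character(node)
  if (length(node) == 2L) {
    if (!all(node %in% tree$tip.label))
      stop("tips not in tree: ", paste(setdiff(node, tree$tip.label),
                                       collapse = ","))
    return(ape::getMRCA(tree, node))
  }
  if (node %in% tree$tip.label) return(match(node, tree$tip.label))
  if (!is.null(tree$node.label) && node %in% tree$node.label)
    return(ntip + match(node, tree$node.label))
  stop("cannot resolve node '", node, "' in tree")
}

# clade key (sorted comma-joined tip set) for the child node of every edge
edge_clade_keys <- function(tree) {
  vapply(tree$edge[, 2], function(child) taxa_key(clade_tips(tree, child)),
         character(1))
}

#' Map one character onto the species tree
#'
#' A character is compatible when its derived-taxon set equals the tip set
#' of the clade below exactly one branch; that branch's child node is
#' returned. Polarity is fixed by the outgroup, so a derived set matching
#' no clade is incompatible even if its complement is a clade.
#'
#' @param derived_taxa Character vector of derived taxon ids, or a
#'   comma-joined key as stored in a character table.
#' @param tree Rooted `phylo` whose tips are the ingroup taxa.
#' @return The child node number of the matching branch, or `NA` if the
#'   character is incompatible with the tree.
#' @export
map_character <- function(derived_taxa, tree) {
  if (length(derived_taxa) == 1L && grepl(",", derived_taxa))
    derived_taxa <- strsplit(derived_taxa, ",")[[1]]
  missing <- setdiff(derived_taxa, tree$tip.label)
  if (length(missing) > 0L)
    stop("derived taxa absent from tree: ", paste(missing, collapse = ","))
  key <- taxa_key(derived_taxa)
  keys <- edge_clade_keys(tree)
  hit <- which(keys == key)
  if (length(hit) == 0L) return(NA_integer_)
  tree$edge[hit[1], 2]
}

#' Branch lengths in RGC_CA units
#'
#' Maps every character onto the tree and counts, per branch, the
#' compatible characters whose derived set is exactly that branch's clade.
#' Characters matching no clade are tallied as incompatible (homoplasy).
#'
#' @param chars `rgc_characters` data.frame (needs a `derived_taxa`
#'   column of comma-joined taxon sets).
#' @param tree Rooted `phylo` over the ingroup taxa.
#' @return Object of class `rgc_counts`: list with `tree`, `counts`
#'   (integer vector along `tree$edge` rows), `edge_keys` (clade key per
#'   edge), and `summary` (list `total`, `compatible`, `incompatible`,
#'   `homoplasy_fraction`).
#' @export
branch_lengths <- function(chars, tree) {
  keys <- edge_clade_keys(tree)
  counts <- integer(nrow(tree$edge))
  total <- nrow(chars)
  if (total > 0L) {
    all_taxa <- unique(unlist(strsplit(chars$derived_taxa, ",")))
    missing <- setdiff(all_taxa, tree$tip.label)
    if (length(missing) > 0L)
      stop("derived taxa absent from tree: ", paste(missing, collapse = ","))
    idx <- match(chars$derived_taxa, keys)
    tab <- table(idx[!is.na(idx)])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  compatible <- sum(counts)
  structure(list(
    tree = tree, counts = counts, edge_keys = keys,
    summary = list(total = total, compatible = compatible,
                   incompatible = total - compatible,
                   homoplasy_fraction =
                     if (total > 0L) (total - compatible) / total else NA_real_)
  ), class = "rgc_counts")
}

#' @export
print.rgc_counts <- function(x, ...) {
  s <- x$summary
  cat("<rgc_counts> ", ape::Ntip(x$tree), " tips; characters: total ",
      s$total, ", compatible ", s$compatible, ", incompatible ",
      s$incompatible, sep = "")
  if (!is.na(s$homoplasy_fraction))
    cat(sprintf(" (homoplasy %.1f%%)", 100 * s$homoplasy_fraction))
  cat("\n")
  invisible(x)
}

#' Per-branch count table
#' @param x An `rgc_counts` object.
#' @param ... Unused.
#' @return data.frame with `branch` (clade key of the child node),
#'   `child_label` (tip or node label where available), `count`.
#' @export
as.data.frame.rgc_counts <- function(x, ...) {
  child <- x$tree$edge[, 2]
  ntip <- ape::Ntip(x$tree)
  lab <- character(length(child))
  is_tip <- child <= ntip
  lab[is_tip] <- x$tree$tip.label[child[is_tip]]
  if (!is.null(x$tree$node.label))
    lab[!is_tip] <- x$tree$node.label[child[!is_tip] - ntip]
  data.frame(branch = x$edge_keys, child_label = lab, count = x$counts,
             stringsAsFactors = FALSE)
}

#' Write the counted tree as Newick with counts as branch lengths
#' @param x An `rgc_counts` object.
#' @param path Output path.
#' @export
write_counts_newick <- function(x, path) {
  tr <- x$tree
  tr$edge.length <- as.numeric(x$counts)
  ape::write.tree(tr, file = path)
  invisible(path)
}

#' Sum of branch counts along a node-to-tip path
#'
#' @param x An `rgc_counts` object.
#' @param node Start node (any form accepted by [resolve_node()]).
#' @param tip End tip label (must descend from `node`).
#' @return Integer path length in RGC_CA units.
#' @export
path_length <- function(x, node, tip) {
  tree <- x$tree
  node <- resolve_node(tree, node)
  tip_n <- resolve_node(tree, tip)
  if (tip_n > ape::Ntip(tree)) stop("'tip' must be a terminal taxon")
  if (!(tree$tip.label[tip_n] %in% clade_tips(tree, node)))
    stop("tip '", tree$tip.label[tip_n], "' does not descend from the node")
  if (node == tip_n) return(0L)
  nodes <- ape::nodepath(tree, from = node, to = tip_n)
  eidx <- vapply(seq_len(length(nodes) - 1L), function(i) {
    which(tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1L])
  }, integer(1))
  sum(x$counts[eidx])
}

#' Compare character accumulation on two equal-duration paths
#'
#' Tests whether two paths of equal elapsed time accumulated characters at
#' the same rate. The default is a 1-degree-of-freedom chi-square
#' goodness-of-fit of the counts against equal expectations
#' `(k1 + k2) / 2` (equivalently a two-sided normal z on the count
#' difference, no continuity correction); `method = "binomial"` gives the
#' exact two-sided binomial test of k1 successes in k1 + k2 trials at
#' p = 1/2.
#'
#' @param k1,k2 Nonnegative character counts; `k1 + k2 > 0`.
#' @param method `"chisq"` (default) or `"binomial"`.
#' @return Two-sided p-value in [0, 1].
#' @examples
#' compare_paths(123, 118)  # ~0.75
#' @export
compare_paths <- function(k1, k2, method = c("chisq", "binomial")) {
  method <- match.arg(method)
  if (k1 < 0 || k2 < 0) stop("counts must be nonnegative")
  if (k1 + k2 == 0) stop("both counts are zero; no information")
  if (method == "chisq") {
    stat <- (k1 - k2)^2 / (k1 + k2)
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::binom.test(k1, k1 + k2, p = 0.5)$p.value
  }
}
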