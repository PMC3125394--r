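#' Define a calibration point
#'
#' A dated internal node used to convert RGC_CA counts into absolute time.
#' The node is given as the MRCA of two tips; the date is a point value
#' `Tc` (used by the parsimony estimator) inside a fossil interval.
#'
#' @param name Short name for the calibration.
#' @param tips Length-2 character vector of tip labels; the calibrated node
#'   is their MRCA.
#' @param Tc Point date in Mya.
#' @param interval Numeric `c(lower, upper)` in Mya with
#'   `lower <= Tc <= upper`.
#' @return Object of class `rgc_calibration`.
#' @export
calibration <- function(name, tips, Tc, interval = c(Tc, Tc)) {
  stopifnot(length(tips) == 2L, length(interval) == 2L)
  interval <- as.numeric(interval); Tc <- as.numeric(Tc)
  if (!(interval[1] <= Tc && Tc <= interval[2]))
    stop("calibration '", name, "': Tc must lie inside its interval")
  if (Tc <= 0) stop("calibration dates must be positive")
  structure(list(name = name, tips = as.character(tips), Tc = Tc,
                 interval = interval,
                 midpoint = mean(interval)),
            class = "rgc_calibration")
}

#' Read calibrations from a YAML config file
#'
#' Expects a top-level `calibrations` list of entries with fields
#' `name`, `tips` (two tip labels), `age` (point date, Mya) and
#' `interval` (two dates, Mya).
#'
#' @param path Path to YAML file.
#' @return List of [calibration()] objects.
#' @export
read_calibrations <- function(path) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(cfg$calibrations)) cfg$calibrations else cfg
  lapply(entries, function(e)
    calibration(e$name, unlist(e$tips), e$age, unlist(e$interval)))
}

#' Clock rate implied by a calibration and one descending path
#'
#' Under the strict clock, the rate is the path count from the calibrated
#' node down to a tip divided by the calibration date.
#'
#' @param x An `rgc_counts` object.
#' @param cal An [calibration()] object.
#' @param tip Tip label; the path runs from the calibrated node to it.
#' @return Rate in RGC_CA per My.
#' @export
clock_rate <- function(x, cal, tip) {
  node <- resolve_node(x$tree, cal$tips)
  k <- path_length(x, node, tip)
  if (k == 0L)
    stop("zero-count calibration path ", cal$name, " -> ", tip,
         "; rate undefined")
  k / cal$Tc
}

#' One strict-clock parsimony age estimate
#'
#' The estimator is `Te = Tc * K_target / K_cal`, the ratio of the two
#' node-to-tip path counts scaled by the calibration date: under a strict
#' clock, node-to-tip counts are proportional to node ages on an
#' ultrametric time tree, for any choice of descending tip.
#'
#' @param x An `rgc_counts` object.
#' @param target Target internal node ([resolve_node()] forms accepted).
#' @param cal A [calibration()] object.
#' @param cal_tip Tip terminating the calibration path.
#' @param target_tip Tip terminating the target path.
#' @param Tc Calibration date to use; defaults to `cal$Tc` (pass an
#'   interval endpoint to produce an estimate band).
#' @return Estimated age `Te` in Mya.
#' @export
estimate_age <- function(x, target, cal, cal_tip, target_tip, Tc = cal$Tc) {
  tnode <- resolve_node(x$tree, target)
  if (tnode <= ape::Ntip(x$tree)) stop("target must be an internal node")
  cnode <- resolve_node(x$tree, cal$tips)
  k_cal <- path_length(x, cnode, cal_tip)
  if (k_cal == 0L)
    stop("zero-count calibration path for ", cal$name, "; estimate skipped")
  k_target <- path_length(x, tnode, target_tip)
  Tc * k_target / k_cal
}

#' All (calibration, path, path) parsimony estimates for target nodes
#'
#' Enumerates, for every target node, every combination of calibration,
#' tip path descending from the calibrated node, and tip path descending
#' from the target node, and computes `Te` for each. Combinations with a
#' zero-count calibration path are skipped and reported in the
#' `skipped` attribute.
#'
#' @param x An `rgc_counts` object.
#' @param calibrations List of [calibration()] objects (length >= 1).
#' @param targets Named list (or vector) of target node specifications;
#'   names label the `target` column.
#' @return data.frame with columns `target`, `calibration`, `cal_tip`,
#'   `target_tip`, `Te`.
#' @export
all_estimates <- function(x, calibrations, targets) {
  if (inherits(calibrations, "rgc_calibration"))
    calibrations <- list(calibrations)
  if (length(calibrations) < 1L) stop("at least one calibration is required")
  if (is.null(names(targets)))
    names(targets) <- vapply(targets, function(t)
      paste(as.character(t), collapse = "-"), character(1))
  tree <- x$tree
  rows <- list(); skipped <- list()
  for (tname in names(targets)) {
    tnode <- resolve_node(tree, targets[[tname]])
    if (tnode <= ape::Ntip(tree))
      stop("target '", tname, "' must be an internal node")
    ttips <- clade_tips(tree, tnode)
    for (cal in calibrations) {
      cnode <- resolve_node(tree, cal$tips)
      for (ctip in clade_tips(tree, cnode)) {
        k_cal <- path_length(x, cnode, ctip)
        if (k_cal == 0L) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(calibration = cal$name, cal_tip = ctip,
                       stringsAsFactors = FALSE)
          next
        }
        for (ttip in ttips) {
          rows[[length(rows) + 1L]] <- data.frame(
            target = tname, calibration = cal$name, cal_tip = ctip,
            target_tip = ttip,
            Te = cal$Tc * path_length(x, tnode, ttip) / k_cal,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(target = character(), calibration = character(),
               cal_tip = character(), target_tip = character(),
               Te = numeric(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(do.call(rbind, c(skipped, list(
    data.frame(calibration = character(), cal_tip = character(),
               stringsAsFactors = FALSE)))))
  out
}

#' Summarise pooled estimates per target node
#'
#' @param estimates Output of [all_estimates()].
#' @return data.frame with one row per target: `target`, `n`, `mean`,
#'   `median`, `sd`, `min`, `max`.
#' @export
summarize_estimates <- function(estimates) {
  split_te <- split(estimates$Te, estimates$target)
  out <- do.call(rbind, lapply(names(split_te), function(tg) {
    v <- split_te[[tg]]
    data.frame(target = tg, n = length(v), mean = mean(v),
               median = stats::median(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cross-validate the calibration set
#'
#' Each calibration in turn is withheld; its node's age is re-estimated as
#' the pooled mean of all parsimony estimates anchored on the remaining
#' calibrations, and the discrepancy `dTc = |Tc - Te_c|` is reported.
#' Large `dTc` flags a calibration inconsistent with the clock implied by
#' the others.
#'
#' @param x An `rgc_counts` object.
#' @param calibrations List of at least two [calibration()] objects.
#' @param targets Optional named list of additional target nodes; when
#'   given, the returned object carries a `pairs` attribute pairing every
#'   target estimate `Te` anchored on a calibration with that
#'   calibration's `dTc`, for outlier diagnostics.
#' @return data.frame with columns `calibration`, `Tc`, `Te_c`, `dTc`.
#' @export
cross_validate <- function(x, calibrations, targets = NULL) {
  if (length(calibrations) < 2L)
    stop("cross-validation requires at least two calibrations")
  recs <- lapply(seq_along(calibrations), function(i) {
    cal <- calibrations[[i]]
    est <- all_estimates(x, calibrations[-i],
                         targets = stats::setNames(list(cal$tips), cal$name))
    Te_c <- mean(est$Te)
    data.frame(calibration = cal$name, Tc = cal$Tc, Te_c = Te_c,
               dTc = abs(cal$Tc - Te_c), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (!is.null(targets)) {
    est <- all_estimates(x, calibrations, targets)
    est$dTc <- out$dTc[match(est$calibration, out$calibration)]
    attr(out, "pairs") <- est[, c("target", "calibration", "Te", "dTc")]
  }
  out
}

#' Molecular-clock diagnostics
#'
#' Plots-by-numbers version of the rate-linearity check: for every
#' calibrated node and every tip descending from it, pairs the
#' node-to-tip path count with the calibration-interval midpoint, and
#' reports the Pearson correlation of counts against midpoints together
#' with a per-path rate table. A correlation near 1 indicates clocklike
#' accumulation.
#'
#' @param x An `rgc_counts` object.
#' @param calibrations List of [calibration()] objects yielding at least
#'   three (count, midpoint) pairs.
#' @return List with `pairs` (data.frame `calibration`, `tip`, `count`,
#'   `midpoint`, `rate` = count/Tc) and `r` (Pearson correlation).
#' @export
clock_diagnostics <- function(x, calibrations) {
  rows <- list()
  for (cal in calibrations) {
    cnode <- resolve_node(x$tree, cal$tips)
    for (tip in clade_tips(x$tree, cnode)) {
      k <- path_length(x, cnode, tip)
      rows[[length(rows) + 1L]] <- data.frame(
        calibration = cal$name, tip = tip, count = k,
        midpoint = cal$midpoint, rate = k / cal$Tc,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("clock diagnostics require at least three (count, midpoint) pairs")
  list(pairs = pairs, r = stats::cor(pairs$count, pairs$midpoint))
}

#' Pairwise proportion-of-differences distances between taxa
#'
#' Simple comparator distance for the clock diagnostics: the proportion of
#' differing residues between two taxa over all columns (pooled across
#' alignments) where neither taxon has a gap or ambiguity symbol.
#'
#' @param alns An `rgc_alignment` or list of them.
#' @return Symmetric numeric matrix over the union of taxa.
#' @export
pairwise_pdist <- function(alns) {
  if (inherits(alns, "rgc_alignment")) alns <- list(alns)
  alns <- usable_alignments(alns)
  taxa <- sort(unique(unlist(lapply(alns, function(a) rownames(a$aa)))))
  diff <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  tot <- diff
  for (a in alns) {
    m <- a$aa
    usable <- !(m %in% c("-", AMBIGUOUS_AA))
    dim(usable) <- dim(m)
    dimnames(usable) <- dimnames(m)
    for (i in seq_along(taxa)) {
      for (j in seq_len(i - 1L)) {
        ti <- taxa[i]; tj <- taxa[j]
        if (!(ti %in% rownames(m)) || !(tj %in% rownames(m))) next
        ok <- usable[ti, ] & usable[tj, ]
        diff[i, j] <- diff[i, j] + sum(m[ti, ok] != m[tj, ok])
        tot[i, j] <- tot[i, j] + sum(ok)
      }
    }
  }
  d <- ifelse(tot > 0, diff / tot, NA_real_)
  d[upper.tri(d)] <- t(d)[upper.tri(d)]
  diag(d) <- 0
  d
}

#' Clock diagnostics using proportion-of-differences distances
#'
#' Same correlation as [clock_diagnostics()] but with a conventional
#' sequence distance in place of RGC_CA counts: the accumulation from a
#' calibrated node down to tip t is approximated by half the mean
#' p-distance between t and the tips on the other side of that node.
#'
#' @param alns Alignments (passed to [pairwise_pdist()]).
#' @param tree Rooted `phylo` over the ingroup taxa.
#' @param calibrations List of [calibration()] objects (>= 3 pairs needed).
#' @return List with `pairs` (`calibration`, `tip`, `distance`,
#'   `midpoint`) and `r`.
#' @export
clock_diagnostics_pdist <- function(alns, tree, calibrations) {
  pd <- pairwise_pdist(alns)
  rows <- list()
  for (cal in calibrations) {
    cnode <- resolve_node(tree, cal$tips)
    tips <- clade_tips(tree, cnode)
    kids <- tree$edge[tree$edge[, 1] == cnode, 2]
    sides <- lapply(kids, clade_tips, tree = tree)
    for (tip in tips) {
      other <- unlist(sides[!vapply(sides, function(s) tip %in% s, logical(1))])
      rows[[length(rows) + 1L]] <- data.frame(
        calibration = cal$name, tip = tip,
        distance = mean(pd[tip, other]) / 2,
        midpoint = cal$midpoint, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) < 3L)
    stop("clock diagnostics require at least three pairs")
  list(pairs = pairs, r = stats::cor(pairs$distance, pairs$midpoint))
}
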