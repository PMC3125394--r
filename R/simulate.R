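#' The study time tree (coelomate topology, 10 eukaryotes)
#'
#' A rooted ultrametric tree over the ten eukaryote ingroup taxa with
#' branch lengths in My. Internal nodes are labelled (LECA, Plantae,
#' Angiospermae, Opisthokonta, Fungi, Bilateria, Coelomata, Vertebrata,
#' Diptera). Node ages: LECA 1130, Opisthokonta 949, Bilateria 619,
#' Plantae (moss-angiosperm) 450, Vertebrata 370, Angiospermae
#' (monocot-dicot) 339, Diptera 260; the undated Fungi and Coelomata
#' nodes are set to 500 and 550 Mya.
#'
#' Taxon abbreviations: Hs human, Gg chicken, Dm fly, Ag mosquito,
#' Ce nematode, Sc/Sp yeasts, At/Os dicot/monocot plants, Pp moss.
#'
#' @return A `phylo` object.
#' @export
study_time_tree <- function() {
  ages <- c(LECA = 1130, Plantae = 450, Angiospermae = 339,
            Opisthokonta = 949, Fungi = 500, Bilateria = 619,
            Coelomata = 550, Vertebrata = 370, Diptera = 260)
  txt <- paste0("((Pp,(At,Os)Angiospermae)Plantae,((Sc,Sp)Fungi,",
                "(Ce,((Hs,Gg)Vertebrata,(Dm,Ag)Diptera)Coelomata)",
                "Bilateria)Opisthokonta)LECA;")
  tree <- ape::read.tree(text = txt)
  ntip <- ape::Ntip(tree)
  node_age <- c(rep(0, ntip), ages[tree$node.label])
  tree$edge.length <- node_age[tree$edge[, 1]] - node_age[tree$edge[, 2]]
  stopifnot(all(tree$edge.length > 0))
  tree
}

#' Node ages of an ultrametric time tree
#' @param tree Ultrametric `phylo` with edge lengths in My.
#' @return Named numeric vector of ages for labelled internal nodes.
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ntip <- ape::Ntip(tree)
  idx <- (ntip + 1L):(ntip + tree$Nnode)
  stats::setNames(ages[idx],
                  if (!is.null(tree$node.label)) tree$node.label
                  else as.character(idx))
}

#' Taxon roles for the study configuration
#' @param n_outgroup Number of prokaryote outgroup taxa (default 10,
#'   named P1..Pn).
#' @return A [taxon_roles()] object.
#' @export
study_roles <- function(n_outgroup = 10L) {
  taxon_roles(study_time_tree()$tip.label, paste0("P", seq_len(n_outgroup)))
}

#' The study calibration set
#'
#' Three fossil calibrations: fly-mosquito 260 Mya (250-260),
#' moss-angiosperm 450 Mya (430-450), human-chicken 370 Mya (310-370).
#'
#' @return List of [calibration()] objects.
#' @export
study_calibrations <- function() {
  list(
    calibration("diptera", c("Dm", "Ag"), 260, c(250, 260)),
    calibration("plants", c("Pp", "At"), 450, c(430, 450)),
    calibration("vertebrates", c("Hs", "Gg"), 370, c(310, 370))
  )
}

#' The study target nodes
#' @return Named list of internal-node labels whose ages are estimated.
#' @export
study_targets <- function() {
  list(LECA = "LECA", opisthokonts = "Opisthokonta",
       bilateria = "Bilateria", monocot_dicot = "Angiospermae")
}

#' Simulation configuration
#'
#' Parameters of the synthetic sequence-evolution generator. The process
#' plants rare conservative replacements on the branches of a dated tree:
#' each eligible site is hit by Poisson(`lambda` x branch duration)
#' changes per branch; a planted change replaces the ancestral residue in
#' the branch's whole clade with a residue drawn at genetic-code distance
#' 1-3 (`class_probs`). With probability `homoplasy_prob` the same derived
#' residue is additionally planted on a disjoint branch (a
#' tree-incompatible character); with probability `multistate_prob` a
#' different derived residue is planted on another disjoint branch
#' (a multi-state site, excluded from the character set). The outgroup is
#' invariant at every site unless `outgroup_noise > 0`.
#'
#' @param time_tree Rooted ultrametric `phylo` with branch lengths in My.
#' @param outgroup Character vector of outgroup taxon names.
#' @param n_genes Number of gene alignments.
#' @param sites_per_gene Alignment length per gene (amino acids).
#' @param eligible_fraction Fraction of sites free to change; eligible
#'   sites are placed inside the reliable interior (`flank` columns from
#'   the ends).
#' @param lambda Expected substitutions per eligible site per My.
#' @param class_probs Probabilities of drawing a class 1/2/3 replacement
#'   (renormalised over the classes reachable from the ancestral residue).
#' @param homoplasy_prob,multistate_prob Per-change probabilities h and m
#'   described above.
#' @param saturated_fraction Fraction of interior sites (disjoint from the
#'   eligible set) that evolve fast: every analysed taxon, outgroup
#'   included, draws independently from a site-specific two-residue pool.
#'   Such sites are saturated in the sense that their apparent conservation
#'   is coincidental; with few outgroup taxa they can slip through the
#'   unanimity filter and contribute tree-incompatible characters.
#'   Default 0.
#' @param outgroup_noise Per outgroup cell probability of a random
#'   deviating residue (tests the unanimity filter; default 0).
#' @param gap_prob Per cell probability of replacing a residue by a gap
#'   (tests the reliability filter; default 0).
#' @param flank Reliable-window flank used to place eligible sites.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(time_tree = study_time_tree(),
                       outgroup = paste0("P", 1:10),
                       n_genes = 100L, sites_per_gene = 400L,
                       eligible_fraction = 0.65, lambda = 9.5e-6,
                       class_probs = c(0.70, 0.25, 0.05),
                       homoplasy_prob = 0.15, multistate_prob = 0.16,
                       saturated_fraction = 0, outgroup_noise = 0,
                       gap_prob = 0, flank = 5L, seed = NULL) {
  stopifnot(inherits(time_tree, "phylo"), length(outgroup) >= 1L,
            n_genes >= 1L, sites_per_gene >= 1L,
            eligible_fraction > 0, eligible_fraction <= 1,
            lambda > 0, length(class_probs) == 3L, all(class_probs >= 0),
            sum(class_probs) > 0,
            homoplasy_prob >= 0, homoplasy_prob <= 1,
            multistate_prob >= 0, multistate_prob <= 1,
            saturated_fraction >= 0, saturated_fraction < 1,
            outgroup_noise >= 0, outgroup_noise <= 1,
            gap_prob >= 0, gap_prob < 1, flank >= 0)
  if (is.null(time_tree$edge.length) || any(time_tree$edge.length <= 0))
    stop("time_tree must have positive branch lengths (durations in My)")
  if (length(intersect(time_tree$tip.label, outgroup)) > 0L)
    stop("outgroup names must not collide with ingroup tips")
  interior <- sites_per_gene - 2L * flank
  n_eligible <- round(eligible_fraction * sites_per_gene)
  n_saturated <- round(saturated_fraction * sites_per_gene)
  if (interior < n_eligible + n_saturated)
    stop("eligible_fraction + saturated_fraction too large for ",
         "sites_per_gene given the flank")
  structure(list(time_tree = time_tree, outgroup = as.character(outgroup),
                 n_genes = as.integer(n_genes),
                 sites_per_gene = as.integer(sites_per_gene),
                 eligible_fraction = eligible_fraction, lambda = lambda,
                 class_probs = class_probs / sum(class_probs),
                 homoplasy_prob = homoplasy_prob,
                 multistate_prob = multistate_prob,
                 saturated_fraction = saturated_fraction,
                 outgroup_noise = outgroup_noise, gap_prob = gap_prob,
                 flank = as.integer(flank), seed = seed,
                 n_eligible = as.integer(n_eligible),
                 n_saturated = as.integer(n_saturated)),
            class = "sim_config")
}

#' Default configuration emulating the study conditions
#'
#' [sim_config()] on the [study_time_tree()] with 10 outgroup taxa,
#' 100 genes x 400 sites (65% eligible), rate tuned so the expected
#' number of detected characters is ~1300, homoplasy 15% and multi-state
#' fraction 16%.
#'
#' @param seed Optional integer seed.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config` object.
#' @export
default_study_config <- function(seed = NULL, ...) {
  sim_config(seed = seed, ...)
}

# per-edge helper table: child node, clade key, duration, disjoint edges
edge_plan <- function(tree) {
  keys <- edge_clade_keys(tree)
  clades <- lapply(tree$edge[, 2], clade_tips, tree = tree)
  n_in <- ape::Ntip(tree)
  ne <- nrow(tree$edge)
  disjoint <- lapply(seq_len(ne), function(i) {
    ok <- vapply(seq_len(ne), function(j) {
      j != i &&
        length(intersect(clades[[i]], clades[[j]])) == 0L &&
        length(clades[[i]]) + length(clades[[j]]) < n_in
    }, logical(1))
    which(ok)
  })
  list(keys = keys, clades = clades, duration = tree$edge.length,
       disjoint = disjoint)
}

# derived residue at genetic-code distance drawn from class_probs
draw_derived <- function(anc, class_probs, exclude = NULL) {
  d <- std_aa_distance_matrix()[anc, ]
  pool <- setdiff(names(d)[d > 0L], exclude)
  if (length(pool) == 0L) return(NULL)
  avail <- sort(unique(d[pool]))
  p <- class_probs[avail]
  cls <- if (length(avail) == 1L) avail else sample(avail, 1L, prob = p)
  cands <- pool[d[pool] == cls]
  cands[sample.int(length(cands), 1L)]
}

# minimal-change codon pair: a codon of `anc`, and a codon of `der`
# at minimal Hamming distance from it
codon_pair <- function(anc_codon, der) {
  code <- genetic_code()
  cands <- names(code)[code == der]
  hd <- vapply(cands, function(cd)
    sum(strsplit(cd, "")[[1]] != strsplit(anc_codon, "")[[1]]), integer(1))
  cands[which.min(hd)]
}

random_codon <- function(aa) {
  code <- genetic_code()
  cands <- names(code)[code == aa]
  cands[sample.int(length(cands), 1L)]
}

#' Simulate a full dataset with ground truth
#'
#' Runs the generator described in [sim_config()] and returns the
#' alignments (with codon layers) together with a truth record for every
#' planted change.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return List of class `rgc_simulation` with elements
#'   \describe{
#'     \item{alignments}{named list of `rgc_alignment` objects}
#'     \item{truth}{list with `changes` (one row per planted change:
#'       `gene_id`, `site`, `branch` clade key, `ancestral`, `derived`,
#'       `sub_class`, `kind` in primary/homoplasy/multistate, and for
#'       primary rows the flags `has_homoplasy`, `has_multistate`),
#'       `branches` (per-branch `branch`, `duration`, `expected`,
#'       `realized` primary-change counts), and `ages` (true node ages)}
#'     \item{roles}{the [taxon_roles()] used}
#'     \item{config}{the configuration}
#'   }
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(seed)) set.seed(seed)
  tree <- config$time_tree
  plan <- edge_plan(tree)
  ingroup <- tree$tip.label
  taxa <- c(ingroup, config$outgroup)
  ne <- nrow(tree$edge)
  L <- config$sites_per_gene
  interior <- (config$flank + 1L):(L - config$flank)
  E_g <- config$n_eligible
  total_dur <- sum(plan$duration)
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))

  alns <- vector("list", config$n_genes)
  changes <- list()
  realized <- integer(ne)

  for (g in seq_len(config$n_genes)) {
    anc_aa <- sample(STANDARD_AA, L, replace = TRUE)
    special <- sample(interior, E_g + config$n_saturated)
    eligible <- sort(special[seq_len(E_g)])
    saturated <- if (config$n_saturated > 0L) special[-seq_len(E_g)]
                 else integer(0)
    n_changes <- min(stats::rpois(1L, config$lambda * E_g * total_dur), E_g)
    M <- matrix(rep(anc_aa, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
    codon_anc <- vapply(anc_aa, random_codon, character(1))
    K <- matrix(rep(codon_anc, each = length(taxa)), nrow = length(taxa),
                dimnames = list(taxa, NULL))
    for (s in saturated) {
      pool <- sample(STANDARD_AA, 2L)
      states <- sample(pool, length(taxa), replace = TRUE)
      M[, s] <- states
      K[, s] <- vapply(states, random_codon, character(1))
    }
    if (n_changes > 0L) {
      sites <- sample(eligible, n_changes)
      branches <- sample.int(ne, n_changes, replace = TRUE,
                             prob = plan$duration)
      for (i in seq_len(n_changes)) {
        s <- sites[i]; b <- branches[i]
        anc <- anc_aa[s]
        der <- draw_derived(anc, config$class_probs)
        carriers <- plan$clades[[b]]
        M[carriers, s] <- der
        K[carriers, s] <- codon_pair(codon_anc[s], der)
        realized[b] <- realized[b] + 1L
        has_h <- stats::runif(1) < config$homoplasy_prob &&
          length(plan$disjoint[[b]]) > 0L
        has_m <- stats::runif(1) < config$multistate_prob &&
          length(plan$disjoint[[b]]) > 1L
        rec <- data.frame(
          gene_id = gene_ids[g], site = s, branch = plan$keys[b],
          ancestral = anc, derived = der,
          sub_class = unname(std_aa_distance_matrix()[anc, der]),
          kind = "primary", has_homoplasy = has_h, has_multistate = has_m,
          stringsAsFactors = FALSE)
        changes[[length(changes) + 1L]] <- rec
        used <- b
        if (has_h) {
          b2 <- plan$disjoint[[b]][sample.int(length(plan$disjoint[[b]]), 1L)]
          used <- c(used, b2)
          car2 <- plan$clades[[b2]]
          M[car2, s] <- der
          K[car2, s] <- codon_pair(codon_anc[s], der)
          changes[[length(changes) + 1L]] <- within(rec, {
            branch <- plan$keys[b2]; kind <- "homoplasy"
          })
        }
        if (has_m) {
          cand3 <- setdiff(plan$disjoint[[b]], used)
          if (length(cand3) > 0L) {
            b3 <- cand3[sample.int(length(cand3), 1L)]
            der2 <- draw_derived(anc, config$class_probs, exclude = der)
            if (!is.null(der2)) {
              car3 <- plan$clades[[b3]]
              M[car3, s] <- der2
              K[car3, s] <- codon_pair(codon_anc[s], der2)
              changes[[length(changes) + 1L]] <- within(rec, {
                branch <- plan$keys[b3]; kind <- "multistate"
                derived <- der2
                sub_class <- unname(std_aa_distance_matrix()[anc, der2])
              })
            }
          }
        }
      }
    }
    if (config$outgroup_noise > 0) {
      og_cells <- which(matrix(stats::runif(length(config$outgroup) * L),
                               nrow = length(config$outgroup)) <
                          config$outgroup_noise, arr.ind = TRUE)
      for (k in seq_len(nrow(og_cells))) {
        tx <- config$outgroup[og_cells[k, 1]]; s <- og_cells[k, 2]
        new_aa <- sample(setdiff(STANDARD_AA, M[tx, s]), 1L)
        M[tx, s] <- new_aa
        K[tx, s] <- random_codon(new_aa)
      }
    }
    if (config$gap_prob > 0) {
      gaps <- matrix(stats::runif(length(taxa) * L),
                     nrow = length(taxa)) < config$gap_prob
      M[gaps] <- "-"
      K[gaps] <- "---"
    }
    alns[[g]] <- structure(list(gene_id = gene_ids[g], aa = M, codons = K),
                           class = "rgc_alignment")
  }
  names(alns) <- gene_ids

  changes <- do.call(rbind, c(changes, list(data.frame(
    gene_id = character(), site = integer(), branch = character(),
    ancestral = character(), derived = character(), sub_class = integer(),
    kind = character(), has_homoplasy = logical(), has_multistate = logical(),
    stringsAsFactors = FALSE))))
  rownames(changes) <- NULL
  branches <- data.frame(
    branch = plan$keys, duration = plan$duration,
    expected = config$lambda * E_g * config$n_genes * plan$duration,
    realized = realized, stringsAsFactors = FALSE)
  structure(list(
    alignments = alns,
    truth = list(changes = changes, branches = branches,
                 ages = node_ages(tree)),
    roles = taxon_roles(ingroup, config$outgroup),
    config = config
  ), class = "rgc_simulation")
}

#' Simulate the compatible branch-count layer only
#'
#' Fast counterpart of [simulate_dataset()] for experiments that operate
#' on counted trees directly (cross-validation, clock diagnostics over
#' many replicates): draws per-branch Poisson counts with mean
#' `lambda x eligible sites x duration`, thinned by the multi-state and
#' homoplasy losses, so the counts are distributed like the compatible
#' characters the full pipeline would map.
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return An `rgc_counts` object over `config$time_tree`.
#' @export
simulate_branch_counts <- function(config, seed = config$seed) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  if (!is.null(seed)) set.seed(seed)
  tree <- config$time_tree
  keys <- edge_clade_keys(tree)
  mu <- config$lambda * config$n_eligible * config$n_genes *
    tree$edge.length * (1 - config$multistate_prob) *
    (1 - config$homoplasy_prob)
  counts <- stats::rpois(length(mu), mu)
  structure(list(
    tree = tree, counts = counts, edge_keys = keys,
    summary = list(total = sum(counts), compatible = sum(counts),
                   incompatible = 0L,
                   homoplasy_fraction = if (sum(counts) > 0) 0 else NA_real_)
  ), class = "rgc_counts")
}

#' Write a simulated dataset to disk
#'
#' Writes per-gene amino-acid and nucleotide FASTA alignments, the time
#' tree as Newick, the taxon roles and calibration-free truth tables as
#' TSV; all files are consumed unchanged by the analysis functions.
#'
#' @param sim An `rgc_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aln in sim$alignments) {
    aa <- apply(aln$aa, 1, paste, collapse = "")
    Biostrings::writeXStringSet(
      Biostrings::BStringSet(aa),
      file.path(dir, paste0(aln$gene_id, ".fa")))
    if (!is.null(aln$codons)) {
      nt <- apply(aln$codons, 1, paste, collapse = "")
      Biostrings::writeXStringSet(
        Biostrings::BStringSet(nt),
        file.path(dir, paste0(aln$gene_id, ".nt.fasta")))
    }
  }
  ape::write.tree(sim$config$time_tree, file.path(dir, "time_tree.nwk"))
  yaml::write_yaml(list(ingroup = sim$roles$ingroup,
                        outgroup = sim$roles$outgroup),
                   file.path(dir, "roles.yaml"))
  utils::write.table(sim$truth$changes, file.path(dir, "truth_changes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$branches, file.path(dir, "truth_branches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
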