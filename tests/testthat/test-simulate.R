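test_that("invalid configurations are rejected before any output", {
  expect_error(sim_config(lambda = 0))
  expect_error(sim_config(eligible_fraction = 0))
  expect_error(sim_config(eligible_fraction = 1.2))
  expect_error(sim_config(homoplasy_prob = 1.5))
  expect_error(sim_config(sites_per_gene = 12, eligible_fraction = 0.9),
               "too large")
  expect_error(sim_config(outgroup = c("Hs", "P1")), "collide")
  tr <- study_time_tree(); tr$edge.length <- NULL
  expect_error(sim_config(time_tree = tr), "branch lengths")
  expect_error(simulate_dataset(list()), "sim_config")
})

test_that("identical seeds reproduce the dataset; different seeds do not", {
  cfg <- sim_config(n_genes = 4, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(lapply(a$alignments, `[[`, "aa"),
                   lapply(b$alignments, `[[`, "aa"))
  expect_identical(a$truth$changes, b$truth$changes)
  c <- simulate_dataset(cfg, seed = 100)
  expect_false(identical(a$truth$changes, c$truth$changes))
})

test_that("invariant sites are identical across all taxa and the outgroup never varies", {
  sim <- simulate_dataset(sim_config(n_genes = 3, seed = 7))
  for (aln in sim$alignments) {
    og <- aln$aa[sim$roles$outgroup, , drop = FALSE]
    expect_true(all(og == og[rep(1, nrow(og)), ]))
    touched <- unique(sim$truth$changes$site[
      sim$truth$changes$gene_id == aln$gene_id])
    untouched <- setdiff(seq_len(ncol(aln$aa)), touched)
    sub <- aln$aa[, untouched, drop = FALSE]
    expect_true(all(sub == sub[rep(1, nrow(sub)), ]))
  }
})

test_that("codon layers translate to the amino-acid rows", {
  sim <- simulate_dataset(sim_config(n_genes = 2, seed = 15))
  code <- genetic_code()
  for (aln in sim$alignments) {
    expect_false(is.null(aln$codons))
    expect_identical(unname(code[aln$codons]), c(aln$aa))
  }
})

test_that("realized branch totals are Poisson-consistent with expectations", {
  sim <- simulate_dataset(sim_config(n_genes = 120, seed = 55))
  br <- sim$truth$branches
  # totals within 4 standard deviations, strong per-branch agreement
  expect_lt(abs(sum(br$realized) - sum(br$expected)),
            4 * sqrt(sum(br$expected)))
  expect_gt(cor(br$realized, br$expected), 0.9)
  # dispersion index of the standardised residuals near 1
  disp <- sum((br$realized - br$expected)^2 / br$expected) / nrow(br)
  expect_gt(disp, 0.3); expect_lt(disp, 3)
  # bookkeeping identity: per-branch realized = per-gene sums
  primary <- sim$truth$changes[sim$truth$changes$kind == "primary", ]
  expect_equal(setNames(br$realized, br$branch)[sort(unique(primary$branch))],
               table(primary$branch)[sort(unique(primary$branch))],
               ignore_attr = TRUE)
  expect_equal(sum(br$realized), nrow(primary))
})

test_that("doubling the rate doubles the detected character count", {
  n_chars <- function(lam, seed) {
    sim <- simulate_dataset(sim_config(n_genes = 50, lambda = lam,
                                       seed = seed))
    nrow(detect_characters(sim$alignments, sim$roles))
  }
  n1 <- n_chars(9.5e-6, 201)
  n2 <- n_chars(1.9e-5, 202)
  expect_gt(n1, 300)  # enough characters for the ratio to be meaningful
  se <- 4 * sqrt(1 / n1 + 1 / n2)  # delta-method error on the log ratio
  expect_lt(abs(log(n2 / n1) - log(2)), se)
})

test_that("planted homoplasy is recovered at the configured level", {
  sim <- simulate_dataset(sim_config(homoplasy_prob = 0.15, seed = 77))
  chars <- detect_characters(sim$alignments, sim$roles)
  s <- branch_lengths(chars, sim$config$time_tree)$summary
  expect_lt(abs(s$homoplasy_fraction - 0.15),
            4 * sqrt(0.15 * 0.85 / s$total) + 0.01)
})

test_that("gap injection shrinks the reliable set; outgroup noise drops columns", {
  clean <- simulate_dataset(sim_config(n_genes = 5, seed = 33))
  gappy <- simulate_dataset(sim_config(n_genes = 5, gap_prob = 0.02,
                                       seed = 33))
  rel_clean <- sum(lengths(lapply(clean$alignments, reliable_positions)))
  rel_gappy <- sum(lengths(lapply(gappy$alignments, reliable_positions)))
  expect_lt(rel_gappy, rel_clean)
  noisy <- simulate_dataset(sim_config(n_genes = 5, outgroup_noise = 0.05,
                                       seed = 33))
  n_noisy <- nrow(detect_characters(noisy$alignments, noisy$roles))
  n_clean <- nrow(detect_characters(clean$alignments, clean$roles))
  expect_lt(n_noisy, n_clean)
})

test_that("the default study configuration encodes the study conditions", {
  cfg <- default_study_config()
  ages <- node_ages(cfg$time_tree)
  expect_equal(unname(ages["LECA"]), 1130)
  expect_equal(unname(ages["Opisthokonta"]), 949)
  expect_equal(unname(ages["Bilateria"]), 619)
  expect_equal(unname(ages["Angiospermae"]), 339)
  cals <- study_calibrations()
  expect_equal(vapply(cals, `[[`, 0, "Tc"), c(260, 450, 370))
  expect_equal(cals[[1]]$interval, c(250, 260))
  expect_equal(cals[[3]]$interval, c(310, 370))
  # expected detected characters near 1300 at the default rate
  expected_changes <- cfg$lambda * cfg$n_eligible * cfg$n_genes *
    sum(cfg$time_tree$edge.length)
  expect_lt(abs(expected_changes * (1 - cfg$multistate_prob) - 1300), 100)
})

test_that("a written dataset analyses identically to the in-memory one", {
  cfg <- sim_config(n_genes = 6, gap_prob = 0.005, seed = 121)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  roles <- read_taxon_roles(file.path(dir, "roles.yaml"))
  alns <- read_alignment_dir(dir, roles)
  expect_length(alns, 6L)
  expect_equal(detect_characters(alns, roles),
               detect_characters(sim$alignments, sim$roles),
               ignore_attr = TRUE)
  tree <- ape::read.tree(file.path(dir, "time_tree.nwk"))
  expect_setequal(tree$tip.label, roles$ingroup)
  truth <- utils::read.delim(file.path(dir, "truth_changes.tsv"))
  expect_equal(nrow(truth), nrow(sim$truth$changes))
})

test_that("the count-layer simulator matches the full pipeline distribution", {
  cfg <- default_study_config()
  # compare means over a handful of replicates: count layer vs full run
  set.seed(303)
  fast_tot <- mean(replicate(10, sum(simulate_branch_counts(
    cfg, seed = sample.int(2^30, 1))$counts)))
  sim <- simulate_dataset(cfg, seed = 404)
  full_cnt <- branch_lengths(detect_characters(sim$alignments, sim$roles),
                             cfg$time_tree)
  # compatible characters in the full pipeline vs the thinned Poisson layer
  expect_lt(abs(full_cnt$summary$compatible - fast_tot) / fast_tot, 0.15)
})
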