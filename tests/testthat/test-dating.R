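test_that("the clock rate is the path count over the calibration date", {
  tr <- study_time_tree()
  # put 26 characters on the Diptera->Dm terminal branch
  dm_edge <- which(tr$edge[, 2] == resolve_node(tr, "Dm"))
  counts <- integer(nrow(tr$edge)); counts[dm_edge] <- 26L
  x <- fabricate_counts(tr, counts)
  cal <- calibration("diptera", c("Dm", "Ag"), 260, c(250, 260))
  expect_equal(clock_rate(x, cal, "Dm"), 0.1)
  expect_error(clock_rate(x, cal, "Ag"), "zero-count")
})

test_that("the parsimony estimator scales the calibration date by path counts", {
  tr <- study_time_tree()
  counts <- integer(nrow(tr$edge))
  dm_edge <- which(tr$edge[, 2] == resolve_node(tr, "Dm"))
  counts[dm_edge] <- 26L
  # 113 characters along LECA->...->Hs, all placed on the terminal branch
  hs_edge <- which(tr$edge[, 2] == resolve_node(tr, "Hs"))
  counts[hs_edge] <- 113L
  x <- fabricate_counts(tr, counts)
  cal <- calibration("diptera", c("Dm", "Ag"), 260)
  est <- estimate_age(x, "LECA", cal, cal_tip = "Dm", target_tip = "Hs")
  expect_equal(est, 260 * 113 / 26)
  expect_equal(est, 1130)
  expect_error(estimate_age(x, "Hs", cal, "Dm", "Hs"), "internal")
  expect_error(estimate_age(x, "LECA", cal, "Ag", "Hs"), "zero-count")
})

test_that("self-calibration returns Tc exactly for every path choice", {
  sim_counts <- simulate_branch_counts(default_study_config(), seed = 5)
  for (cal in study_calibrations()) {
    cnode <- resolve_node(sim_counts$tree, cal$tips)
    for (tip in clade_tips(sim_counts$tree, cnode)) {
      if (path_length(sim_counts, cnode, tip) == 0L) next
      expect_equal(estimate_age(sim_counts, cnode, cal,
                                cal_tip = tip, target_tip = tip), cal$Tc)
    }
  }
})

test_that("estimates are equivariant under rescaling all calibration dates", {
  x <- simulate_branch_counts(default_study_config(), seed = 9)
  cals <- study_calibrations()
  scaled <- lapply(cals, function(cl)
    calibration(cl$name, cl$tips, 3 * cl$Tc, 3 * cl$interval))
  e1 <- all_estimates(x, cals, study_targets())
  e3 <- all_estimates(x, scaled, study_targets())
  expect_equal(e3$Te, 3 * e1$Te)
})

test_that("exactly proportional counts recover every node age exactly", {
  tr <- study_time_tree()
  x <- fabricate_counts(tr, tr$edge.length)  # rate 1 per My, no noise
  est <- all_estimates(x, study_calibrations(), study_targets())
  truth <- node_ages(tr)[c(LECA = "LECA", opisthokonts = "Opisthokonta",
                           bilateria = "Bilateria",
                           monocot_dicot = "Angiospermae")]
  names(truth) <- names(study_targets())
  expect_equal(est$Te, unname(truth[est$target]), tolerance = 1e-12)
  smry <- summarize_estimates(est)
  expect_equal(smry$sd, rep(0, nrow(smry)), tolerance = 1e-9)
  expect_true(all(smry$min <= smry$median & smry$median <= smry$max))
})

test_that("estimate enumeration matches the combinatorial count", {
  x <- simulate_branch_counts(default_study_config(), seed = 13)
  cals <- study_calibrations()
  est <- all_estimates(x, cals, study_targets())
  # calibration tip paths: diptera 2, plants 3, vertebrates 2 = 7
  tips_under <- function(spec) length(clade_tips(x$tree,
                                                 resolve_node(x$tree, spec)))
  for (tname in names(study_targets())) {
    n_expect <- 7L * tips_under(study_targets()[[tname]])
    expect_equal(sum(est$target == tname), n_expect)
  }
  # single calibration, single tip path: one estimate, sd 0
  ce_cal <- calibration("bilat", c("Ce", "Hs"), 619)
  one <- all_estimates(x, list(ce_cal), list(fungi = "Fungi"))
  one_ce <- one[one$cal_tip == "Ce" & one$target_tip == "Sc", ]
  expect_equal(nrow(one_ce), 1L)
  s <- summarize_estimates(one_ce)
  expect_equal(s$mean, one_ce$Te)
  expect_equal(s$sd, 0)
})

test_that("zero-count calibration paths are skipped and reported", {
  tr <- study_time_tree()
  counts <- rep(1L, nrow(tr$edge))
  counts[tr$edge[, 2] == resolve_node(tr, "Dm")] <- 0L
  # zero the whole Diptera->Dm path: also the Diptera stem stays positive,
  # so only the Dm tip path is dead
  x <- fabricate_counts(tr, counts)
  est <- all_estimates(x, study_calibrations()[1], list(LECA = "LECA"))
  skipped <- attr(est, "skipped")
  expect_equal(nrow(est), 10L)  # only the Ag path remains (10 target tips)
  expect_equal(skipped$cal_tip, "Dm")
})

test_that("cross-validation needs two calibrations and flags consistency", {
  x <- simulate_branch_counts(default_study_config(), seed = 17)
  cals <- study_calibrations()
  expect_error(cross_validate(x, cals[1]), "two calibrations")
  xv <- cross_validate(x, cals)
  expect_equal(nrow(xv), 3L)
  expect_equal(xv$dTc, abs(xv$Tc - xv$Te_c))
  # mutually consistent calibrations: discrepancies small vs the dates
  expect_true(all(xv$dTc / xv$Tc < 0.35))
})

test_that("a corrupted calibration shows the largest cross-validation gap", {
  cfg <- default_study_config()
  cals <- study_calibrations()
  cals[[3]] <- calibration(cals[[3]]$name, cals[[3]]$tips,
                           2 * cals[[3]]$Tc, 2 * cals[[3]]$interval)
  x <- simulate_branch_counts(cfg, seed = 19)
  xv <- cross_validate(x, cals, targets = study_targets())
  expect_equal(xv$calibration[which.max(xv$dTc)], "vertebrates")
  pairs <- attr(xv, "pairs")
  expect_true(all(c("target", "calibration", "Te", "dTc") %in% names(pairs)))
  # estimates anchored on the corrupted calibration are the outliers:
  # their pooled LECA mean is far above the clean-anchored pool
  leca <- pairs[pairs$target == "LECA", ]
  corrupt_mean <- mean(leca$Te[leca$calibration == "vertebrates"])
  clean_mean <- mean(leca$Te[leca$calibration != "vertebrates"])
  expect_gt(corrupt_mean / clean_mean, 1.5)
})

test_that("clock diagnostics demand three pairs and bound the correlation", {
  tr <- study_time_tree()
  x <- fabricate_counts(tr, tr$edge.length * 0.2)
  expect_error(clock_diagnostics(x, list()), "three")
  d <- clock_diagnostics(x, all_node_calibrations(tr))
  expect_equal(d$r, 1)
  expect_true(all(c("calibration", "tip", "count", "midpoint", "rate")
                  %in% names(d$pairs)))
  # noisy counts: correlation high but below 1
  xn <- simulate_branch_counts(default_study_config(), seed = 23)
  dn <- clock_diagnostics(xn, all_node_calibrations(tr))
  expect_true(dn$r > 0.8 && dn$r <= 1)
})

test_that("the p-distance comparator also correlates with node depth", {
  sim <- simulate_dataset(sim_config(n_genes = 25, seed = 27))
  tr <- sim$config$time_tree
  pd <- pairwise_pdist(sim$alignments)
  expect_true(isSymmetric(pd))
  expect_true(all(diag(pd) == 0))
  expect_true(all(pd >= 0 & pd <= 1, na.rm = TRUE))
  d <- clock_diagnostics_pdist(sim$alignments, tr, all_node_calibrations(tr))
  expect_gt(d$r, 0.8)
})

test_that("calibration YAML round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(calibrations = list(
    list(name = "diptera", tips = c("Dm", "Ag"), age = 260,
         interval = c(250, 260)),
    list(name = "plants", tips = c("Pp", "At"), age = 450,
         interval = c(430, 450)))), path)
  cals <- read_calibrations(path)
  expect_length(cals, 2L)
  expect_equal(cals[[1]]$Tc, 260)
  expect_equal(cals[[2]]$midpoint, 440)
  expect_error(calibration("bad", c("a", "b"), 100, c(150, 200)), "interval")
})
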