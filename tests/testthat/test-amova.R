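test_that("AMOVA degrees of freedom follow the three-level design", {
  cfg <- sim_config(sizes = c(14, 14), n_admixed = 13, seed = 4)
  gm <- simulate_panel(cfg)  # N = 41 with 3 labels (Pop1, Pop2, Admix)
  res <- amova_codominant(gm, n_perm = 0)
  expect_equal(res$table$df, c(2L, 38L, 41L, 81L))
  expect_equal(sum(res$table$df[1:3]), 81L)
  # SS additivity and percent closure
  expect_equal(sum(res$table$SS[1:3]), res$table$SS[4], tolerance = 1e-8)
  expect_equal(sum(res$table$percent[1:3]), 100)
  expect_true(all(res$table$est_var >= 0))
})

test_that("complete fixation gives F_ST = 1 with all variance among populations", {
  gm <- make_gm(m1 = c("A/A", "A/A", "G/G", "G/G"),
                m2 = c("C/C", "C/C", "T/T", "T/T"),
                populations = c("p1", "p1", "p2", "p2"))
  res <- amova_codominant(gm, n_perm = 0)
  expect_equal(res$f_st, 1)
  expect_equal(res$table$percent[1], 100)
  # enumerated truth: permutations preserving sizes can tie but never
  # exceed F_ST = 1, and exactly 2 of the 6 assignments reproduce it
  combos <- combn(4, 2)
  fs <- apply(combos, 2, function(ix) {
    pops <- rep("p2", 4); pops[ix] <- "p1"
    amova_codominant(make_gm(m1 = gm$calls[, 1], m2 = gm$calls[, 2],
                             populations = pops), n_perm = 0)$f_st
  })
  expect_true(all(fs <= 1 + 1e-12))
  p_exact <- mean(fs >= 1 - 1e-12)  # = 1/3
  pv <- permute_fst(gm, res, n_perm = 600, seed = 2)
  expect_gte(pv, 1 / 601)
  expect_lt(abs(pv - p_exact), 0.07)
})

test_that("AMOVA SS agree exactly with pair-enumeration oracle on small panels", {
  for (seed in 1:8) {
    gm <- random_panel(8, 6, seed = 100 + seed,
                       missing_rate = ifelse(seed %% 2, 0, 0.1))
    pops <- rep(c("x", "y"), each = 4)
    gm$populations <- setNames(pops, gm$accession_ids)
    res <- try(amova_codominant(gm, n_perm = 0), silent = TRUE)
    if (inherits(res, "try-error")) next  # all-missing corner
    oracle <- brute_amova_ss(gm, pops)
    expect_equal(res$table$SS[1:3], unname(oracle[1:3]), tolerance = 1e-10)
    expect_equal(res$table$SS[4], unname(oracle[4]), tolerance = 1e-10)
  }
})

test_that("duplicating loci doubles SS but leaves F_ST and percentages fixed", {
  gm <- random_panel(12, 10, seed = 77)
  pops <- rep(c("x", "y"), each = 6)
  gm$populations <- setNames(pops, gm$accession_ids)
  res1 <- amova_codominant(gm, n_perm = 0)
  calls2 <- cbind(gm$calls, gm$calls)
  colnames(calls2) <- paste0("L", seq_len(20))
  gm2 <- genotype_matrix(calls2, populations = pops)
  res2 <- amova_codominant(gm2, n_perm = 0)
  expect_equal(res2$table$SS, 2 * res1$table$SS, tolerance = 1e-10)
  expect_equal(res2$f_st, res1$f_st, tolerance = 1e-10)
  expect_equal(res2$table$percent, res1$table$percent, tolerance = 1e-8)
})

test_that("a panmictic population split at random shows near-zero F_ST", {
  set.seed(9)
  fsts <- ps <- numeric(60)
  for (r in seq_len(60)) {
    gm <- random_panel(30, 25, seed = 500 + r)
    pops <- sample(rep(c("a", "b"), each = 15))
    gm$populations <- setNames(pops, gm$accession_ids)
    res <- amova_codominant(gm, n_perm = 19, seed = r)
    fsts[r] <- res$f_st
    ps[r] <- res$p_value
  }
  expect_lt(mean(fsts), 0.02)   # truncation at 0 makes the mean slightly +
  # p-values roughly uniform: around half should be below 0.5
  expect_gt(mean(ps <= 0.5), 0.3)
  expect_lt(mean(ps <= 0.5), 0.75)
})

test_that("permutation p-values are bounded, deterministic and error-checked", {
  gm <- random_panel(10, 8, seed = 55)
  pops <- rep(c("a", "b"), each = 5)
  gm$populations <- setNames(pops, gm$accession_ids)
  res <- amova_codominant(gm, n_perm = 99, seed = 1)
  expect_gte(res$p_value, 1 / 100)
  expect_lte(res$p_value, 1)
  res2 <- amova_codominant(gm, n_perm = 99, seed = 1)
  expect_identical(res$p_value, res2$p_value)
  expect_error(amova_codominant(gm, populations = rep("one", 10),
                                n_perm = 0), ">= 2 populations")
  expect_error(amova_codominant(gm, populations = c("a", rep("b", 9)),
                                n_perm = 0), "single individual")
  expect_error(permute_fst(gm, res, n_perm = 0), ">= 1")
})

test_that("AMOVA estimate tracks the realized F_ST of each replicate", {
  # companion to the parameter-recovery criterion: against the *realized*
  # differentiation of the drawn populations the estimator is tight
  # "realized" = the same estimator on a 15x larger sample drawn from the
  # identical population frequencies, where sampling noise is negligible
  hits <- 0L
  for (s in 1:12) {
    cfg <- sim_config(sizes = c(40, 40, 40), n_admixed = 0, n_loci = 70,
                      monomorphic_fraction = 0, target_fst = 0.3,
                      f_excess = 0, seed = 900 + s)
    freqs <- simulate_allele_frequencies(cfg)
    gm <- simulate_genotypes(cfg, freqs)
    est <- amova_codominant(gm, n_perm = 0)$f_st
    cfg_big <- sim_config(sizes = c(600, 600, 600), n_admixed = 0,
                          n_loci = 70, monomorphic_fraction = 0,
                          target_fst = 0.3, f_excess = 0, seed = 900 + s)
    gm_big <- simulate_genotypes(cfg_big, freqs)
    realized <- amova_codominant(gm_big, n_perm = 0)$f_st
    if (abs(est - realized) <= 0.04) hits <- hits + 1L
  }
  expect_gte(hits, 11L)
})
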