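test_that("individual profiles spread diploid calls into frequencies", {
  gm <- make_gm(m1 = c("A/G", "A/A"), m2 = c(NA, "C/T"))
  p1 <- individual_allele_profile(gm, "acc01")
  expect_equal(p1$m1, c(A = 0.5, G = 0.5))
  expect_false("m2" %in% names(p1))
  p2 <- individual_allele_profile(gm, "acc02")
  expect_equal(p2$m1, c(A = 1))
  for (prof in list(p1, p2)) {
    expect_true(all(abs(vapply(prof, sum, numeric(1)) - 1) < 1e-12))
  }
})

test_that("Nei standard distance reproduces closed forms", {
  gm <- make_gm(m1 = c("A/A", "A/G"))
  pa <- individual_allele_profile(gm, "acc01")
  pb <- individual_allele_profile(gm, "acc02")
  expect_equal(nei_standard_distance(pa, pa), 0)
  expect_equal(nei_standard_distance(pa, pb), 0.5 * log(2))
  gm2 <- make_gm(m1 = c("A/A", "A/A"), m2 = c("A/A", "G/G"))
  expect_equal(nei_standard_distance(
    individual_allele_profile(gm2, "acc01"),
    individual_allele_profile(gm2, "acc02")), log(2))
  # no shared alleles anywhere -> infinite
  gm3 <- make_gm(m1 = c("A/A", "G/G"))
  expect_equal(nei_standard_distance(
    individual_allele_profile(gm3, "acc01"),
    individual_allele_profile(gm3, "acc02")), Inf)
  expect_error(distance_matrix(gm3), "infinite")
})

test_that("distance matrix equals the brute-force oracle and relabels cleanly", {
  gm <- random_panel(8, 12, seed = 3, missing_rate = 0.08)
  dm <- distance_matrix(gm)
  expect_true(isSymmetric(unname(dm$d)))
  expect_equal(unname(diag(dm$d)), rep(0, 8))
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(dm$d[i, j],
                 brute_nei(gm, gm$accession_ids[i], gm$accession_ids[j]))
  }
  # duplicated accession rows are at distance zero
  calls <- rbind(gm$calls, dup = gm$calls[1, ])
  rownames(calls) <- c(gm$accession_ids, "dup")
  dm2 <- distance_matrix(genotype_matrix(calls))
  expect_equal(unname(dm2$d["dup", gm$accession_ids[1]]), 0)
  # permutation equivariance
  perm <- c(5, 2, 8, 1, 3, 7, 6, 4)
  dmp <- distance_matrix(subset_genotypes(gm, accessions = perm))
  expect_equal(dmp$d, dm$d[perm, perm])
})

test_that("UPGMA reproduces the hand-executed merge sequence", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(d)
  expect_equal(to_newick(tree), "((A:1,B:1):1,C:2);")
  d2 <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  expect_equal(to_newick(upgma(d2)), "(A:1,B:1);")
  expect_error(upgma(matrix(c(0, NA, NA, 0), 2, 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "NaN/NA")
})

test_that("UPGMA trees are ultrametric and fix ultrametric inputs", {
  gm <- random_panel(12, 20, seed = 5)
  dm <- distance_matrix(gm)
  tree <- upgma(dm)
  coph <- cophenetic_distances(tree)
  # every leaf at height 0, root-to-leaf distance constant
  check_heights <- function(node) {
    if (!is.null(node$label)) return(invisible(NULL))
    for (k in node$children) {
      expect_true(node$height >= k$height - 1e-9)
      check_heights(k)
    }
  }
  check_heights(tree)
  # cophenetic matrix satisfies the ultrametric three-point condition
  l <- coph$labels
  for (rep in 1:50) {
    ijk <- sample(length(l), 3)
    dd <- sort(c(coph$d[ijk[1], ijk[2]], coph$d[ijk[1], ijk[3]],
                 coph$d[ijk[2], ijk[3]]))
    expect_lte(dd[3], dd[2] + 1e-9)
  }
  # reapplying UPGMA to an ultrametric matrix reproduces it exactly
  tree2 <- upgma(coph)
  coph2 <- cophenetic_distances(tree2)
  expect_equal(coph2$d[l, l], coph$d[l, l], tolerance = 1e-12)
})

test_that("Newick output parses back and quotes awkward labels", {
  skip_if_not_installed("ape")
  gm <- random_panel(9, 15, seed = 11)
  tree <- upgma(distance_matrix(gm))
  ph <- ape::read.tree(text = to_newick(tree))
  expect_setequal(ph$tip.label, gm$accession_ids)
  # branch lengths are serialized at 6 significant digits
  expect_true(ape::is.ultrametric(ph, tol = 1e-5))
  coph <- cophenetic_distances(tree)
  apec <- ape::cophenetic.phylo(ph)[coph$labels, coph$labels]
  expect_equal(unname(apec), unname(coph$d), tolerance = 1e-4)
  # labels with spaces are quoted
  d <- matrix(c(0, 2, 2, 0), 2, 2,
              dimnames = list(c("taxon one", "B"), c("taxon one", "B")))
  expect_match(to_newick(upgma(d)), "'taxon one':1")
})
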