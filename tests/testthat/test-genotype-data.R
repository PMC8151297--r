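test_that("genotype tables parse, normalize and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tm1\tm2",
               "s1\tA/A\tG/G",
               "s2\tA/G\t-/-"), path)
  gm <- suppressMessages(read_genotype_table(path))
  expect_equal(dim(gm), c(2L, 2L))
  expect_equal(unname(gm$calls["s2", "m1"]), "A/G")
  expect_true(is.na(gm$calls["s2", "m2"]))
  expect_equal(sum(gm$calls == "A/G", na.rm = TRUE), 1L)

  # unordered-pair symmetry: G/A reads identically to A/G
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tm1\tm2",
               "s1\tA/A\tG/G",
               "s2\tG/a\t-/-"), path2)
  gm2 <- suppressMessages(read_genotype_table(path2))
  expect_identical(gm$calls, gm2$calls)

  # 41 x 70 synthetic fixture: read . write . read is the identity
  big <- simulate_panel(sim_config(seed = 99, missing_rate = 0.05))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(big, p3)
  back <- suppressMessages(read_genotype_table(p3))
  expect_identical(back$calls, big$calls)
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(back, p4)
  expect_identical(readLines(p3), readLines(p4))
})

test_that("malformed genotype input is rejected with named cells", {
  calls <- matrix("A/A", 2, 1, dimnames = list(c("x", "x"), "m"))
  expect_error(genotype_matrix(calls), "duplicate accession")
  calls <- matrix(c("A/A", "A/-"), 2, 1,
                  dimnames = list(c("x", "y"), "m"))
  expect_error(genotype_matrix(calls), "half-missing.*y @ m")
  calls[2, 1] <- "A/Z"
  expect_error(genotype_matrix(calls), "non-nucleotide")
  calls[2, 1] <- "AG"
  expect_error(genotype_matrix(calls), "malformed")
})

test_that("normalization is idempotent and order-insensitive", {
  cases <- c("g/a", " T/C ", "A/A", "-/-")
  for (x in cases) {
    once <- normalize_call(x)
    expect_identical(normalize_call(if (is.na(once)) "-/-" else once), once)
  }
  expect_identical(normalize_call("G/A"), normalize_call("A/G"))
})

test_that("packaged marker panel loads with recomputed substitution classes", {
  defs <- load_marker_panel()
  expect_equal(nrow(defs), 70L)
  tab <- table(defs$substitution_class)
  expect_equal(unname(tab[["transition"]]), 44L)
  expect_equal(unname(tab[["transversion"]]), 26L)
  row <- defs[defs$marker_id == "AB-gCAPS-005", ]
  expect_equal(row$ref, "G")
  expect_equal(row$alt, "A")
  expect_equal(row$enzyme, "BsaBI")
  expect_equal(row$temp_c, 60)
})

test_that("marker table rejects inconsistent rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker_id\tsubstitution\tref\talt\tenzyme",
               "M1\tTransition\tG\tG\tFoo"), path)
  expect_error(read_marker_table(path), "not a substitution")
  writeLines(c("marker_id\tsubstitution\tref\talt\tenzyme",
               "M1\tTransversion\tG\tA\tFoo"), path)
  expect_error(read_marker_table(path), "conflicts.*M1")
})

test_that("validate_against_markers reports off-panel alleles and missingness", {
  defs <- data.frame(marker_id = c("m1", "m2"), ref = c("G", "C"),
                     alt = c("A", "T"), stringsAsFactors = FALSE)
  gm <- make_gm(m1 = c("A/G", "G/G", "C/C"), m2 = c("C/T", NA, "T/T"))
  rep <- validate_against_markers(gm, defs)
  expect_equal(nrow(rep$violations), 1L)
  expect_equal(rep$violations$accession, "acc03")
  expect_equal(rep$violations$marker, "m1")
  expect_equal(rep$missingness, 1 / 6)
  expect_error(validate_against_markers(
    make_gm(mX = c("A/A", "A/A")), defs), "absent")

  # consistency by construction: simulated matrix vs its own definitions
  freqs <- simulate_allele_frequencies(sim_config(seed = 7))
  gm2 <- simulate_genotypes(sim_config(seed = 7), freqs)
  defs2 <- data.frame(marker_id = freqs$marker_ids, ref = freqs$ref,
                      alt = freqs$alt, stringsAsFactors = FALSE)
  expect_equal(nrow(validate_against_markers(gm2, defs2)$violations), 0L)

  # injected missingness is counted exactly
  cfg <- sim_config(seed = 13, missing_rate = 0.05)
  gm3 <- simulate_panel(cfg)
  rep3 <- validate_against_markers(
    gm3, data.frame(marker_id = gm3$marker_ids, ref = "A", alt = "C"))
  expect_equal(sum(rep3$per_marker$n_missing), sum(is.na(gm3$calls)))
  expect_equal(rep3$missingness, mean(is.na(gm3$calls)))
})
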