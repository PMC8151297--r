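test_that("substitution classification matches purine/pyrimidine rule", {
  expect_equal(classify_substitution("G", "A"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_error(classify_substitution("A", "A"), "not a substitution")
  expect_error(classify_substitution("A", "N"), "nucleotide")
  # exactly 4 of the 12 ordered pairs are transitions; symmetric
  pairs <- expand.grid(r = c("A", "C", "G", "T"), a = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$r != pairs$a, ]
  cls <- mapply(classify_substitution, pairs$r, pairs$a)
  expect_equal(sum(cls == "transition"), 4L)
  swapped <- mapply(classify_substitution, pairs$a, pairs$r)
  expect_identical(unname(cls), unname(swapped))
})

test_that("recognition-site scanning handles IUPAC, strands and overlaps", {
  hinfi <- restriction_enzyme("HinfI", "GANTC", 1)
  expect_equal(as.integer(find_recognition_sites("AAGAATCAA", hinfi)), 2L)
  # palindromic motif reported once per coordinate
  haeiii <- restriction_enzyme("HaeIII", "GGCC", 2)
  expect_equal(as.integer(find_recognition_sites("TTGGCCTT", haeiii)), 2L)
  expect_length(find_recognition_sites("TTTTTTTT", haeiii), 0L)
  # overlapping matches all reported
  tgca <- restriction_enzyme("HpyCH4V", "TGCA", 2)
  expect_equal(as.integer(find_recognition_sites("ATGCATGCAT", tgca)),
               c(1L, 5L))
  # non-palindromic: bottom-strand site found at forward coordinate
  bcci <- restriction_enzyme("toy", "CCATC", 2)
  expect_equal(as.integer(find_recognition_sites("AAGATGGAA", bcci)), 2L)
})

test_that("digestion partitions the sequence", {
  enz <- restriction_enzyme("toy", "GAATTC", 1)
  s100 <- paste0(strrep("A", 39), "GAATTC", strrep("C", 55))
  fp <- digest_amplicon(s100, enz)
  expect_equal(fp$lengths, c(40L, 60L))
  expect_equal(digest_amplicon(strrep("A", 100), enz)$lengths, 100L)
  s2 <- paste0(strrep("A", 19), "GAATTC", strrep("A", 44), "GAATTC",
               strrep("C", 25))
  expect_equal(digest_amplicon(s2, enz)$lengths, sort(c(20L, 50L, 30L)))
})

test_that("fragment lengths always sum to input length", {
  enzymes <- read_enzyme_table()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(60:400, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                 collapse = "")
    enz <- enzymes[[sample(length(enzymes), 1)]]
    fp <- suppressWarnings(digest_amplicon(seq, enz))
    expect_equal(sum(fp$lengths), n)
  }
})

test_that("palindromic-motif digestion is reverse-complement invariant", {
  haeiii <- restriction_enzyme("HaeIII", "GGCC", 2)
  set.seed(7)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                 collapse = "")
    expect_equal(digest_amplicon(seq, haeiii)$lengths,
                 digest_amplicon(reverse_complement(seq), haeiii)$lengths)
  }
})

test_that("CAPS assessment detects site-destroying SNPs", {
  enz <- restriction_enzyme("toy", "GAATTC", 1)
  # SNP at the first motif base: ref G completes the site, alt T breaks it
  seqs <- paste0(strrep("A", 39), "GAATTC", strrep("C", 55))
  amp <- amplicon(seqs, 39, "G", "T")
  ass <- assess_caps_marker(amp, enz)
  expect_equal(ass$ref_pattern$lengths, c(40L, 60L))
  expect_equal(ass$alt_pattern$lengths, 100L)
  expect_true(ass$differential)
  expect_equal(ass$min_length_delta, 20L)

  # SNP far from any site: identical patterns
  amp2 <- amplicon(seqs, 0, "A", "C")
  expect_false(assess_caps_marker(amp2, enz)$differential)

  # SNP under a degenerate motif position: both alleles still match
  hinfi <- restriction_enzyme("HinfI", "GANTC", 1)
  seq3 <- paste0(strrep("T", 10), "GAATC", strrep("T", 10))
  amp3 <- amplicon(seq3, 12, "A", "C")  # the N position
  expect_false(assess_caps_marker(amp3, hinfi)$differential)
})

test_that("genotypes are called from band patterns", {
  enz <- restriction_enzyme("toy", "GAATTC", 1)
  amp <- amplicon(paste0(strrep("A", 39), "GAATTC", strrep("C", 55)),
                  39, "G", "T")
  ass <- assess_caps_marker(amp, enz)
  expect_equal(call_genotype_from_fragments(c(100), ass)$call, "T/T")
  expect_equal(call_genotype_from_fragments(c(40, 60), ass)$call, "G/G")
  expect_equal(call_genotype_from_fragments(c(100, 40, 60), ass)$call,
               "G/T")
  bad <- call_genotype_from_fragments(c(55, 45), ass)
  expect_true(is.na(bad$call))
  expect_match(bad$diagnostic, "unexplained")
  amp2 <- amplicon(strrep("A", 50), 0, "A", "C")
  ass2 <- assess_caps_marker(amp2, enz)
  expect_error(call_genotype_from_fragments(c(50), ass2),
               "non-differential")
})

test_that("FASTA round trip preserves amplicon sequences", {
  seqs <- c(m1 = strrep("ACGT", 30), m2 = paste0(strrep("A", 10), "GGCC"))
  path <- withr::local_tempfile(fileext = ".fa")
  write_amplicon_fasta(seqs, path)
  expect_identical(read_amplicon_fasta(path), seqs)
})
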