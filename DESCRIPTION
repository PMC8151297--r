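Package: capspop
Title: CAPS Marker Genotyping and Population Genetics for Germplasm Panels
Version: 1.0.0
Authors@R: person("Maintainer", "capspop", email = "capspop@example.org",
    role = c("aut", "cre"))
Description: In-silico CAPS (cleaved amplified polymorphic sequence) assay
    evaluation and a complete codominant population-genetics workflow for
    small germplasm collections: restriction-site scanning and fragment
    prediction, per-locus diversity statistics (major allele frequency,
    genotype and allele counts, gene diversity, observed heterozygosity),
    cross-marker-type diversity rescaling, Nei standard genetic distance with
    UPGMA clustering and Newick export, principal coordinates analysis,
    three-level codominant AMOVA with permutation tests, Bayesian
    admixture-model clustering with Evanno delta-K model choice, genotype
    accumulation curves and greedy minimum-marker-set selection, plus a
    seeded generator of synthetic genotype panels with known population
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
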