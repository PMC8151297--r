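#' Configuration for synthetic genotype panels
#'
#' Describes a panel of diploid accessions drawn from K diverged
#' populations (Balding-Nichols model) plus an admixed tail. Defaults mirror
#' a small cultivated-mushroom germplasm collection: 41 accessions (two core
#' populations of 17 plus 7 admixed), 70 biallelic loci of which 6 are
#' monomorphic, among-population differentiation F_ST = 0.15, and a
#' homozygote-excess parameter tuned so mean observed heterozygosity lands
#' near 0.26 (heterokaryotic cultivars are far from Hardy-Weinberg).
#'
#' @param sizes integer vector of core population sizes (each >= 2).
#' @param n_admixed accessions drawing each allele copy from a two-population
#'   mixture with individual-specific weights uniform on the simplex.
#' @param n_loci number of biallelic loci.
#' @param monomorphic_fraction fraction of loci fixed in every population.
#' @param target_fst Balding-Nichols F in `[0, 1)`.
#' @param ancestral_range range of the uniform ancestral allele frequency.
#' @param f_excess homozygote excess: heterozygote probability is
#'   `2pq(1 - f_excess)`.
#' @param missing_rate fraction of calls set to missing.
#' @param seed RNG seed (mandatory; every downstream draw derives from it).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sizes = c(17L, 17L), n_admixed = 7L, n_loci = 70L,
                       monomorphic_fraction = 6 / 70, target_fst = 0.15,
                       ancestral_range = c(0.1, 0.9), f_excess = 0.15,
                       missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(sizes >= 2L), n_admixed >= 0L, n_loci >= 1L,
            monomorphic_fraction >= 0, monomorphic_fraction <= 1,
            target_fst >= 0, target_fst < 1,
            missing_rate >= 0, missing_rate <= 1,
            f_excess >= 0, f_excess <= 1)
  structure(list(sizes = as.integer(sizes), n_admixed = as.integer(n_admixed),
                 n_loci = as.integer(n_loci),
                 monomorphic_fraction = monomorphic_fraction,
                 target_fst = target_fst, ancestral_range = ancestral_range,
                 f_excess = f_excess, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

TS_PAIRS <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"), ncol = 2,
                   byrow = TRUE)
TV_PAIRS <- matrix(c("A", "C", "A", "T", "C", "A", "C", "G", "G", "C",
                     "G", "T", "T", "A", "T", "G"), ncol = 2, byrow = TRUE)

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral ref-allele frequencies are uniform on the configured range;
#' each population's frequency is then Beta(p(1-F)/F, (1-p)(1-F)/F), which
#' has mean p and variance p(1-p)F. F = 0 short-circuits to the ancestral
#' value. A configured fraction of loci is forced monomorphic (ref frequency
#' 1 everywhere). Each locus also receives ref/alt nucleotide symbols, drawn
#' as transitions with probability 44/70 to mimic the empirical Ts/Tv mix of
#' SNP panels.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_freqs`: `p_anc`, `pop_freqs` (populations x
#'   loci, ref-allele frequency), `monomorphic` (logical), `ref`, `alt`
#'   (nucleotide per locus), `marker_ids`.
#' @export
simulate_allele_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$n_loci
  K <- length(cfg$sizes)
  p_anc <- runif(L, cfg$ancestral_range[1], cfg$ancestral_range[2])
  n_mono <- round(cfg$monomorphic_fraction * L)
  mono <- rep(FALSE, L)
  if (n_mono > 0) mono[sample.int(L, n_mono)] <- TRUE
  F <- cfg$target_fst
  pop_freqs <- matrix(NA_real_, K, L)
  for (k in seq_len(K)) {
    pop_freqs[k, ] <- if (F == 0) p_anc else
      rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  pop_freqs[, mono] <- 1
  p_anc[mono] <- 1
  is_ts <- runif(L) < 44 / 70
  pick <- function(pairs) pairs[sample.int(nrow(pairs), 1), ]
  ra <- t(vapply(is_ts, function(ts) pick(if (ts) TS_PAIRS else TV_PAIRS),
                 character(2)))
  structure(list(p_anc = p_anc, pop_freqs = pop_freqs, monomorphic = mono,
                 ref = ra[, 1], alt = ra[, 2],
                 marker_ids = sprintf("SYN-CAPS-%03d", seq_len(L))),
            class = "sim_freqs")
}

#' Simulate a diploid genotype matrix
#'
#' Core-population individuals draw genotypes from their population's
#' frequencies with heterozygote probability `2pq(1 - f_excess)` (the excess
#' homozygosity going to the two homozygote classes in proportion p:q of
#' pq each). Admixed individuals pick two source populations and a uniform
#' mixture weight, then draw each allele copy independently through the
#' mixture. Missing calls are injected completely at random.
#'
#' @param cfg a [sim_config()].
#' @param freqs result of [simulate_allele_frequencies()].
#' @return a [genotype_matrix()] with population labels (`Pop1`, `Pop2`,
#'   ..., `Admix`) and attribute `truth` (the `freqs` object plus admixture
#'   weights).
#' @export
simulate_genotypes <- function(cfg, freqs) {
  set.seed(cfg$seed + 1L)
  K <- length(cfg$sizes)
  N <- sum(cfg$sizes) + cfg$n_admixed
  L <- cfg$n_loci
  pop_of <- c(rep(seq_len(K), cfg$sizes), rep(NA_integer_, cfg$n_admixed))
  labels <- c(rep(paste0("Pop", seq_len(K)), cfg$sizes),
              rep("Admix", cfg$n_admixed))
  calls <- matrix(NA_character_, N, L)
  admix_w <- NULL
  f <- cfg$f_excess
  lo <- pmin(freqs$ref, freqs$alt)
  hi <- pmax(freqs$ref, freqs$alt)
  hom_ref <- matrix(paste(freqs$ref, freqs$ref, sep = "/"), N, L,
                    byrow = TRUE)
  het <- matrix(paste(lo, hi, sep = "/"), N, L, byrow = TRUE)
  hom_alt <- matrix(paste(freqs$alt, freqs$alt, sep = "/"), N, L,
                    byrow = TRUE)
  core <- which(!is.na(pop_of))
  if (length(core)) {
    p <- freqs$pop_freqs[pop_of[core], , drop = FALSE]
    q <- 1 - p
    # genotype classes: hom-ref, het, hom-alt with homozygote excess f
    pr_hom_ref <- p^2 + p * q * f
    pr_het <- 2 * p * q * (1 - f)
    u <- matrix(runif(length(core) * L), length(core), L)
    g <- 1L + (u >= pr_hom_ref) + (u >= pr_hom_ref + pr_het)
    calls[core, ] <- ifelse(g == 1L, hom_ref[core, ],
                            ifelse(g == 2L, het[core, ], hom_alt[core, ]))
  }
  for (i in which(is.na(pop_of))) {
    src <- if (K >= 2) sample.int(K, 2L) else c(1L, 1L)
    w <- runif(1)
    admix_w <- rbind(admix_w, c(i, src, w))
    copy <- vapply(1:2, function(a) {
      k <- src[ifelse(runif(L) < w, 1L, 2L)]
      p_l <- freqs$pop_freqs[cbind(k, seq_len(L))]
      ifelse(runif(L) < p_l, freqs$ref, freqs$alt)
    }, character(L))
    calls[i, ] <- paste(pmin(copy[, 1], copy[, 2]),
                        pmax(copy[, 1], copy[, 2]), sep = "/")
  }
  if (cfg$missing_rate > 0) {
    calls[runif(length(calls)) < cfg$missing_rate] <- NA_character_
  }
  dimnames(calls) <- list(sprintf("ACC%03d", seq_len(N)), freqs$marker_ids)
  gm <- new_genotype_matrix(calls, populations = labels)
  attr(gm, "truth") <- list(freqs = freqs, admix_weights = admix_w)
  gm
}

#' Simulate a full panel in one call
#'
#' Convenience wrapper chaining [simulate_allele_frequencies()] and
#' [simulate_genotypes()].
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_panel <- function(cfg) {
  simulate_genotypes(cfg, simulate_allele_frequencies(cfg))
}

#' Simulate amplicons and enzyme assignments for a CAPS panel
#'
#' For each locus, constructs a random amplicon in which the reference
#' allele completes a recognition site overlapping the SNP while the
#' alternative allele breaks it, guaranteeing a differential (gel-scorable)
#' assay. Each generated marker is verified with [assess_caps_marker()];
#' construction retries with fresh randomness and other enzymes until the
#' assay is differential AND gel-scorable (ref, alt and heterozygote band
#' sets pairwise distinct — a lost cut can otherwise merge fragments into
#' a band that comigrates with an existing one, making the heterozygote
#' set collapse onto a homozygote's).
#'
#' @param freqs a [simulate_allele_frequencies()] result (supplies ref/alt
#'   alleles and marker ids).
#' @param enzymes named list from [read_enzyme_table()]; defaults to the
#'   packaged table (outside cutters are excluded from the draw to keep cut
#'   sites inside short amplicons).
#' @param amp_len_range amplicon length bounds (bp).
#' @param seed RNG seed.
#' @return list of class `caps_panel`: `amplicons` (list of [amplicon()]),
#'   `assessments`, `enzymes_used`, `marker_ids`.
#' @export
simulate_caps_panel <- function(freqs, enzymes = read_enzyme_table(),
                                amp_len_range = c(150L, 400L), seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  inside <- Filter(function(e) !e$outside, enzymes)
  L <- length(freqs$ref)
  amps <- vector("list", L)
  assessments <- vector("list", L)
  used <- character(L)
  for (l in seq_len(L)) {
    ref <- freqs$ref[l]; alt <- freqs$alt[l]
    done <- FALSE
    for (attempt in seq_len(200L)) {
      enz <- inside[[sample.int(length(inside), 1L)]]
      motif_sets <- IUPAC_SETS[strsplit(enz$motif, "")[[1]]]
      # motif position that admits ref but rejects alt
      cand <- which(vapply(motif_sets, function(s)
        ref %in% s && !(alt %in% s), logical(1)))
      if (length(cand) == 0L) next
      j <- cand[sample.int(length(cand), 1L)]
      site <- vapply(motif_sets, function(s) s[sample.int(length(s), 1L)],
                     character(1))
      site[j] <- ref
      n <- sample(seq(amp_len_range[1], amp_len_range[2]), 1L)
      pos <- sample.int(n - length(site) - 2L, 1L) + 1L  # keep off the ends
      bg <- sample(NUCLEOTIDES, n, replace = TRUE)
      bg[seq(pos, pos + length(site) - 1L)] <- site
      amp <- amplicon(paste(bg, collapse = ""), pos + j - 2L, ref, alt)
      ass <- assess_caps_marker(amp, enz)
      # gel-scorable: the three expected band sets must be pairwise
      # distinct (comigrating bands can make a het look like a homozygote)
      rb <- expected_bands(ass, "ref")
      ab <- expected_bands(ass, "alt")
      hb <- expected_bands(ass, "het")
      if (ass$differential && !identical(rb, hb) && !identical(ab, hb)) {
        amps[[l]] <- amp
        assessments[[l]] <- ass
        used[l] <- enz$name
        done <- TRUE
        break
      }
    }
    if (!done) stop("could not place a differential site for locus ", l)
  }
  names(amps) <- names(assessments) <- freqs$marker_ids
  structure(list(amplicons = amps, assessments = assessments,
                 enzymes_used = used, marker_ids = freqs$marker_ids),
            class = "caps_panel")
}

#' Re-call genotypes from rendered fragment patterns
#'
#' End-to-end round trip: for every accession x locus, renders the gel band
#' pattern its true genotype would produce under the panel's assessments and
#' re-calls the genotype from those bands. With fully differential assays
#' the result reproduces the input matrix exactly.
#'
#' @param gm a [genotype_matrix()] whose alleles match `panel`.
#' @param panel a [simulate_caps_panel()] result.
#' @return a [genotype_matrix()] of re-called genotypes.
#' @export
recall_genotypes <- function(gm, panel) {
  idx <- match(gm$marker_ids, panel$marker_ids)
  if (anyNA(idx)) stop("marker ids not covered by panel")
  out <- gm$calls
  for (j in seq_along(gm$marker_ids)) {
    ass <- panel$assessments[[idx[j]]]
    ref_call <- normalize_call(paste(ass$ref_allele, ass$ref_allele,
                                     sep = "/"))
    alt_call <- normalize_call(paste(ass$alt_allele, ass$alt_allele,
                                     sep = "/"))
    for (i in seq_along(gm$accession_ids)) {
      cell <- gm$calls[i, j]
      if (is.na(cell)) { out[i, j] <- NA_character_; next }
      kind <- if (cell == ref_call) "ref" else if (cell == alt_call) "alt"
        else "het"
      bands <- expected_bands(ass, kind)
      out[i, j] <- call_genotype_from_fragments(bands, ass)$call
    }
  }
  genotype_matrix(out, populations = gm$populations)
}
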