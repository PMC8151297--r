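#' Classify a nucleotide substitution as transition or transversion
#'
#' Transitions exchange purines (A<->G) or pyrimidines (C<->T); transversions
#' cross the purine/pyrimidine divide. Of the 12 ordered nucleotide pairs,
#' exactly 4 are transitions.
#'
#' @param ref,alt single nucleotides in `A/C/G/T`; must differ.
#' @return `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("G", "A")  # transition
#' classify_substitution("C", "A")  # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!(ref %in% NUCLEOTIDES) || !(alt %in% NUCLEOTIDES)) {
    stop("ref and alt must be nucleotides (A/C/G/T), got '", ref, "', '",
         alt, "'")
  }
  if (ref == alt) stop("ref == alt ('", ref, "'): not a substitution")
  purines <- c("A", "G")
  if ((ref %in% purines) == (alt %in% purines)) "transition" else "transversion"
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_to_regex <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) stop("non-IUPAC symbol in motif: ", bad[1])
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' Reverse complement of a DNA string (IUPAC-aware)
#' @param seq DNA string.
#' @return reverse complement string.
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Define a restriction enzyme
#'
#' @param name enzyme label (e.g. `"HinfI"`).
#' @param motif IUPAC recognition motif on the top strand.
#' @param cut_offset 0-based cut position relative to motif start on the top
#'   strand; must lie within `[0, nchar(motif)]` unless `outside = TRUE`
#'   (outside cutters such as BtsCI cut downstream of the motif).
#' @param outside logical; enzyme cuts outside its recognition site.
#' @return object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, motif, cut_offset, outside = FALSE) {
  motif <- toupper(motif)
  if (!nzchar(motif)) stop("empty motif")
  iupac_to_regex(motif)  # validates alphabet
  cut_offset <- as.integer(cut_offset)
  if (!outside && (cut_offset < 0L || cut_offset > nchar(motif))) {
    stop(name, ": cut_offset ", cut_offset,
         " outside [0, motif length] for a within-site cutter")
  }
  structure(list(name = name, motif = motif, cut_offset = cut_offset,
                 outside = isTRUE(outside)),
            class = "restriction_enzyme")
}

#' Read a restriction-enzyme table
#'
#' Tab-separated columns: `name`, `motif` (IUPAC), `cut_offset` (0-based from
#' motif start, top strand), `outside` (0/1). The packaged table covers the
#' 38 commercial enzymes used by the shipped CAPS marker panel; motifs follow
#' the REBASE prototype definitions and the table is plain text so users can
#' extend it.
#'
#' @param path file path; defaults to the packaged table.
#' @return named list of [restriction_enzyme()] objects.
#' @export
read_enzyme_table <- function(path = system.file("extdata", "enzymes.tsv",
                                                 package = "capspop")) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "character", "integer",
                                  "integer"))
  enz <- lapply(seq_len(nrow(df)), function(i) {
    restriction_enzyme(df$name[i], df$motif[i], df$cut_offset[i],
                       outside = df$outside[i] == 1L)
  })
  names(enz) <- df$name
  enz
}

#' Find restriction recognition sites
#'
#' Scans both strands: positions where the motif matches the forward strand,
#' and positions where the reverse complement of the motif matches (i.e. the
#' motif occurs on the bottom strand), all reported as 0-based forward-strand
#' coordinates of the match start. Overlapping matches are all reported;
#' palindromic motifs yield each coordinate once.
#'
#' @param seq DNA string over A/C/G/T.
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer vector of 0-based match start positions, with a
#'   logical attribute `"reverse"` marking bottom-strand-only matches.
#' @examples
#' find_recognition_sites("AAGAATCAA", restriction_enzyme("HinfI", "GANTC", 1))
#' @export
find_recognition_sites <- function(seq, enzyme) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence must be over A/C/G/T")
  fwd <- overlap_matches(seq, iupac_to_regex(enzyme$motif))
  rcm <- reverse_complement(enzyme$motif)
  rev <- if (rcm == enzyme$motif) integer(0) else
    overlap_matches(seq, iupac_to_regex(rcm))
  rev_only <- setdiff(rev, fwd)
  pos <- sort(c(fwd, rev_only))
  attr(pos, "reverse") <- pos %in% rev_only
  pos
}

overlap_matches <- function(seq, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Digest an amplicon sequence in silico
#'
#' Cuts a linear sequence at each recognition site's cut position. For a
#' forward-strand site at position `p` the top strand is cut at
#' `p + cut_offset`; for a bottom-strand site the cut is mirrored to
#' `p + motif length - cut_offset`. Cut positions falling outside the
#' sequence (an outside cutter near an end) are skipped and recorded.
#'
#' @param seq DNA string.
#' @param enzyme a [restriction_enzyme()].
#' @return object of class `fragment_pattern`: list with sorted integer
#'   `lengths` (multiset of fragment sizes in bp, summing to `nchar(seq)`)
#'   and `skipped` (count of out-of-range cut sites).
#' @export
digest_amplicon <- function(seq, enzyme) {
  seq <- toupper(seq)
  n <- nchar(seq)
  pos <- find_recognition_sites(seq, enzyme)
  revm <- attr(pos, "reverse")
  cuts <- ifelse(revm, pos + nchar(enzyme$motif) - enzyme$cut_offset,
                 pos + enzyme$cut_offset)
  ok <- cuts > 0L & cuts < n
  skipped <- sum(!ok)
  if (skipped > 0L && enzyme$outside) {
    warning(enzyme$name, ": ", skipped,
            " cut position(s) outside the sequence were skipped")
  }
  cuts <- sort(unique(cuts[ok]))
  lens <- diff(c(0L, cuts, n))
  fragment_pattern(lens, skipped = skipped)
}

fragment_pattern <- function(lengths, skipped = 0L) {
  lengths <- sort(as.integer(lengths))
  if (length(lengths) < 1L || any(lengths <= 0L)) {
    stop("fragment pattern needs >=1 positive length")
  }
  structure(list(lengths = lengths, skipped = skipped),
            class = "fragment_pattern")
}

#' Define an amplicon carrying one SNP
#'
#' @param sequence reference-allele amplicon sequence.
#' @param snp_offset 0-based index of the SNP in `sequence`.
#' @param ref_allele,alt_allele the two SNP alleles;
#'   `substr(sequence, snp_offset+1, snp_offset+1)` must equal `ref_allele`.
#' @return object of class `amplicon`.
#' @export
amplicon <- function(sequence, snp_offset, ref_allele, alt_allele) {
  sequence <- toupper(sequence)
  snp_offset <- as.integer(snp_offset)
  if (snp_offset < 0L || snp_offset >= nchar(sequence)) {
    stop("snp_offset outside sequence")
  }
  classify_substitution(ref_allele, alt_allele)  # validates both
  if (substr(sequence, snp_offset + 1L, snp_offset + 1L) != ref_allele) {
    stop("sequence[snp_offset] != ref_allele")
  }
  structure(list(sequence = sequence, snp_offset = snp_offset,
                 ref_allele = toupper(ref_allele),
                 alt_allele = toupper(alt_allele)),
            class = "amplicon")
}

substitute_allele <- function(amp, allele) {
  s <- amp$sequence
  substr(s, amp$snp_offset + 1L, amp$snp_offset + 1L) <- allele
  s
}

#' Assess whether a CAPS assay is differential
#'
#' Digests the amplicon under each allele and compares the fragment patterns.
#' A marker is usable (differential) when the two multisets of fragment
#' lengths differ, i.e. the SNP creates or destroys a recognition site. The
#' minimum pairwise difference between distinct band lengths across both
#' patterns is reported as a gel-resolvability proxy.
#'
#' @param amp an [amplicon()].
#' @param enzyme a [restriction_enzyme()].
#' @return list with `ref_pattern`, `alt_pattern` ([digest_amplicon()]
#'   results), `differential` flag, `min_length_delta` (NA when all bands
#'   comigrate), and the enzyme / alleles used.
#' @export
assess_caps_marker <- function(amp, enzyme) {
  ref_pat <- digest_amplicon(substitute_allele(amp, amp$ref_allele), enzyme)
  alt_pat <- digest_amplicon(substitute_allele(amp, amp$alt_allele), enzyme)
  union_lens <- sort(unique(c(ref_pat$lengths, alt_pat$lengths)))
  delta <- if (length(union_lens) > 1L) min(diff(union_lens)) else NA_integer_
  list(ref_pattern = ref_pat, alt_pattern = alt_pat,
       differential = !identical(ref_pat$lengths, alt_pat$lengths),
       min_length_delta = delta, enzyme = enzyme,
       ref_allele = amp$ref_allele, alt_allele = amp$alt_allele)
}

band_set <- function(lengths) sort(unique(as.integer(lengths)))

#' Expected gel band set for a genotype
#'
#' Heterozygotes show the union of both allele patterns; comigrating bands
#' (equal lengths) collapse, since a gel cannot resolve dosage.
#'
#' @param assessment result of [assess_caps_marker()].
#' @param genotype `"ref"`, `"alt"`, or `"het"`.
#' @return sorted vector of distinct band lengths.
#' @export
expected_bands <- function(assessment, genotype = c("ref", "alt", "het")) {
  genotype <- match.arg(genotype)
  switch(genotype,
         ref = band_set(assessment$ref_pattern$lengths),
         alt = band_set(assessment$alt_pattern$lengths),
         het = band_set(c(assessment$ref_pattern$lengths,
                          assessment$alt_pattern$lengths)))
}

#' Call a genotype from an observed fragment pattern
#'
#' Compares the observed band set against the expected ref-homozygote,
#' alt-homozygote and heterozygote band sets. An observation matching none,
#' or matching ambiguously (possible when allele patterns comigrate), yields
#' a missing call with a diagnostic.
#'
#' @param observed a [digest_amplicon()] result or a numeric vector of band
#'   lengths.
#' @param assessment a differential [assess_caps_marker()] result.
#' @return list with `call` (`"X/Y"` or `NA`) and `diagnostic`.
#' @export
call_genotype_from_fragments <- function(observed, assessment) {
  if (!assessment$differential) {
    stop("non-differential assessment: this enzyme/SNP pair cannot genotype")
  }
  obs <- band_set(if (inherits(observed, "fragment_pattern"))
    observed$lengths else observed)
  cand <- list(ref = expected_bands(assessment, "ref"),
               alt = expected_bands(assessment, "alt"),
               het = expected_bands(assessment, "het"))
  hits <- names(cand)[vapply(cand, function(b) identical(b, obs), logical(1))]
  a <- sort(c(assessment$ref_allele, assessment$alt_allele))
  if (length(hits) == 1L) {
    call <- switch(hits,
                   ref = paste(assessment$ref_allele,
                               assessment$ref_allele, sep = "/"),
                   alt = paste(assessment$alt_allele,
                               assessment$alt_allele, sep = "/"),
                   het = paste(a[1], a[2], sep = "/"))
    list(call = normalize_call(call), diagnostic = "ok")
  } else if (length(hits) == 0L) {
    list(call = NA_character_,
         diagnostic = paste0("unexplained band pattern {",
                             paste(obs, collapse = ","), "}"))
  } else {
    list(call = NA_character_,
         diagnostic = paste0("ambiguous pattern (matches ",
                             paste(hits, collapse = "+"), ")"))
  }
}

#' Read amplicon sequences from a FASTA file
#'
#' Record ids are taken as marker ids. A plain parser is used so amplicon
#' fixtures stay dependency-free; sequences may span multiple lines.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_amplicon_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), function(x)
    toupper(paste(x, collapse = "")), character(1))
  setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_amplicon_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
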