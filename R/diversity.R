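#' Allele frequency spectrum at a locus
#'
#' Each non-missing diploid call contributes two allele copies; missing calls
#' are excluded entirely.
#'
#' @param gm a [genotype_matrix()].
#' @param marker_id marker to summarize.
#' @return list with `marker_id`, `frequencies` (named proportions, sorted by
#'   decreasing frequency then allele symbol), and `n_copies`.
#' @export
allele_frequencies <- function(gm, marker_id) {
  j <- match(marker_id, gm$marker_ids)
  if (is.na(j)) stop("unknown marker: ", marker_id)
  col <- gm$calls[, j]
  alleles <- unlist(strsplit(col[!is.na(col)], "/", fixed = TRUE))
  if (length(alleles) == 0L) stop("all calls missing at ", marker_id)
  tb <- table(alleles)
  freq <- as.numeric(tb) / sum(tb)
  names(freq) <- names(tb)
  ord <- order(-freq, names(freq))
  list(marker_id = marker_id, frequencies = freq[ord],
       n_copies = length(alleles))
}

#' Per-locus diversity statistics
#'
#' Computes the five standard codominant marker statistics:
#' * `maf` — major allele frequency (ties at 0.5 report 0.5, the major
#'   allele being the lexicographically first);
#' * `ng` — number of distinct unordered genotype classes observed;
#' * `na` — number of distinct alleles observed;
#' * `gd` — gene diversity (expected heterozygosity)
#'   \eqn{GD = 1 - \sum_u p_u^2};
#' * `he` — observed heterozygosity, the proportion of heterozygous calls.
#'
#' @param gm a [genotype_matrix()].
#' @param marker_id marker name.
#' @return one-row data.frame with columns `marker_id, maf, ng, na, gd, he`.
#' @export
compute_locus_stats <- function(gm, marker_id) {
  afs <- allele_frequencies(gm, marker_id)
  p <- afs$frequencies
  col <- gm$calls[, match(marker_id, gm$marker_ids)]
  col <- col[!is.na(col)]
  parts <- strsplit(col, "/", fixed = TRUE)
  het <- vapply(parts, function(a) a[1] != a[2], logical(1))
  data.frame(marker_id = marker_id,
             maf = unname(p[1]),
             ng = length(unique(col)),
             na = length(p),
             gd = 1 - sum(p^2),
             he = mean(het),
             stringsAsFactors = FALSE)
}

#' Diversity statistics for every marker
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame, one row per marker (see [compute_locus_stats()]).
#' @export
locus_stats_table <- function(gm) {
  do.call(rbind, lapply(gm$marker_ids, function(m)
    compute_locus_stats(gm, m)))
}

#' Panel-level diversity summary
#'
#' Means of each statistic over all loci and over polymorphic loci only
#' (monomorphic = MAF 1), plus per-substitution-class gene-diversity means
#' when marker definitions are supplied.
#'
#' @param stats data.frame as returned by [locus_stats_table()] (or a
#'   published statistics table with the same columns).
#' @param defs optional marker definitions ([read_marker_table()]) used to
#'   stratify gene diversity by transition/transversion class.
#' @return list with `n_loci`, `n_polymorphic`, `n_monomorphic`,
#'   `mean_all`, `mean_polymorphic` (named vectors over maf/ng/na/gd/he),
#'   and optionally `gd_by_class`.
#' @export
summarize_panel <- function(stats, defs = NULL) {
  if (nrow(stats) == 0L) stop("empty statistics table")
  cols <- c("maf", "ng", "na", "gd", "he")
  poly <- stats$maf < 1
  out <- list(n_loci = nrow(stats),
              n_polymorphic = sum(poly),
              n_monomorphic = sum(!poly),
              mean_all = colMeans(stats[, cols]),
              mean_polymorphic = if (any(poly))
                colMeans(stats[poly, cols, drop = FALSE]) else
                  setNames(rep(NA_real_, length(cols)), cols))
  if (!is.null(defs)) {
    cls <- defs$substitution_class[match(stats$marker_id, defs$marker_id)]
    if (anyNA(cls)) {
      stop("marker(s) missing from definitions: ",
           paste(stats$marker_id[is.na(cls)], collapse = ", "))
    }
    out$gd_by_class <- tapply(stats$gd, cls, mean)
    out$n_by_class <- table(cls)
  }
  out
}

#' Rescale gene diversity by its theoretical maximum
#'
#' Marker systems with different allele counts are not directly comparable on
#' raw gene diversity: a k-allele locus tops out at \eqn{(k-1)/k} (all
#' alleles equifrequent). Dividing by that maximum puts marker types (e.g.
#' biallelic SNP/CAPS vs multiallelic SSR panels) on a common 0..1 scale.
#'
#' @param gd gene diversity value(s) in `[0, (k-1)/k]`.
#' @param max_alleles k, the maximum allele count of the marker system
#'   (k >= 2).
#' @return `gd / ((k-1)/k)`.
#' @examples
#' scaled_gene_diversity(0.3599, 3)  # ~0.540
#' @export
scaled_gene_diversity <- function(gd, max_alleles) {
  k <- as.integer(max_alleles)
  if (k < 2L) stop("max_alleles must be >= 2")
  gmax <- (k - 1) / k
  if (any(gd < 0 | gd > gmax + 1e-12)) {
    stop("gd outside [0, (k-1)/k] = [0, ", format(gmax), "]")
  }
  gd / gmax
}

#' Packaged diversity statistics of the published A. bisporus CAPS panel
#'
#' Transcription of the published per-locus diversity index table for the
#' 41-accession button-mushroom collection typed at 70 CAPS markers. Columns
#' match [locus_stats_table()].
#'
#' @return data.frame with 70 rows.
#' @export
load_panel_stats <- function() {
  path <- system.file("extdata", "table3_stats.tsv", package = "capspop")
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = c("character", rep("numeric", 5)))
  names(df) <- c("marker_id", "maf", "ng", "na", "gd", "he")
  df
}

#' Packaged marker definitions of the published A. bisporus CAPS panel
#'
#' Transcription of the published 70-marker CAPS panel: SNP alleles,
#' substitution class, restriction enzyme, incubation temperature, primers.
#'
#' @return data.frame of marker definitions (see [read_marker_table()]).
#' @export
load_marker_panel <- function() read_marker_table()
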