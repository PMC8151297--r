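#' Count distinct multilocus genotypes over a marker subset
#'
#' Accessions are grouped by exact equality of their call vectors restricted
#' to the subset; a missing call matches only another missing call
#' (conservative: missing data never create spurious discrimination).
#'
#' @param gm a [genotype_matrix()].
#' @param marker_subset marker ids (or indices).
#' @return number of distinct multilocus genotype (MLG) classes.
#' @export
distinct_mlg_count <- function(gm, marker_subset) {
  if (length(marker_subset) == 0L) stop("empty marker subset")
  if (is.character(marker_subset)) {
    idx <- match(marker_subset, gm$marker_ids)
    if (anyNA(idx)) stop("unknown marker id(s): ",
                         paste(marker_subset[is.na(idx)], collapse = ", "))
  } else idx <- marker_subset
  sub <- gm$calls[, idx, drop = FALSE]
  sub[is.na(sub)] <- "?"
  length(unique(apply(sub, 1, paste, collapse = "|")))
}

#' Genotype accumulation curve
#'
#' For each subset size n = 1..L-1, draws `r` random locus subsets (uniform,
#' without replacement within a subset) and records the number of distinct
#' multilocus genotypes each resolves — the standard check of how many
#' markers are needed to separate all accessions.
#'
#' @param gm a [genotype_matrix()] with >= 2 loci.
#' @param r random subsets per size.
#' @param seed RNG seed.
#' @return object of class `accumulation_curve`: `counts` (r x (L-1) matrix),
#'   `sizes`, `mean`, `q25`, `q75`, `full_panel_mlg`.
#' @export
accumulation_curve <- function(gm, r = 100, seed = NULL) {
  L <- length(gm$marker_ids)
  if (L < 2L) stop("need >= 2 loci")
  if (r < 1) stop("r must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sizes <- seq_len(L - 1L)
  counts <- matrix(NA_integer_, r, length(sizes),
                   dimnames = list(NULL, sizes))
  for (n in sizes) {
    for (b in seq_len(r)) {
      counts[b, n] <- distinct_mlg_count(gm, sample.int(L, n))
    }
  }
  structure(list(counts = counts, sizes = sizes,
                 mean = colMeans(counts),
                 q25 = apply(counts, 2, stats::quantile, 0.25),
                 q75 = apply(counts, 2, stats::quantile, 0.75),
                 full_panel_mlg = distinct_mlg_count(gm, gm$marker_ids)),
            class = "accumulation_curve")
}

#' Greedy minimum marker set selection
#'
#' The first marker is the polymorphic locus with the highest gene
#' diversity (ties broken by genotype-class count, then allele count, then
#' marker id); each subsequent marker is the one whose addition yields the
#' largest number of distinct multilocus genotypes (ties broken by gene
#' diversity, then marker id). Selection stops when every accession is
#' distinguished or no marker increases the count.
#'
#' @param gm a [genotype_matrix()].
#' @param stats optional precomputed [locus_stats_table()].
#' @param first_marker optionally pin the initial marker explicitly (the
#'   published pipeline's first-pick criterion is ambiguous, so users can
#'   override it).
#' @return object of class `selection_result`: `selected` (ordered ids),
#'   `step_counts` (distinct MLGs after each step, strictly increasing),
#'   `complete` (all accessions unique), `n_selected`, `n_accessions`.
#' @export
greedy_minimal_marker_set <- function(gm, stats = NULL, first_marker = NULL) {
  if (is.null(stats)) stats <- locus_stats_table(gm)
  stats <- stats[match(gm$marker_ids, stats$marker_id), ]
  n_acc <- length(gm$accession_ids)
  poly <- which(stats$maf < 1)
  if (length(poly) == 0L) {
    return(structure(list(selected = character(0), step_counts = integer(0),
                          complete = FALSE, n_selected = 0L,
                          n_accessions = n_acc), class = "selection_result"))
  }
  if (is.null(first_marker)) {
    ord <- poly[order(-stats$gd[poly], -stats$ng[poly], -stats$na[poly],
                      stats$marker_id[poly])]
    first <- stats$marker_id[ord[1]]
  } else {
    if (!first_marker %in% gm$marker_ids) stop("unknown first_marker")
    first <- first_marker
  }
  selected <- first
  counts <- distinct_mlg_count(gm, selected)
  remaining <- setdiff(gm$marker_ids[poly], selected)
  while (counts[length(counts)] < n_acc && length(remaining) > 0L) {
    cand <- vapply(remaining, function(m)
      distinct_mlg_count(gm, c(selected, m)), integer(1))
    best <- max(cand)
    if (best <= counts[length(counts)]) break
    tied <- remaining[cand == best]
    gd <- stats$gd[match(tied, stats$marker_id)]
    pick <- tied[order(-gd, tied)][1]
    selected <- c(selected, pick)
    counts <- c(counts, best)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(selected = selected, step_counts = counts,
                 complete = counts[length(counts)] == n_acc,
                 n_selected = length(selected), n_accessions = n_acc),
            class = "selection_result")
}

#' Exhaustive minimum marker set (oracle)
#'
#' Breadth-first enumeration over subset sizes: the smallest cardinality
#' achieving the full-panel MLG count, with the lexicographically first
#' witness. Exponential — restricted to small panels.
#'
#' @param gm a [genotype_matrix()].
#' @param max_loci refuse panels larger than this (default 15).
#' @return list with `size` and `witness` (marker ids).
#' @export
exhaustive_minimal_marker_set <- function(gm, max_loci = 15L) {
  L <- length(gm$marker_ids)
  if (L > max_loci) stop("panel too large for exhaustive search (L = ", L,
                         " > max_loci = ", max_loci, ")")
  target <- distinct_mlg_count(gm, gm$marker_ids)
  for (size in seq_len(L)) {
    subsets <- combn(L, size)
    for (s in seq_len(ncol(subsets))) {
      if (distinct_mlg_count(gm, subsets[, s]) == target) {
        return(list(size = size,
                    witness = gm$marker_ids[subsets[, s]]))
      }
    }
  }
  list(size = L, witness = gm$marker_ids)  # unreachable: size L always works
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selection_result: %d marker(s), %d/%d accessions resolved%s\n",
              x$n_selected,
              if (length(x$step_counts)) max(x$step_counts) else 1L,
              x$n_accessions, if (x$complete) " (complete)" else ""))
  if (x$n_selected) {
    cat("  ", paste(x$selected, collapse = ", "), "\n")
  }
  invisible(x)
}
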