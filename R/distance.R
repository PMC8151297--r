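#' Per-locus allele frequency profile of one diploid accession
#'
#' A homozygote contributes frequency 1 for its allele, a heterozygote 0.5
#' for each allele; missing loci are absent from the profile. These
#' within-individual frequencies let Nei's standard distance, defined on
#' population frequency profiles, be applied between single accessions.
#'
#' @param gm a [genotype_matrix()].
#' @param accession accession id.
#' @return named list (one element per non-missing locus) of named frequency
#'   vectors.
#' @export
individual_allele_profile <- function(gm, accession) {
  i <- match(accession, gm$accession_ids)
  if (is.na(i)) stop("unknown accession: ", accession)
  row <- gm$calls[i, ]
  prof <- lapply(row, function(cell) {
    if (is.na(cell)) return(NULL)
    a <- strsplit(cell, "/", fixed = TRUE)[[1]]
    if (a[1] == a[2]) setNames(1, a[1]) else setNames(c(0.5, 0.5), a)
  })
  names(prof) <- gm$marker_ids
  prof[!vapply(prof, is.null, logical(1))]
}

#' Nei's standard genetic distance between two frequency profiles
#'
#' \eqn{D = -\ln(J_{XY} / \sqrt{J_X J_Y})} where, over loci scored in both
#' profiles, \eqn{J_X} is the mean of \eqn{\sum_u x_{lu}^2}, \eqn{J_Y}
#' likewise, and \eqn{J_{XY}} the mean of \eqn{\sum_u x_{lu} y_{lu}}.
#' Loci missing in either profile are dropped (pairwise deletion). When the
#' profiles share no allele at any locus (\eqn{J_{XY} = 0}) the distance is
#' infinite and `Inf` is returned.
#'
#' @param x_profile,y_profile profiles from [individual_allele_profile()] (or
#'   any named lists of per-locus allele frequency vectors).
#' @return non-negative numeric distance (possibly `Inf`).
#' @export
nei_standard_distance <- function(x_profile, y_profile) {
  shared <- intersect(names(x_profile), names(y_profile))
  if (length(shared) == 0L) stop("no locus scored in both profiles")
  jx <- jy <- jxy <- numeric(length(shared))
  for (k in seq_along(shared)) {
    x <- x_profile[[shared[k]]]
    y <- y_profile[[shared[k]]]
    jx[k] <- sum(x^2)
    jy[k] <- sum(y^2)
    common <- intersect(names(x), names(y))
    jxy[k] <- sum(x[common] * y[common])
  }
  J_xy <- mean(jxy)
  if (J_xy <= 0) return(Inf)
  max(0, -log(J_xy / sqrt(mean(jx) * mean(jy))))
}

#' Pairwise Nei standard distance matrix
#'
#' @param gm a [genotype_matrix()] with at least two accessions.
#' @return object of class `distance_matrix`: list with `labels` and the
#'   symmetric numeric matrix `d` (zero diagonal).
#' @export
distance_matrix <- function(gm) {
  n <- length(gm$accession_ids)
  if (n < 2L) stop("need >= 2 accessions")
  profiles <- lapply(gm$accession_ids, function(a)
    individual_allele_profile(gm, a))
  d <- matrix(0, n, n, dimnames = list(gm$accession_ids, gm$accession_ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- nei_standard_distance(profiles[[i]],
                                                  profiles[[j]])
    }
  }
  if (any(is.infinite(d))) {
    bad <- which(is.infinite(d) & upper.tri(d), arr.ind = TRUE)
    stop("infinite Nei distance (no shared alleles) for pair(s): ",
         paste(apply(bad, 1, function(ij)
           paste(rownames(d)[ij[1]], colnames(d)[ij[2]], sep = "~")),
           collapse = ", "))
  }
  structure(list(labels = gm$accession_ids, d = d), class = "distance_matrix")
}

as_distance_matrix <- function(d, labels = rownames(d)) {
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' UPGMA clustering of a distance matrix
#'
#' Classic (size-weighted) unweighted pair group method with arithmetic
#' mean: repeatedly merge the closest pair of clusters at height
#' `distance/2`, updating distances as the size-weighted mean of the merged
#' members' distances. Ties are broken on the lowest (row, column) index
#' pair in the current label order, making the tree deterministic.
#'
#' @param dm a `distance_matrix` (or plain symmetric matrix with dimnames).
#' @return object of class `upgma_tree`: a rooted, binary, ultrametric tree
#'   stored as nested lists (`label` at leaves; `children` + `height`
#'   internally).
#' @export
upgma <- function(dm) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else
    as_distance_matrix(dm)$d
  if (anyNA(d)) stop("NaN/NA in distance matrix")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need >= 2 taxa")
  nodes <- lapply(rownames(d), function(l)
    structure(list(label = l, height = 0), class = "upgma_tree"))
  sizes <- rep(1L, n)
  active <- d
  while (length(nodes) > 1L) {
    m <- length(nodes)
    # ties broken on the lexicographically smallest (row, col) pair
    best <- c(1L, 2L)
    bval <- Inf
    for (i in 1L:(m - 1L)) for (j in (i + 1L):m) {
      if (active[i, j] < bval) { bval <- active[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    h <- bval / 2
    merged <- structure(list(children = list(nodes[[i]], nodes[[j]]),
                             height = h), class = "upgma_tree")
    si <- sizes[i]; sj <- sizes[j]
    newd <- (si * active[i, ] + sj * active[j, ]) / (si + sj)
    keep <- setdiff(seq_len(m), c(i, j))
    active <- rbind(cbind(active[keep, keep, drop = FALSE], newd[keep]),
                    c(newd[keep], 0))
    nodes <- c(nodes[keep], list(merged))
    sizes <- c(sizes[keep], si + sj)
  }
  nodes[[1]]
}

tree_leaves <- function(tree) {
  if (!is.null(tree$label)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves))
}

#' Cophenetic distance matrix of an ultrametric tree
#'
#' @param tree an [upgma()] tree.
#' @return `distance_matrix` of twice the height of each pair's most recent
#'   common ancestor.
#' @export
cophenetic_distances <- function(tree) {
  leaves <- sort(tree_leaves(tree))
  n <- length(leaves)
  d <- matrix(0, n, n, dimnames = list(leaves, leaves))
  fill <- function(node) {
    if (!is.null(node$label)) return(node$label)
    kids <- lapply(node$children, fill)
    for (a in seq_along(kids)) for (b in seq_along(kids)) {
      if (a < b) d[kids[[a]], kids[[b]]] <<- d[kids[[b]], kids[[a]]] <<-
          2 * node$height
    }
    unlist(kids)
  }
  fill(tree)
  as_distance_matrix(d, leaves)
}

#' Serialize a tree to Newick
#'
#' Branch lengths are parent-child height differences, formatted to 6
#' significant digits. Children are ordered by their smallest leaf label;
#' labels containing spaces are single-quoted. A trailing semicolon is
#' emitted.
#'
#' @param tree an [upgma()] tree.
#' @return Newick string.
#' @examples
#' dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(dm))  # "((A:1,B:1):1,C:2);"
#' @export
to_newick <- function(tree) {
  fmt <- function(x) as.character(signif(x, 6))
  quote_label <- function(l) if (grepl("[][ ():;,]", l))
    paste0("'", l, "'") else l
  render <- function(node, parent_height) {
    bl <- fmt(parent_height - node$height)
    if (!is.null(node$label)) {
      return(paste0(quote_label(node$label), ":", bl))
    }
    kids <- node$children[order(vapply(node$children, function(k)
      min(tree_leaves(k)), character(1)))]
    inner <- paste(vapply(kids, render, character(1), node$height),
                   collapse = ",")
    paste0("(", inner, "):", bl)
  }
  if (!is.null(tree$label)) return(paste0(tree$label, ";"))
  kids <- tree$children[order(vapply(tree$children, function(k)
    min(tree_leaves(k)), character(1)))]
  inner <- paste(vapply(kids, render, character(1), tree$height),
                 collapse = ",")
  paste0("(", inner, ");")
}

#' Write a distance matrix as square TSV
#' @param dm a `distance_matrix`.
#' @param path output path.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(label = dm$labels, dm$d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
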