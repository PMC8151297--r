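#' Principal coordinates analysis (classical MDS)
#'
#' Gower double-centers \eqn{-\frac{1}{2} d_{ij}^2}, eigendecomposes, and
#' scales eigenvectors by the square root of their (positive) eigenvalues.
#' Percent variance is computed over the positive eigenvalues only; negative
#' eigenvalues (non-Euclidean input) are reported and their axes dropped, or
#' removed beforehand with the Cailliez additive correction.
#'
#' Axis signs are fixed by making each axis's largest-magnitude coordinate
#' positive, so output is reproducible across platforms.
#'
#' @param dm a `distance_matrix` (or symmetric matrix with dimnames).
#' @param n_axes number of axes to return (default: all positive); truncated
#'   with a warning when exceeding the positive-eigenvalue count.
#' @param cailliez apply the Cailliez correction (add the smallest constant
#'   to off-diagonal distances making the configuration Euclidean).
#' @return object of class `pcoa_result`: `coordinates` (accessions x axes),
#'   `eigenvalues` (all, descending), `percent_variance` (positive axes),
#'   `negative_eigenvalues`.
#' @export
pcoa <- function(dm, n_axes = NULL, cailliez = FALSE) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as_distance_matrix(dm)$d
  if (anyNA(d) || any(is.infinite(d))) stop("distances must be finite")
  n <- nrow(d)
  labels <- rownames(d)
  if (cailliez) d <- cailliez_correct(d)
  B <- gower_center(d)
  eig <- eigen(B, symmetric = TRUE)
  vals <- eig$values
  tol <- max(abs(vals)) * 1e-9
  pos <- which(vals > tol)
  if (length(pos) == 0L) {
    coords <- matrix(0, n, 0, dimnames = list(labels, NULL))
    return(structure(list(coordinates = coords, eigenvalues = vals,
                          percent_variance = numeric(0),
                          negative_eigenvalues = vals[vals < -tol]),
                     class = "pcoa_result"))
  }
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); truncating axes")
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(vals[keep]), n_axes)
  for (a in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  dimnames(coords) <- list(labels, paste0("Axis", seq_len(n_axes)))
  structure(list(coordinates = coords, eigenvalues = vals,
                 percent_variance = 100 * vals[pos] / sum(vals[pos]),
                 negative_eigenvalues = vals[vals < -tol]),
            class = "pcoa_result")
}

gower_center <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

# Cailliez (1983): smallest c so that d + c (off-diagonal) is Euclidean,
# the largest eigenvalue of the 2n x 2n block companion matrix.
cailliez_correct <- function(d) {
  n <- nrow(d)
  A1 <- gower_center(d)
  A2 <- gower_center_linear(d)
  blk <- rbind(cbind(matrix(0, n, n), 2 * A1),
               cbind(-diag(n), -4 * A2))
  cc <- max(Re(eigen(blk, only.values = TRUE)$values))
  if (cc > 0) d <- d + cc * (1 - diag(n))
  d
}

gower_center_linear <- function(d) {
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% (-0.5 * d) %*% J
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("pcoa_result: %d points, %d positive axes\n",
              nrow(x$coordinates), k))
  if (k > 0) {
    pv <- x$percent_variance[seq_len(min(k, 3))]
    cat("  % variance:", paste(sprintf("%.1f", pv), collapse = ", "), "\n")
  }
  if (length(x$negative_eigenvalues)) {
    cat("  negative eigenvalues:", length(x$negative_eigenvalues), "\n")
  }
  invisible(x)
}

#' Write PCoA coordinates and eigenvalue table as TSV
#' @param res a [pcoa()] result.
#' @param path output path for coordinates; the eigenvalue table goes to
#'   `<path>.eigen.tsv`.
#' @export
write_pcoa_tsv <- function(res, path) {
  df <- data.frame(accession = rownames(res$coordinates), res$coordinates,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  np <- length(res$percent_variance)
  ev <- data.frame(axis = seq_along(res$eigenvalues),
                   eigenvalue = res$eigenvalues,
                   percent_variance = c(res$percent_variance,
                                        rep(NA, length(res$eigenvalues) - np)))
  write.table(ev, paste0(path, ".eigen.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
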