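# Internal: encode a genotype matrix into per-allele copy counts.
# Returns CNT (N x C matrix of 0/1/2 copy counts; C = total locus-allele
# columns), colLoc (locus index per column), copies (N x L; 2 or 0),
# het (N x L logical).
encode_allele_counts <- function(gm) {
  N <- length(gm$accession_ids)
  L <- length(gm$marker_ids)
  cnt_cols <- list()
  colLoc <- integer(0)
  copies <- matrix(0L, N, L)
  het <- matrix(FALSE, N, L)
  for (l in seq_len(L)) {
    col <- gm$calls[, l]
    ok <- !is.na(col)
    a1 <- a2 <- rep(NA_character_, N)
    if (any(ok)) {
      sp <- strsplit(col[ok], "/", fixed = TRUE)
      a1[ok] <- vapply(sp, `[`, character(1), 1L)
      a2[ok] <- vapply(sp, `[`, character(1), 2L)
    }
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) == 0L) alleles <- "A"  # all-missing locus
    m <- matrix(0L, N, length(alleles))
    for (u in seq_along(alleles)) {
      m[, u] <- (a1 %in% alleles[u]) + (a2 %in% alleles[u])
    }
    copies[ok, l] <- 2L
    het[ok, l] <- a1[ok] != a2[ok]
    cnt_cols[[l]] <- m
    colLoc <- c(colLoc, rep(l, length(alleles)))
  }
  list(CNT = do.call(cbind, cnt_cols), colLoc = colLoc, copies = copies,
       het = het)
}

# Sum of squared differences terms from allele counts: for a group with
# total copies m and per-allele counts c_u, the sum over unordered copy
# pairs of the 0/1 mismatch distance is (m^2 - sum c_u^2) / 2, and the SS
# contribution is that divided by m.
ss_from_counts <- function(groupCNT, groupCopies, colLoc) {
  sumsq <- t(rowsum(t(groupCNT^2), colLoc))         # groups x L
  m <- groupCopies                                  # groups x L
  term <- (m^2 - sumsq) / (2 * m)
  term[m == 0] <- 0
  sum(term)
}

#' Three-level codominant AMOVA
#'
#' Partitions molecular variance among populations, among individuals within
#' populations, and within individuals, from squared differences between
#' allele copies (0/1 mismatch per locus, summed over loci). Degrees of
#' freedom are (P-1, N-P, N) with total 2N-1. Variance components are solved
#' from the expected mean squares using the unequal-size coefficient
#' \eqn{n_0 = (2N - \sum_p (2N_p)^2 / 2N) / (P - 1)}; negative components
#' are truncated to zero before percentages (GenAlEx convention).
#' \eqn{F_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_b + \sigma^2_c)}.
#'
#' Missing calls are handled by locus-wise deletion: an individual missing at
#' a locus contributes no copy pairs there; counts of excluded calls are
#' returned in `n_missing_by_locus`.
#'
#' Significance is assessed by permuting whole individuals among populations
#' (preserving sizes) and recomputing \eqn{F_{ST}};
#' \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1) / (n_{perm} + 1)}.
#'
#' @param gm a [genotype_matrix()] carrying population labels (or supply
#'   `populations`).
#' @param populations optional per-accession labels overriding
#'   `gm$populations`.
#' @param n_perm permutations for the F_ST test (0 to skip).
#' @param seed RNG seed for the permutation test.
#' @return object of class `amova_result`: `table` (Source, df, SS, MS,
#'   est_var, percent), `f_st`, `p_value`, `n_permutations`, `n0`,
#'   `n_missing_by_locus`.
#' @export
amova_codominant <- function(gm, populations = NULL, n_perm = 1000,
                             seed = NULL) {
  pops <- if (is.null(populations)) gm$populations else
    setNames(as.character(populations), gm$accession_ids)
  if (is.null(pops)) stop("population labels required for AMOVA")
  pops <- factor(pops)
  sizes <- table(pops)
  if (length(sizes) < 2L) stop("need >= 2 populations")
  if (any(sizes < 2L)) {
    stop("population(s) with a single individual: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  enc <- encode_allele_counts(gm)
  N <- length(gm$accession_ids)
  P <- length(sizes)
  df <- c(P - 1L, N - P, N)
  # permutation-invariant pieces
  tot_cnt <- matrix(colSums(enc$CNT), 1)
  tot_cop <- matrix(colSums(enc$copies), 1)
  ss_total <- ss_from_counts(tot_cnt, tot_cop, enc$colLoc)
  ss_wi <- sum(enc$het) / 2
  n0 <- (2 * N - sum((2 * as.numeric(sizes))^2) / (2 * N)) / (P - 1)

  fst_for <- function(g) {
    gi <- as.integer(g)
    A <- rowsum(enc$CNT, gi)
    Mp <- rowsum(enc$copies, gi)
    ss_wp <- ss_from_counts(A, Mp, enc$colLoc)
    ss <- c(ss_total - ss_wp, ss_wp - ss_wi, ss_wi)
    ms <- ss / df
    sc <- ms[3]
    sb <- (ms[2] - ms[3]) / 2
    sa <- (ms[1] - ms[2]) / n0
    comp <- pmax(c(sa, sb, sc), 0)
    list(ss = ss, ms = ms, comp = comp,
         f_st = if (sum(comp) > 0) comp[1] / sum(comp) else 0)
  }
  obs <- fst_for(pops)
  tbl <- data.frame(
    source = c("Among Pops", "Among Indiv", "Within Indiv", "Total"),
    df = c(df, 2L * N - 1L),
    SS = c(obs$ss, sum(obs$ss)),
    MS = c(obs$ms, NA),
    est_var = c(obs$comp, sum(obs$comp)),
    percent = c(100 * obs$comp / sum(obs$comp), 100),
    stringsAsFactors = FALSE)
  res <- structure(list(table = tbl, f_st = obs$f_st, p_value = NA_real_,
                        n_permutations = 0L, n0 = n0,
                        n_missing_by_locus = colSums(enc$copies == 0L),
                        .enc = enc, .pops = pops, .df = df,
                        .ss_total = ss_total, .ss_wi = ss_wi),
                   class = "amova_result")
  if (n_perm > 0) {
    res$p_value <- permute_fst(gm, res, n_perm, seed)
    res$n_permutations <- as.integer(n_perm)
  }
  res
}

#' Permutation test of F_ST
#'
#' Whole individuals are shuffled among populations (sizes preserved) and
#' the AMOVA F_ST recomputed for each permutation.
#'
#' @param gm the [genotype_matrix()] used for `observed` (unused beyond
#'   interface symmetry; the encoded data ride along in `observed`).
#' @param observed an [amova_codominant()] result.
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed (optional).
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permute_fst <- function(gm, observed, n_perm, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  enc <- observed$.enc
  df <- observed$.df
  n0 <- observed$n0
  ss_total <- observed$.ss_total
  ss_wi <- observed$.ss_wi
  pops <- observed$.pops
  fst_obs <- observed$f_st
  count <- 0L
  for (b in seq_len(n_perm)) {
    g <- as.integer(pops)[sample.int(length(pops))]
    A <- rowsum(enc$CNT, g)
    Mp <- rowsum(enc$copies, g)
    ss_wp <- ss_from_counts(A, Mp, enc$colLoc)
    ss <- c(ss_total - ss_wp, ss_wp - ss_wi, ss_wi)
    ms <- ss / df
    comp <- pmax(c((ms[1] - ms[2]) / n0, (ms[2] - ms[3]) / 2, ms[3]), 0)
    f <- if (sum(comp) > 0) comp[1] / sum(comp) else 0
    if (f >= fst_obs - 1e-12) count <- count + 1L
  }
  (count + 1) / (n_perm + 1)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Codominant AMOVA\n")
  tbl <- x$table
  tbl$SS <- round(tbl$SS, 3)
  tbl$MS <- round(tbl$MS, 3)
  tbl$est_var <- round(tbl$est_var, 3)
  tbl$percent <- sprintf("%.0f%%", tbl$percent)
  print(tbl, row.names = FALSE)
  cat(sprintf("F_ST = %.3f", x$f_st))
  if (!is.na(x$p_value)) {
    cat(sprintf(" (p = %.4g, %d permutations)", x$p_value,
                x$n_permutations))
  }
  cat("\n")
  invisible(x)
}

#' Write an AMOVA table as TSV
#' @param res an [amova_codominant()] result.
#' @param path output path.
#' @export
write_amova_tsv <- function(res, path) {
  tbl <- res$table
  tbl$F_ST <- c(res$f_st, rep(NA, nrow(tbl) - 1))
  tbl$p_value <- c(res$p_value, rep(NA, nrow(tbl) - 1))
  write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
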