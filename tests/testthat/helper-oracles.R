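# Shared fixtures and independent brute-force oracles.

# Build a genotype matrix from per-marker call vectors.
make_gm <- function(..., populations = NULL) {
  cols <- list(...)
  n <- length(cols[[1]])
  calls <- do.call(cbind, cols)
  rownames(calls) <- sprintf("acc%02d", seq_len(n))
  genotype_matrix(calls, populations = populations)
}

# Gene diversity by explicit enumeration of allele copies.
brute_gd <- function(calls) {
  copies <- unlist(strsplit(calls[!is.na(calls)], "/", fixed = TRUE))
  p <- table(copies) / length(copies)
  1 - sum(p^2)
}

# Nei standard distance straight from its definition on two accessions.
brute_nei <- function(gm, a1, a2) {
  i <- match(a1, gm$accession_ids)
  j <- match(a2, gm$accession_ids)
  shared <- which(!is.na(gm$calls[i, ]) & !is.na(gm$calls[j, ]))
  jx <- jy <- jxy <- numeric(0)
  for (l in shared) {
    fx <- table(strsplit(gm$calls[i, l], "/")[[1]]) / 2
    fy <- table(strsplit(gm$calls[j, l], "/")[[1]]) / 2
    alle <- union(names(fx), names(fy))
    x <- sapply(alle, function(u) ifelse(u %in% names(fx), fx[[u]], 0))
    y <- sapply(alle, function(u) ifelse(u %in% names(fy), fy[[u]], 0))
    jx <- c(jx, sum(x^2)); jy <- c(jy, sum(y^2)); jxy <- c(jxy, sum(x * y))
  }
  -log(mean(jxy) / sqrt(mean(jx) * mean(jy)))
}

# AMOVA sums of squares by explicit enumeration of all pairs of allele
# copies, per locus, summed over loci. Returns the three-level SS vector.
brute_amova_ss <- function(gm, pops) {
  L <- length(gm$marker_ids)
  ss_total <- ss_wp <- ss_wi <- 0
  group_ss <- function(copies) {
    m <- length(copies)
    if (m < 2) return(0)
    s <- 0
    for (a in 1:(m - 1)) for (b in (a + 1):m) {
      s <- s + as.integer(copies[a] != copies[b])
    }
    s / m
  }
  for (l in seq_len(L)) {
    col <- gm$calls[, l]
    ok <- !is.na(col)
    parts <- strsplit(col[ok], "/", fixed = TRUE)
    owner <- rep(which(ok), each = 2)
    copies <- unlist(parts)
    ss_total <- ss_total + group_ss(copies)
    for (p in unique(pops)) {
      sel <- pops[owner] == p
      ss_wp <- ss_wp + group_ss(copies[sel])
    }
    for (i in which(ok)) {
      ss_wi <- ss_wi + group_ss(copies[owner == i])
    }
  }
  c(among_pops = ss_total - ss_wp, among_indiv = ss_wp - ss_wi,
    within_indiv = ss_wi, total = ss_total)
}

# Random genotype panel (unstructured) for property tests.
random_panel <- function(n_acc, n_loci, seed, missing_rate = 0) {
  set.seed(seed)
  calls <- matrix(NA_character_, n_acc, n_loci)
  for (l in seq_len(n_loci)) {
    ab <- sample(c("A", "C", "G", "T"), 2)
    p <- runif(1, 0.2, 0.8)
    g <- sample(1:3, n_acc, replace = TRUE, prob = c(p^2, 2 * p * (1 - p),
                                                     (1 - p)^2))
    calls[, l] <- c(paste(ab[1], ab[1], sep = "/"),
                    paste(sort(ab)[1], sort(ab)[2], sep = "/"),
                    paste(ab[2], ab[2], sep = "/"))[g]
  }
  if (missing_rate > 0) calls[runif(length(calls)) < missing_rate] <- NA
  rownames(calls) <- sprintf("a%03d", seq_len(n_acc))
  colnames(calls) <- sprintf("L%03d", seq_len(n_loci))
  genotype_matrix(calls)
}
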