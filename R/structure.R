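# Internal: encode calls into a N x 2L matrix of 0-based allele codes
# (-1 = missing) plus per-locus allele counts.
encode_for_admixture <- function(gm) {
  N <- length(gm$accession_ids)
  L <- length(gm$marker_ids)
  geno <- matrix(-1L, N, 2L * L)
  nAlleles <- integer(L)
  for (l in seq_len(L)) {
    col <- gm$calls[, l]
    parts <- strsplit(col, "/", fixed = TRUE)
    alleles <- sort(unique(unlist(parts)))
    nAlleles[l] <- max(length(alleles), 1L)
    for (i in seq_len(N)) {
      if (!is.na(col[i])) {
        geno[i, 2L * l - 1L] <- match(parts[[i]][1], alleles) - 1L
        geno[i, 2L * l] <- match(parts[[i]][2], alleles) - 1L
      }
    }
  }
  list(geno = geno, nAlleles = nAlleles)
}

#' Bayesian admixture-model clustering (Gibbs sampler)
#'
#' Implements the standard no-linkage admixture model: individual i draws
#' each allele copy from cluster k with probability \eqn{q_{ik}}, and
#' cluster k holds its own allele frequencies per locus. The Gibbs cycle
#' samples (i) the cluster origin of every allele copy, (ii) cluster allele
#' frequencies from their Dirichlet(1 + counts) posteriors, (iii) each
#' individual's admixture proportions from Dirichlet(alpha + counts), and
#' (iv) the shared concentration alpha by a symmetric-proposal Metropolis
#' step under a uniform prior on (0, 10]. The data log-likelihood is
#' recorded every `thin` iterations after burn-in.
#'
#' Defaults mirror common practice for germplasm panels (10,000 burn-in,
#' 100,000 sampling iterations); reduce both for testing. All randomness
#' flows from `seed` via R's RNG, so runs are bit-reproducible.
#'
#' @param gm a [genotype_matrix()].
#' @param K number of clusters (1 <= K <= number of accessions).
#' @param burn_in burn-in iterations.
#' @param n_iter post-burn-in iterations.
#' @param thin record every `thin`-th iteration.
#' @param seed RNG seed.
#' @param alpha_init,alpha_max,alpha_prop_sd concentration-update controls.
#' @return object of class `structure_run`: `K`, `q` (accessions x K
#'   posterior-mean admixture proportions, rows summing to 1), `alpha`
#'   (mean, sd, acceptance rate), `log_lik_trace`, `ln_pd` (model
#'   log-evidence estimate, see [estimate_log_evidence()]).
#' @export
run_admixture_gibbs <- function(gm, K, burn_in = 10000, n_iter = 100000,
                                thin = 10, seed = NULL, alpha_init = 1,
                                alpha_max = 10, alpha_prop_sd = 0.05) {
  N <- length(gm$accession_ids)
  if (K > N) stop("K exceeds the number of accessions")
  if (n_iter < thin) stop("n_iter must be >= thin")
  if (!is.null(seed)) set.seed(seed)
  enc <- encode_for_admixture(gm)
  out <- admixture_gibbs_cpp(enc$geno, enc$nAlleles, as.integer(K),
                             as.integer(burn_in), as.integer(n_iter),
                             as.integer(thin), alpha_init, alpha_max,
                             alpha_prop_sd)
  q <- out$q
  q <- q / rowSums(q)
  dimnames(q) <- list(gm$accession_ids, paste0("Cluster", seq_len(K)))
  structure(list(K = as.integer(K), q = q,
                 alpha = list(mean = mean(out$alpha_trace),
                              sd = sd(out$alpha_trace),
                              accept_rate = out$alpha_accept_rate),
                 log_lik_trace = out$log_lik_trace,
                 ln_pd = estimate_log_evidence(out$log_lik_trace)),
            class = "structure_run")
}

#' Estimate the model log-evidence from a log-likelihood trace
#'
#' The usual harmonic-style approximation reported as "Ln P(D)":
#' \eqn{\hat{L} = \bar{\ell} - \mathrm{Var}(\ell)/2} with the population
#' (1/n) variance over recorded iterations.
#'
#' @param log_lik_trace numeric vector, length >= 2.
#' @return scalar log-evidence estimate.
#' @examples
#' estimate_log_evidence(c(-10, -12))  # -11.5
#' @export
estimate_log_evidence <- function(log_lik_trace) {
  n <- length(log_lik_trace)
  if (n < 2L) stop("trace must have length >= 2")
  m <- mean(log_lik_trace)
  v <- mean((log_lik_trace - m)^2)
  m - v / 2
}

#' Run replicate admixture chains over a range of K
#'
#' @param gm a [genotype_matrix()].
#' @param k_range integer vector of contiguous K values (e.g. `1:10`).
#' @param n_reps replicate chains per K.
#' @param seed base seed; chain (K, rep) uses `seed + 1000*K + rep` so every
#'   chain is independently reproducible.
#' @inheritParams run_admixture_gibbs
#' @return object of class `structure_sweep`: `ln_pd` (matrix reps x K),
#'   `runs` (list of lists of `structure_run`), `k_range`.
#' @export
structure_sweep <- function(gm, k_range, n_reps = 10, burn_in = 10000,
                            n_iter = 100000, thin = 10, seed = 1) {
  k_range <- sort(as.integer(k_range))
  lnpd <- matrix(NA_real_, n_reps, length(k_range),
                 dimnames = list(NULL, paste0("K", k_range)))
  runs <- vector("list", length(k_range))
  names(runs) <- paste0("K", k_range)
  for (ki in seq_along(k_range)) {
    runs[[ki]] <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      run <- run_admixture_gibbs(gm, k_range[ki], burn_in = burn_in,
                                 n_iter = n_iter, thin = thin,
                                 seed = seed + 1000L * k_range[ki] + r)
      lnpd[r, ki] <- run$ln_pd
      runs[[ki]][[r]] <- run
    }
  }
  structure(list(ln_pd = lnpd, runs = runs, k_range = k_range),
            class = "structure_sweep")
}

#' Evanno delta-K table
#'
#' For replicate log-evidence values \eqn{L(K)} over a contiguous K range:
#' \eqn{L'(K) = \bar{L}(K) - \bar{L}(K-1)},
#' \eqn{|L''(K)| = |\bar{L}(K+1) - 2\bar{L}(K) + \bar{L}(K-1)|}, and
#' \eqn{\Delta K = |L''(K)| / s(K)} with the sample (n-1) standard deviation
#' across replicates. Delta-K is defined only at interior K with positive
#' replicate spread; the arg-max is reported as the optimal K.
#'
#' @param ln_pd matrix of replicate log-evidence values (replicates x K,
#'   columns in ascending contiguous K order, named `K<k>`), or a
#'   `structure_sweep`.
#' @return object of class `evanno_table`: data.frame with `K, mean_lnpd,
#'   sd_lnpd, lprime, lsecond, delta_k`, plus attribute `optimal_k`.
#' @export
evanno_delta_k <- function(ln_pd) {
  if (inherits(ln_pd, "structure_sweep")) {
    ks <- ln_pd$k_range
    ln_pd <- ln_pd$ln_pd
  } else {
    ks <- as.integer(sub("^K", "", colnames(ln_pd)))
    if (anyNA(ks)) ks <- seq_len(ncol(ln_pd))
  }
  if (nrow(ln_pd) < 2L) stop("need >= 2 replicates per K")
  if (length(ks) > 1L && any(diff(ks) != 1L)) stop("K range must be contiguous")
  mean_l <- colMeans(ln_pd)
  sd_l <- apply(ln_pd, 2, sd)
  nk <- length(ks)
  lprime <- c(NA, diff(mean_l))
  lsecond <- rep(NA_real_, nk)
  delta <- rep(NA_real_, nk)
  for (i in seq_len(nk)) {
    if (i > 1L && i < nk) {
      lsecond[i] <- abs(mean_l[i + 1] - 2 * mean_l[i] + mean_l[i - 1])
      delta[i] <- if (sd_l[i] > 0) lsecond[i] / sd_l[i] else NA_real_
    }
  }
  tbl <- data.frame(K = ks, mean_lnpd = unname(mean_l),
                    sd_lnpd = unname(sd_l), lprime = unname(lprime),
                    lsecond = lsecond, delta_k = delta)
  opt <- if (all(is.na(delta))) NA_integer_ else ks[which.max(delta)]
  structure(tbl, class = c("evanno_table", "data.frame"), optimal_k = opt)
}

#' Classify accessions into clusters or "Admix"
#'
#' An accession is assigned to its maximum-q cluster when that proportion
#' meets the threshold, and labelled `"Admix"` otherwise.
#'
#' @param run a [run_admixture_gibbs()] result.
#' @param threshold membership threshold in (0.5, 1]; default 0.7.
#' @return named character vector of cluster labels / `"Admix"`.
#' @export
classify_membership <- function(run, threshold = 0.7) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1]")
  }
  q <- run$q
  best <- max.col(q, ties.method = "first")
  lab <- colnames(q)[best]
  lab[q[cbind(seq_len(nrow(q)), best)] < threshold] <- "Admix"
  setNames(lab, rownames(q))
}

#' @export
print.structure_run <- function(x, ...) {
  cat(sprintf("structure_run: K = %d, ln P(D) = %.2f, mean alpha = %.3f\n",
              x$K, x$ln_pd, x$alpha$mean))
  invisible(x)
}
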