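#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gibbs sampler for the vanilla admixture model (no linkage, uniform
// Dirichlet(1) allele-frequency prior, single shared alpha with a
// symmetric-proposal Metropolis update under a uniform prior on (0, alphaMax]).
//
// geno: N x (2L) integer matrix of 0-based allele codes (-1 = missing),
//       columns 2l and 2l+1 are the two copies at locus l.
// nAlleles: allele count per locus.
// Iterations: burnin + iters; the data log-likelihood, alpha and q are
// recorded every `thin` iterations after burn-in. Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, IntegerVector nAlleles, int K,
                         int burnin, int iters, int thin, double alphaInit,
                         double alphaMax, double alphaPropSd) {
  const int N = geno.nrow();
  const int L = nAlleles.size();
  if (geno.ncol() != 2 * L) stop("geno must have 2 * n_loci columns");
  if (K < 1) stop("K must be >= 1");
  int Umax = 0;
  for (int l = 0; l < L; ++l) Umax = std::max(Umax, (int)nAlleles[l]);

  std::vector<double> P((size_t)K * L * Umax, 0.0);   // P[k][l][u]
  std::vector<double> q((size_t)N * K, 1.0 / K);
  std::vector<int> z((size_t)N * 2 * L, 0);
  std::vector<double> cnt((size_t)K * L * Umax);
  std::vector<double> nik((size_t)N * K);
  std::vector<double> probs(K);
  double alpha = alphaInit;

  // init P from the prior
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) {
      double s = 0.0;
      for (int u = 0; u < nAlleles[l]; ++u) {
        double g = R::rgamma(1.0, 1.0);
        P[((size_t)k * L + l) * Umax + u] = g;
        s += g;
      }
      for (int u = 0; u < nAlleles[l]; ++u)
        P[((size_t)k * L + l) * Umax + u] /= s;
    }

  const int total = burnin + iters;
  const int nrec = (thin > 0) ? iters / thin : 0;
  NumericVector loglik(nrec), alphaTrace(nrec);
  NumericMatrix qMean(N, K);
  int rec = 0;
  int alphaAccept = 0, alphaTries = 0;

  for (int t = 1; t <= total; ++t) {
    // (i) sample copy origins z | q, P
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(nik.begin(), nik.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      const double* qi = &q[(size_t)i * K];
      for (int l = 0; l < L; ++l) {
        for (int a = 0; a < 2; ++a) {
          int g = geno(i, 2 * l + a);
          if (g < 0) continue;
          int zi = 0;
          if (K > 1) {
            double s = 0.0;
            for (int k = 0; k < K; ++k) {
              double p = qi[k] * P[((size_t)k * L + l) * Umax + g];
              probs[k] = p;
              s += p;
            }
            double u = R::unif_rand() * s, c = 0.0;
            for (int k = 0; k < K; ++k) {
              c += probs[k];
              if (u <= c) { zi = k; break; }
              zi = k;
            }
          }
          z[((size_t)i * L + l) * 2 + a] = zi;
          cnt[((size_t)zi * L + l) * Umax + g] += 1.0;
          nik[(size_t)i * K + zi] += 1.0;
        }
      }
    }
    // (ii) P | z ~ Dirichlet(1 + counts)
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        for (int u = 0; u < nAlleles[l]; ++u) {
          double g = R::rgamma(1.0 + cnt[((size_t)k * L + l) * Umax + u], 1.0);
          P[((size_t)k * L + l) * Umax + u] = g;
          s += g;
        }
        for (int u = 0; u < nAlleles[l]; ++u)
          P[((size_t)k * L + l) * Umax + u] /= s;
      }
    // (iii) q | z ~ Dirichlet(alpha + n_ik)
    if (K > 1) {
      for (int i = 0; i < N; ++i) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha + nik[(size_t)i * K + k], 1.0);
          if (g <= 0) g = 1e-300;
          q[(size_t)i * K + k] = g;
          s += g;
        }
        for (int k = 0; k < K; ++k) q[(size_t)i * K + k] /= s;
      }
      // (iv) Metropolis update of alpha
      double prop = alpha + R::norm_rand() * alphaPropSd;
      ++alphaTries;
      if (prop > 0 && prop <= alphaMax) {
        double slq = 0.0;
        for (size_t ik = 0; ik < q.size(); ++ik)
          slq += std::log(std::max(q[ik], 1e-300));
        double cur = N * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                     (alpha - 1.0) * slq;
        double nw = N * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                    (prop - 1.0) * slq;
        if (std::log(R::unif_rand()) < nw - cur) {
          alpha = prop;
          ++alphaAccept;
        }
      }
    }
    // record
    if (t > burnin && thin > 0 && (t - burnin) % thin == 0 && rec < nrec) {
      double ll = 0.0;
      for (int i = 0; i < N; ++i) {
        const double* qi = &q[(size_t)i * K];
        for (int l = 0; l < L; ++l)
          for (int a = 0; a < 2; ++a) {
            int g = geno(i, 2 * l + a);
            if (g < 0) continue;
            double p = 0.0;
            for (int k = 0; k < K; ++k)
              p += qi[k] * P[((size_t)k * L + l) * Umax + g];
            ll += std::log(std::max(p, 1e-300));
          }
      }
      loglik[rec] = ll;
      alphaTrace[rec] = alpha;
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k)
          qMean(i, k) += q[(size_t)i * K + k];
      ++rec;
    }
  }
  if (rec > 0)
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < K; ++k) qMean(i, k) /= rec;
  return List::create(_["log_lik_trace"] = loglik,
                      _["alpha_trace"] = alphaTrace,
                      _["q"] = qMean,
                      _["alpha_accept_rate"] =
                          alphaTries ? (double)alphaAccept / alphaTries : NA_REAL);
}
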