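#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the admixture clustering model.
//
// Latent state: the cluster of origin z of every allele copy; cluster-by-
// locus allele frequencies P with Dirichlet(lambda) priors; per-individual
// admixture proportions Q with a symmetric Dirichlet(alpha) prior (alpha
// fixed).  Each sweep draws P | z and Q | z from their Dirichlet full
// conditionals, then resamples z | P,Q while accumulating the cluster and
// admixture counts for the next sweep, and records the observed-data
// log-likelihood ln P(X | P, Q) = sum log( sum_k Q[i,k] P[k, l, x] ) on
// post-burn-in sweeps.  LnP(D) is estimated from that series as
// mean - variance/2.
//
// Uses R's RNG, so results are reproducible under set.seed().

// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix alleles, IntegerVector n_alleles,
                         int K, int n_sweeps, int n_burnin,
                         double lambda, double alpha) {
  const int n = alleles.nrow();
  const int L = n_alleles.size();
  if (alleles.ncol() != 2 * L) stop("alleles must have 2 columns per locus");
  if (K < 1) stop("K must be >= 1");

  // locus offsets into the flattened (cluster, locus, allele) freq array
  std::vector<int> off(L + 1, 0);
  for (int l = 0; l < L; ++l) off[l + 1] = off[l] + n_alleles[l];
  const int A = off[L];

  RNGScope scope;

  std::vector<double> P(static_cast<size_t>(K) * A);
  std::vector<double> Q(static_cast<size_t>(n) * K);
  std::vector<double> pcnt(static_cast<size_t>(K) * A, 0.0);
  std::vector<double> qcnt(static_cast<size_t>(n) * K, 0.0);
  std::vector<double> qsum(static_cast<size_t>(n) * K, 0.0);
  std::vector<double> prob(K);

  // random initial cluster-of-origin assignments, tallied into the counts
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 2 * L; ++c) {
      int a = alleles(i, c);
      if (a < 0) continue;
      int k = static_cast<int>(unif_rand() * K) % K;
      pcnt[static_cast<size_t>(k) * A + off[c / 2] + a] += 1.0;
      qcnt[static_cast<size_t>(i) * K + k] += 1.0;
    }

  double ll_mean = 0.0, ll_m2 = 0.0;
  long n_kept = 0;

  const int total = n_burnin + n_sweeps;
  for (int sweep = 0; sweep < total; ++sweep) {
    // P | z : Dirichlet(lambda + counts) per cluster per locus
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double s = 0.0;
        double *pk = &P[static_cast<size_t>(k) * A + off[l]];
        double *ck = &pcnt[static_cast<size_t>(k) * A + off[l]];
        for (int a = 0; a < n_alleles[l]; ++a) {
          pk[a] = R::rgamma(lambda + ck[a], 1.0);
          s += pk[a];
        }
        for (int a = 0; a < n_alleles[l]; ++a) pk[a] /= s;
      }
    // Q | z : Dirichlet(alpha + counts) per individual
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      double *qi = &Q[static_cast<size_t>(i) * K];
      double *ci = &qcnt[static_cast<size_t>(i) * K];
      for (int k = 0; k < K; ++k) {
        qi[k] = R::rgamma(alpha + ci[k], 1.0);
        s += qi[k];
      }
      for (int k = 0; k < K; ++k) qi[k] /= s;
    }
    // z | P, Q, re-tallying counts; log-likelihood on kept sweeps only
    std::fill(pcnt.begin(), pcnt.end(), 0.0);
    std::fill(qcnt.begin(), qcnt.end(), 0.0);
    const bool keep = sweep >= n_burnin;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      const double *qi = &Q[static_cast<size_t>(i) * K];
      for (int c = 0; c < 2 * L; ++c) {
        int a = alleles(i, c);
        if (a < 0) continue;
        const int o = off[c / 2] + a;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          prob[k] = qi[k] * P[static_cast<size_t>(k) * A + o];
          tot += prob[k];
        }
        if (keep) ll += std::log(tot);
        double u = unif_rand() * tot;
        int k = 0;
        while (k < K - 1 && u > prob[k]) { u -= prob[k]; ++k; }
        pcnt[static_cast<size_t>(k) * A + o] += 1.0;
        qcnt[static_cast<size_t>(i) * K + k] += 1.0;
      }
    }
    if (keep) {
      if (!std::isfinite(ll))
        stop("non-finite log-likelihood at sweep %d", sweep + 1);
      // Welford accumulation of the log-likelihood series
      ++n_kept;
      double d = ll - ll_mean;
      ll_mean += d / n_kept;
      ll_m2 += d * (ll - ll_mean);
      for (size_t j = 0; j < qsum.size(); ++j) qsum[j] += Q[j];
    }
  }

  double ll_var = n_kept > 1 ? ll_m2 / (n_kept - 1) : 0.0;
  NumericMatrix qmean(n, K);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k)
      qmean(i, k) = qsum[static_cast<size_t>(i) * K + k] / n_kept;

  return List::create(_["lnpd"] = ll_mean - ll_var / 2.0,
                      _["loglik_mean"] = ll_mean,
                      _["loglik_var"] = ll_var,
                      _["q"] = qmean);
}
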