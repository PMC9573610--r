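#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Allele-sharing distance between individuals.
// a1, a2: n x m integer matrices of allele indices (1-based, NA = missing),
// sorted within the pair. d(i,j) = 1 - shared / (2 * markers compared),
// pairwise-complete over markers non-missing in both individuals.
// [[Rcpp::export(name = ".allele_share_dist")]]
NumericMatrix allele_share_dist_cpp(IntegerMatrix a1, IntegerMatrix a2) {
  int n = a1.nrow(), m = a1.ncol();
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int shared = 0, compared = 0;
      for (int k = 0; k < m; ++k) {
        int xi1 = a1(i, k), xi2 = a2(i, k);
        int xj1 = a1(j, k), xj2 = a2(j, k);
        if (xi1 == NA_INTEGER || xj1 == NA_INTEGER) continue;
        ++compared;
        // multiset intersection size of sorted pairs {xi1,xi2}, {xj1,xj2}
        int s;
        if (xi1 == xj1 && xi2 == xj2) s = 2;
        else if (xi1 == xj1 || xi1 == xj2 || xi2 == xj1 || xi2 == xj2) s = 1;
        else s = 0;
        // correct the homozygote-vs-het single-share case: {a,a} vs {a,b}
        // already yields 1 by the rule above, {a,b} vs {a,b} yields 2 only
        // via the first branch because pairs are sorted.
        shared += s;
      }
      double val = (compared == 0) ? NA_REAL
                                   : 1.0 - (double)shared / (2.0 * compared);
      d(i, j) = val;
      d(j, i) = val;
    }
  }
  return d;
}

// STRUCTURE-style admixture-model Gibbs sampler with uncorrelated allele
// frequencies. a1, a2: n x m allele-index matrices (1-based, NA missing);
// n_alleles: alleles per marker; K clusters; Dirichlet priors alpha (Q rows)
// and lambda (frequency vectors). Uses R's RNG, so set.seed() upstream makes
// runs reproducible. Returns the posterior-mean Q and the post-burn-in
// log-likelihood trace.
// [[Rcpp::export(name = ".admixture_gibbs")]]
List admixture_gibbs_cpp(IntegerMatrix a1, IntegerMatrix a2,
                         IntegerVector n_alleles, int K,
                         int burnin, int reps,
                         double alpha, double lambda) {
  int n = a1.nrow(), m = a1.ncol();
  int maxA = 0;
  for (int k = 0; k < m; ++k) maxA = std::max(maxA, n_alleles[k]);

  // P[k][j*maxA + a]: frequency of allele a at marker j in cluster k
  std::vector<std::vector<double> > P(K, std::vector<double>(m * maxA, 0.0));
  std::vector<std::vector<double> > cntP(K, std::vector<double>(m * maxA));
  NumericMatrix Q(n, K), Qsum(n, K);
  std::vector<double> cntQ(n * K);
  std::vector<double> prob(K);
  NumericVector lnl(reps);

  // initialize Q uniform and P from the prior
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < m; ++j) {
      double tot = 0.0;
      for (int a = 0; a < n_alleles[j]; ++a) {
        double g = R::rgamma(lambda, 1.0);
        P[k][j * maxA + a] = g;
        tot += g;
      }
      for (int a = 0; a < n_alleles[j]; ++a) P[k][j * maxA + a] /= tot;
    }

  int total = burnin + reps;
  for (int it = 0; it < total; ++it) {
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    for (int k = 0; k < K; ++k)
      std::fill(cntP[k].begin(), cntP[k].end(), 0.0);

    double ll = 0.0;
    bool record = it >= burnin;

    // sample cluster-of-origin for every allele copy
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < m; ++j) {
        int alleles[2] = {a1(i, j), a2(i, j)};
        if (alleles[0] == NA_INTEGER) continue;
        for (int c = 0; c < 2; ++c) {
          int a = alleles[c] - 1;
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[k][j * maxA + a];
            tot += prob[k];
          }
          if (record) ll += std::log(tot);
          double u = R::unif_rand() * tot, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) {
            acc += prob[k];
            if (u <= acc) { z = k; break; }
          }
          cntP[z][j * maxA + a] += 1.0;
          cntQ[i * K + z] += 1.0;
        }
      }
    }
    if (record) lnl[it - burnin] = ll;

    // update allele frequencies: Dirichlet(lambda + counts)
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < m; ++j) {
        double tot = 0.0;
        for (int a = 0; a < n_alleles[j]; ++a) {
          double g = R::rgamma(lambda + cntP[k][j * maxA + a], 1.0);
          P[k][j * maxA + a] = g;
          tot += g;
        }
        for (int a = 0; a < n_alleles[j]; ++a) P[k][j * maxA + a] /= tot;
      }

    // update admixture proportions: Dirichlet(alpha + counts)
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(alpha + cntQ[i * K + k], 1.0);
        Q(i, k) = g;
        tot += g;
      }
      for (int k = 0; k < K; ++k) {
        Q(i, k) /= tot;
        if (record) Qsum(i, k) += Q(i, k);
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= reps;
  return List::create(_["Q"] = Qsum, _["lnl"] = lnl);
}
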