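#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the no-admixture-prior-free admixture model with
// independent Dirichlet(lambda) allele frequencies:
//   z ~ categorical(q_i * p_{k,l,a}); P | z ~ Dir(lambda + counts);
//   q_i | z ~ Dir(alpha + copy counts); alpha by random-walk Metropolis
//   with a uniform prior on (0, 10].
// a1, a2: n x L matrices of per-locus allele indices 1..n_alleles[l],
// 0 = missing. pin: 0 = free individual, k = Q row fixed at e_k.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbs_admixture(IntegerMatrix a1, IntegerMatrix a2,
                     IntegerVector n_alleles, int K, int sweeps, int burnin,
                     double lambda, double alpha0, int thin,
                     IntegerVector pin) {
  const int n = a1.nrow(), L = a1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (burnin >= sweeps) stop("burnin must be smaller than sweeps");

  NumericMatrix Q(n, K);
  for (int i = 0; i < n; ++i) {
    if (pin[i] > 0) Q(i, pin[i] - 1) = 1.0;
    else for (int k = 0; k < K; ++k) Q(i, k) = 1.0 / K;
  }
  // P[k][l] is a frequency vector over the alleles of locus l
  std::vector< std::vector< std::vector<double> > > P(K), Psum(K), M(K);
  for (int k = 0; k < K; ++k) {
    P[k].resize(L); Psum[k].resize(L); M[k].resize(L);
    for (int l = 0; l < L; ++l) {
      P[k][l].assign(n_alleles[l], 1.0 / n_alleles[l]);
      Psum[k][l].assign(n_alleles[l], 0.0);
      M[k][l].assign(n_alleles[l], 0.0);
    }
  }
  double alpha = alpha0;
  const double astep = 0.05, amax = 10.0;

  NumericMatrix Qsum(n, K);
  std::vector<double> lnl_trace, alpha_trace;
  std::vector<double> w(K);
  NumericMatrix Ncopy(n, K);
  int kept = 0;

  for (int s = 0; s < sweeps; ++s) {
    // reset counts
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        std::fill(M[k][l].begin(), M[k][l].end(), 0.0);
    std::fill(Ncopy.begin(), Ncopy.end(), 0.0);

    // (i) allele-copy origins z, accumulating the data log-likelihood
    //     ln L = sum over copies of ln sum_k q_ik p_kla under current Q, P
    double lnl = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = (copy == 0) ? a1(i, l) : a2(i, l);
          if (a == 0) continue;           // missing copy skipped everywhere
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            w[k] = Q(i, k) * P[k][l][a - 1];
            tot += w[k];
          }
          lnl += std::log(tot);
          double u = unif_rand() * tot;
          int z = 0;
          double cum = w[0];
          while (z < K - 1 && u > cum) cum += w[++z];
          M[z][l][a - 1] += 1.0;
          Ncopy(i, z) += 1.0;
        }
      }
    }

    // (ii) allele frequencies P | z
    for (int k = 0; k < K; ++k) {
      for (int l = 0; l < L; ++l) {
        double tot = 0.0;
        for (size_t a = 0; a < P[k][l].size(); ++a) {
          double g = R::rgamma(lambda + M[k][l][a], 1.0);
          P[k][l][a] = g;
          tot += g;
        }
        for (size_t a = 0; a < P[k][l].size(); ++a) P[k][l][a] /= tot;
      }
    }

    // (iii) admixture proportions Q | z (pinned rows stay at e_k)
    if (K > 1) {
      for (int i = 0; i < n; ++i) {
        if (pin[i] > 0) continue;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha + Ncopy(i, k), 1.0);
          Q(i, k) = g;
          tot += g;
        }
        for (int k = 0; k < K; ++k) Q(i, k) /= tot;
      }

      // (iv) alpha: symmetric normal random walk, reflected into (0, 10]
      double prop = alpha + norm_rand() * astep;
      if (prop <= 0) prop = -prop;
      if (prop > amax) prop = 2 * amax - prop;
      if (prop > 0 && prop <= amax) {
        double lp_cur = 0.0, lp_prop = 0.0, slq = 0.0;
        int nfree = 0;
        for (int i = 0; i < n; ++i) {
          if (pin[i] > 0) continue;
          ++nfree;
          for (int k = 0; k < K; ++k)
            slq += std::log(std::max(Q(i, k), 1e-300));
        }
        lp_cur = nfree * (R::lgammafn(K * alpha) - K * R::lgammafn(alpha)) +
                 (alpha - 1.0) * slq;
        lp_prop = nfree * (R::lgammafn(K * prop) - K * R::lgammafn(prop)) +
                  (prop - 1.0) * slq;
        if (std::log(unif_rand()) < lp_prop - lp_cur) alpha = prop;
      }
    }

    if (s >= burnin) {
      ++kept;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l)
          for (size_t a = 0; a < P[k][l].size(); ++a)
            Psum[k][l][a] += P[k][l][a];
      if ((s - burnin) % thin == 0) {
        lnl_trace.push_back(lnl);
        alpha_trace.push_back(alpha);
      }
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= kept;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix pl(K, n_alleles[l]);
    for (int k = 0; k < K; ++k)
      for (int a = 0; a < n_alleles[l]; ++a) pl(k, a) = Psum[k][l][a] / kept;
    Pout[l] = pl;
  }
  return List::create(_["Q"] = Qsum, _["lnl"] = lnl_trace,
                      _["alpha"] = alpha_trace, _["P"] = Pout);
}
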