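#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the conditional GSI mixture model.
//
// expL:   N x K matrix of individual-by-collection likelihoods, already
//         exponentiated (each row may be rescaled by an arbitrary positive
//         constant; only ratios matter).
// zeta:   length-K Dirichlet prior mass on the mixing proportions.
// n_iter: total sweeps; burn_in: discarded leading sweeps.
//
// One sweep: (i) sample each individual's origin Z_i from
// P(Z_i = k) proportional to pi_k * expL(i,k); (ii) draw
// pi ~ Dirichlet(zeta + counts(Z)). Uses R's RNG, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List gsi_gibbs(NumericMatrix expL, NumericVector zeta, int n_iter,
               int burn_in) {
  const int N = expL.nrow(), K = expL.ncol();
  if (burn_in < 0 || burn_in >= n_iter)
    stop("need 0 <= burn_in < n_iter");
  const int n_keep = n_iter - burn_in;
  NumericMatrix pi_draws(n_keep, K);
  NumericMatrix z_counts(N, K);
  std::vector<double> pi(K, 1.0 / K), w(K);
  std::vector<int> z(N), counts(K);

  for (int it = 0; it < n_iter; ++it) {
    std::fill(counts.begin(), counts.end(), 0);
    for (int i = 0; i < N; ++i) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        w[k] = pi[k] * expL(i, k);
        tot += w[k];
      }
      double u = R::runif(0.0, tot);
      int k = 0;
      double cum = w[0];
      while (u > cum && k < K - 1) cum += w[++k];
      z[i] = k;
      ++counts[k];
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      pi[k] = R::rgamma(zeta[k] + counts[k], 1.0);
      s += pi[k];
    }
    for (int k = 0; k < K; ++k) pi[k] /= s;
    if (it >= burn_in) {
      const int row = it - burn_in;
      for (int k = 0; k < K; ++k) pi_draws(row, k) = pi[k];
      for (int i = 0; i < N; ++i) z_counts(i, z[i]) += 1.0;
    }
  }
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) z_counts(i, k) /= n_keep;
  return List::create(_["pi_draws"] = pi_draws, _["z_freq"] = z_counts);
}
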