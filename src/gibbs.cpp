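#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for one LD window under the point-normal prior.
//
// Model: marginal effects beta_hat relate to joint effects b through the
// window LD matrix R; conditionally on the other effects, the residualized
// marginal effect beta_tilde_j = beta_hat_j - sum_{k != j} R_jk b_k is
// treated as N(b_j, 1/n). Prior: b_j = 0 with probability 1 - rho, else
// N(0, sigma2). Each sweep updates every variant: compute the posterior
// inclusion probability from the two marginal likelihoods, then sample the
// effect from its conjugate normal posterior if included. The returned
// weight is the posterior mean of the sampled effects over post-burn-in
// sweeps (zeros included). Uses R's RNG, so results are reproducible under
// set.seed() on the R side.
// [[Rcpp::export]]
List gibbs_window_cpp(NumericMatrix R, NumericVector beta_hat, double n,
                      double rho, double sigma2, int n_iter, int burnin) {
  const int m = beta_hat.size();
  std::vector<double> b(m, 0.0), acc(m, 0.0), inc(m, 0.0);
  const double v_post = 1.0 / (1.0 / sigma2 + n);
  const double post_sd = std::sqrt(v_post);
  const double s1 = std::sqrt(sigma2 + 1.0 / n);
  const double s0 = std::sqrt(1.0 / n);
  const double log_rho = std::log(rho);
  const bool spike = rho < 1.0;
  const double log_1mrho = spike ? std::log(1.0 - rho) : 0.0;

  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < m; ++j) {
      double rb = 0.0;
      for (int k = 0; k < m; ++k) rb += R(k, j) * b[k];
      const double bt = beta_hat[j] - (rb - b[j]);
      double pip = 1.0;
      if (spike) {
        const double l1 = log_rho + R::dnorm(bt, 0.0, s1, 1);
        const double l0 = log_1mrho + R::dnorm(bt, 0.0, s0, 1);
        pip = 1.0 / (1.0 + std::exp(l0 - l1));
      }
      if (!spike || R::unif_rand() < pip) {
        b[j] = v_post * n * bt + post_sd * R::norm_rand();
        if (it >= burnin) inc[j] += 1.0;
      } else {
        b[j] = 0.0;
      }
    }
    if (it >= burnin) {
      for (int j = 0; j < m; ++j) acc[j] += b[j];
    }
  }
  const double kept = n_iter - burnin;
  NumericVector w(m), freq(m);
  for (int j = 0; j < m; ++j) {
    w[j] = acc[j] / kept;
    freq[j] = inc[j] / kept;
  }
  return List::create(_["weight"] = w, _["inclusion"] = freq);
}
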