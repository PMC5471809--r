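#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log marginal likelihood ratio (effect fitted vs not) for one locus with
// the allele-substitution effect integrated out under alpha ~ N(0, s2)
static inline double log_ml_ratio(double rhs, double c, double sig2e,
                                  double s2) {
  double denom = c * s2 + sig2e;
  return 0.5 * std::log(sig2e / denom) +
         s2 * rhs * rhs / (2.0 * sig2e * denom);
}

// BayesB sampler: mixture prior with point mass at zero (prior exclusion
// probability pi) and locus-specific variances from a scaled inverse
// chi-square prior. Per sweep: Gibbs update of the mean, joint
// Metropolis-Hastings update of (delta_j, sigma2_j) per locus with the
// effect marginalized (proposal drawn from the prior), Gibbs update of the
// effect given inclusion, then the residual variance from its scaled
// inverse chi-square full conditional. Uses R's RNG so set.seed() in R
// makes chains reproducible. fix_var > 0 freezes every locus variance at
// that value (conjugate ridge limit); fix_sig2e > 0 freezes the residual
// variance.
// [[Rcpp::export(name = ".bayesb_mcmc")]]
List bayesb_mcmc(const arma::mat& W, const arma::vec& y, double pi,
                 double nu_alpha, double s2_alpha, double nu_e, double s2_e,
                 int n_iter, int burn_in, int sample_every, double fix_var,
                 double fix_sig2e) {
  const int n = W.n_rows, M = W.n_cols;
  arma::vec c(M);
  for (int j = 0; j < M; ++j) c[j] = arma::dot(W.col(j), W.col(j));

  arma::vec alpha(M, arma::fill::zeros), s2(M, arma::fill::zeros);
  arma::ivec delta(M, arma::fill::zeros);
  double mu = arma::mean(y);
  arma::vec e = y - mu;
  double sig2e = fix_sig2e > 0 ? fix_sig2e
                               : (nu_e > 2 ? s2_e * nu_e / (nu_e - 2.0)
                                           : arma::var(e) * 0.5);
  if (sig2e <= 0) sig2e = arma::var(e);

  const int n_keep = n_iter - burn_in;
  const int n_stored = (n_keep + sample_every - 1) / sample_every;
  arma::vec sum_alpha(M, arma::fill::zeros), sum_delta(M, arma::fill::zeros);
  arma::mat alpha_samples(n_stored, M, arma::fill::zeros);
  arma::vec sig2e_chain(n_iter), loglik_chain(n_iter), fitted_chain(n_iter);
  double sum_mu = 0.0, n_prop = 0.0, n_acc = 0.0;
  int stored = 0;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // overall mean
    double mu_new = mu + arma::mean(e) +
                    std::sqrt(sig2e / n) * R::norm_rand();
    e -= (mu_new - mu);
    mu = mu_new;

    int n_fit = 0;
    for (int j = 0; j < M; ++j) {
      if (c[j] <= 0) continue;  // monomorphic after centring
      double old_contrib = delta[j] ? alpha[j] : 0.0;
      double rhs = arma::dot(W.col(j), e) + c[j] * old_contrib;

      // joint MH on (delta_j, sigma2_j), proposal from the prior
      int delta_star = (R::unif_rand() < 1.0 - pi) ? 1 : 0;
      double s2_star = 0.0;
      if (delta_star == 1)
        s2_star = (fix_var > 0) ? fix_var
                                : nu_alpha * s2_alpha / R::rchisq(nu_alpha);
      double logl_cur = delta[j] ? log_ml_ratio(rhs, c[j], sig2e, s2[j]) : 0.0;
      double logl_star = delta_star ? log_ml_ratio(rhs, c[j], sig2e, s2_star)
                                    : 0.0;
      n_prop += 1.0;
      if (std::log(R::unif_rand()) < logl_star - logl_cur) {
        delta[j] = delta_star;
        s2[j] = s2_star;
        n_acc += 1.0;
      }

      // effect given inclusion
      if (delta[j] == 1 && s2[j] > 0) {
        double lambda = sig2e / s2[j];
        double v = sig2e / (c[j] + lambda);
        alpha[j] = rhs / (c[j] + lambda) + std::sqrt(v) * R::norm_rand();
        ++n_fit;
      } else {
        alpha[j] = 0.0;
        delta[j] = 0;
      }
      double new_contrib = delta[j] ? alpha[j] : 0.0;
      if (new_contrib != old_contrib) e -= W.col(j) * (new_contrib - old_contrib);
    }

    double sse = arma::dot(e, e);
    if (!std::isfinite(sse))
      stop("non-finite residual sum of squares at iteration %d", it + 1);
    if (fix_sig2e <= 0)
      sig2e = (sse + nu_e * s2_e) / R::rchisq(nu_e + n);
    sig2e_chain[it] = sig2e;
    loglik_chain[it] = -0.5 * (n * std::log(2.0 * M_PI * sig2e) + sse / sig2e);
    fitted_chain[it] = n_fit;

    if (it >= burn_in) {
      int k = it - burn_in;
      for (int j = 0; j < M; ++j) {
        if (delta[j]) {
          sum_alpha[j] += alpha[j];
          sum_delta[j] += 1.0;
        }
      }
      sum_mu += mu;
      if (k % sample_every == 0 && stored < n_stored) {
        for (int j = 0; j < M; ++j)
          alpha_samples(stored, j) = delta[j] ? alpha[j] : 0.0;
        ++stored;
      }
    }
  }

  return List::create(
    _["alpha_hat"] = sum_alpha / n_keep,
    _["delta_freq"] = sum_delta / n_keep,
    _["mu_hat"] = sum_mu / n_keep,
    _["alpha_samples"] = alpha_samples,
    _["sigma_e2_chain"] = sig2e_chain,
    _["loglik_chain"] = loglik_chain,
    _["n_fitted_chain"] = fitted_chain,
    _["accept_rate"] = n_prop > 0 ? n_acc / n_prop : NA_REAL);
}
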