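#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for Bayes A / Bayes B whole-genome regression.
//
// Model: y = 1*mu + X a + e,  a_j | sigma2_j ~ N(0, sigma2_j),
// sigma2_j ~ scaled-inv-chisq(nu, S), e ~ N(0, I sigma2_e),
// sigma2_e ~ scaled-inv-chisq(nu_e, S_e).
// Bayes B puts a point mass at a_j = 0 with prior P(nonzero) = pi_nonzero;
// the indicator is updated jointly with the effect by integrating the
// effect out of the two-state comparison, so the chain cannot get stuck on
// the point mass.
//
// Uses R's RNG throughout, so results are reproducible under set.seed().
// fix_sigma2e > 0 pins the residual variance (used by prior-conformance
// checks); trace_col (1-based) returns the post-burn-in sigma2_j chain for
// one column.
// [[Rcpp::export]]
List gibbs_bayes(const NumericMatrix& X, const NumericVector& y,
                 const bool bayesB, const double nu, const double S,
                 const double pi_nonzero, const int n_iter,
                 const int burn_in, const int thin,
                 const double nu_e, const double S_e,
                 const double fix_sigma2e, const int trace_col) {
  const int n = X.nrow(), m = X.ncol();
  std::vector<double> a(m, 0.0), s2(m), xtx(m);
  std::vector<int> delta(m, 1);
  const double prior_mean_s2 = nu > 2 ? nu * S / (nu - 2) : S;
  for (int j = 0; j < m; ++j) {
    s2[j] = prior_mean_s2;
    double c = 0.0;
    for (int i = 0; i < n; ++i) c += X(i, j) * X(i, j);
    xtx[j] = c;
  }
  double mu = mean(y);
  double s2e = fix_sigma2e > 0 ? fix_sigma2e : var(y) / 2.0;
  std::vector<double> e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;

  const double log_prior_odds = pi_nonzero < 1.0
      ? std::log(pi_nonzero) - std::log(1.0 - pi_nonzero) : 0.0;
  // accumulators
  double sum_mu = 0.0, sum_s2e = 0.0;
  std::vector<double> sum_a(m, 0.0), sum_s2(m, 0.0), sum_delta(m, 0.0);
  int n_samples = 0;
  std::vector<double> trace;

  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    // overall mean
    double ebar = 0.0;
    for (int i = 0; i < n; ++i) ebar += e[i];
    ebar /= n;
    double mu_new = mu + ebar + R::rnorm(0.0, std::sqrt(s2e / n));
    for (int i = 0; i < n; ++i) e[i] -= (mu_new - mu);
    mu = mu_new;

    // effects
    for (int j = 0; j < m; ++j) {
      const double c = xtx[j];
      if (c <= 0) { a[j] = 0.0; delta[j] = 0; continue; }
      double r = a[j] * c;                 // x_j' (e + x_j a_j)
      for (int i = 0; i < n; ++i) r += X(i, j) * e[i];
      const double lambda = s2e / s2[j];
      double a_new = 0.0;
      int d_new = 1;
      if (bayesB && pi_nonzero < 1.0) {
        const double log_odds = log_prior_odds
          + 0.5 * std::log(lambda / (c + lambda))
          + r * r / (2.0 * s2e * (c + lambda));
        const double p1 = 1.0 / (1.0 + std::exp(-log_odds));
        d_new = (R::unif_rand() < p1) ? 1 : 0;
      }
      if (d_new == 1) {
        const double post_var = s2e / (c + lambda);
        a_new = r / (c + lambda) + R::rnorm(0.0, std::sqrt(post_var));
      }
      if (a_new != a[j]) {
        const double diff = a[j] - a_new;
        for (int i = 0; i < n; ++i) e[i] += X(i, j) * diff;
      }
      a[j] = a_new;
      delta[j] = d_new;

      // per-column variance: scaled-inv-chisq full conditional
      if (d_new == 1)
        s2[j] = (nu * S + a[j] * a[j]) / R::rchisq(nu + 1.0);
      else
        s2[j] = nu * S / R::rchisq(nu);     // prior draw when excluded
    }

    // residual variance
    if (fix_sigma2e <= 0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = (sse + nu_e * S_e) / R::rchisq((double) n + nu_e);
    }

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      ++n_samples;
      sum_mu += mu;
      sum_s2e += s2e;
      for (int j = 0; j < m; ++j) {
        sum_a[j] += a[j];
        sum_s2[j] += s2[j];
        sum_delta[j] += delta[j];
      }
      if (trace_col >= 1) trace.push_back(s2[trace_col - 1]);
    }
  }

  NumericVector effects(m), var_effects(m), inclusion(m);
  for (int j = 0; j < m; ++j) {
    effects[j] = sum_a[j] / n_samples;
    var_effects[j] = sum_s2[j] / n_samples;
    inclusion[j] = sum_delta[j] / n_samples;
  }
  return List::create(
      _["mu"] = sum_mu / n_samples,
      _["effects"] = effects,
      _["var_effects"] = var_effects,
      _["inclusion"] = inclusion,
      _["sigma2_e"] = sum_s2e / n_samples,
      _["n_samples"] = n_samples,
      _["sigma2_trace"] = wrap(trace));
}
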