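#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the BayesB marker-effect model:
//   y = mu + X beta + e,  e ~ N(0, sigma2_e I)
//   beta_j = 0 with probability pi, else N(0, sigma2_j)
//   sigma2_j ~ scaled-inv-chisq(df_b, scale_b)   (marker-specific variance)
//   sigma2_e ~ scaled-inv-chisq(df_e, scale_e)
// The indicator is sampled with the effect integrated out conditional on
// sigma2_j; excluded markers redraw sigma2_j from its prior each sweep.
// All randomness comes from R's RNG so set.seed() controls the chain.

// [[Rcpp::export]]
List bayesb_gibbs(NumericVector y, NumericMatrix X,
                  double pi, double df_b, double scale_b,
                  double df_e, double scale_e,
                  int n_iter, int burn_in, int thin) {
  int n = y.size(), m = X.ncol();
  NumericVector xtx(m);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double mu = mean(y);
  double sigma2_e = scale_e;
  NumericVector beta(m, 0.0), s2(m, scale_b);
  IntegerVector delta(m, 0);
  NumericVector r(n);
  for (int i = 0; i < n; ++i) r[i] = y[i] - mu;

  NumericVector beta_sum(m, 0.0), incl_sum(m, 0.0);
  double mu_sum = 0.0, s2e_sum = 0.0;
  int n_samp = 0;

  for (int it = 0; it < n_iter; ++it) {
    // overall mean
    double rbar = mean(r);
    double mu_new = mu + rbar + R::rnorm(0.0, std::sqrt(sigma2_e / n));
    for (int i = 0; i < n; ++i) r[i] -= (mu_new - mu);
    mu = mu_new;

    for (int j = 0; j < m; ++j) {
      double bj = beta[j];
      if (delta[j] == 1) {
        for (int i = 0; i < n; ++i) r[i] += X(i, j) * bj;
        s2[j] = (df_b * scale_b + bj * bj) / R::rchisq(df_b + 1.0);
      } else {
        s2[j] = df_b * scale_b / R::rchisq(df_b);
      }
      double c = xtx[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * r[i];

      double p_in;
      if (pi <= 0.0) {
        p_in = 1.0;
      } else if (pi >= 1.0) {
        p_in = 0.0;
      } else {
        double v = c * s2[j] / sigma2_e;
        double logBF = std::log((1.0 - pi) / pi) - 0.5 * std::log1p(v) +
          0.5 * rhs * rhs * s2[j] / (sigma2_e * (sigma2_e + c * s2[j]));
        p_in = 1.0 / (1.0 + std::exp(-logBF));
      }
      if (R::runif(0.0, 1.0) < p_in) {
        double prec = c / sigma2_e + 1.0 / s2[j];
        double mean_b = (rhs / sigma2_e) / prec;
        double bnew = mean_b + R::rnorm(0.0, 1.0) / std::sqrt(prec);
        for (int i = 0; i < n; ++i) r[i] -= X(i, j) * bnew;
        beta[j] = bnew;
        delta[j] = 1;
      } else {
        beta[j] = 0.0;
        delta[j] = 0;
      }
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += r[i] * r[i];
    sigma2_e = (df_e * scale_e + sse) / R::rchisq(df_e + n);

    if (it >= burn_in && ((it - burn_in) % thin == 0)) {
      for (int j = 0; j < m; ++j) {
        beta_sum[j] += beta[j];
        incl_sum[j] += delta[j];
      }
      mu_sum += mu;
      s2e_sum += sigma2_e;
      ++n_samp;
    }
  }

  NumericVector beta_hat(m), incl(m);
  for (int j = 0; j < m; ++j) {
    beta_hat[j] = beta_sum[j] / n_samp;
    incl[j] = incl_sum[j] / n_samp;
  }
  return List::create(_["mu"] = mu_sum / n_samp,
                      _["marker_effects"] = beta_hat,
                      _["inclusion_prob"] = incl,
                      _["sigma2_e"] = s2e_sum / n_samp,
                      _["n_samples"] = n_samp);
}
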