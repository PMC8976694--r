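#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for BayesC-pi whole-genome regression:
//   y = 1*mu + sum_k z_k a_k + e,  a_k zero with prior probability pi,
//   nonzero effects share a common variance sigma_a2; pi ~ Uniform(0,1).
// Missing responses (miss, 0-based) are imputed by data augmentation each
// iteration so the sampler can be used directly under cross-validation
// masking. Scaled-inverse-chi-square priors (df nu, scales Se, Sa) on the
// variances. Uses R's RNG, so set.seed() upstream controls the chain.
// [[Rcpp::export]]
List bayescpi_gibbs(NumericVector y, NumericMatrix M, IntegerVector miss,
                    int iterations, int burn_in, int thinning,
                    double nu, double Se, double Sa) {
  const int n = M.nrow(), m = M.ncol();
  std::vector<double> ycur(y.begin(), y.end());
  std::vector<double> a(m, 0.0), g(n, 0.0), e(n);
  std::vector<int> delta(m, 0);
  std::vector<double> zz(m);
  for (int k = 0; k < m; ++k) {
    double s = 0.0;
    const double* zk = &M(0, k);
    for (int i = 0; i < n; ++i) s += zk[i] * zk[i];
    zz[k] = std::max(s, 1e-12);
  }

  // start missing entries at the observed mean
  double mobs = 0.0; int nobs = 0;
  std::vector<bool> is_miss(n, false);
  for (int j = 0; j < miss.size(); ++j) is_miss[miss[j]] = true;
  for (int i = 0; i < n; ++i) if (!is_miss[i]) { mobs += ycur[i]; ++nobs; }
  mobs = (nobs > 0) ? mobs / nobs : 0.0;
  for (int j = 0; j < miss.size(); ++j) ycur[miss[j]] = mobs;

  double mu = mobs, pi = 0.5;
  double sigma_e2 = std::max(Se, 1e-10), sigma_a2 = std::max(Sa, 1e-12);
  for (int i = 0; i < n; ++i) e[i] = ycur[i] - mu;

  int kept = 0;
  const int nkeep = (iterations - burn_in) / thinning + 1;
  NumericVector u_sum(n), a_sum(m), inc_sum(m);
  std::vector<double> s_h2, s_pi, s_se2, s_sa2, s_nin, s_mu;
  s_h2.reserve(nkeep);

  for (int it = 1; it <= iterations; ++it) {
    // intercept
    double r = 0.0;
    for (int i = 0; i < n; ++i) r += e[i];
    double mu_new = mu + r / n + norm_rand() * std::sqrt(sigma_e2 / n);
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // marker effects with spike-and-slab indicator
    int m_in = 0;
    double ss_a = 0.0;
    const double log_se = std::log(sigma_e2), log_sa = std::log(sigma_a2);
    for (int k = 0; k < m; ++k) {
      const double* zk = &M(0, k);
      double old = a[k];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += zk[i] * e[i];
      rhs += zz[k] * old;
      double C = zz[k] + sigma_e2 / sigma_a2;
      double logodds = std::log((1.0 - pi) / pi)
        + 0.5 * (log_se - log_sa - std::log(C))
        + 0.5 * rhs * rhs / (sigma_e2 * C);
      double p_in = 1.0 / (1.0 + std::exp(-logodds));
      double anew = 0.0;
      int din = (unif_rand() < p_in) ? 1 : 0;
      if (din) {
        anew = rhs / C + norm_rand() * std::sqrt(sigma_e2 / C);
        ++m_in;
        ss_a += anew * anew;
      }
      delta[k] = din;
      a[k] = anew;
      if (anew != old) {
        double d = anew - old;
        for (int i = 0; i < n; ++i) { g[i] += zk[i] * d; e[i] -= zk[i] * d; }
      }
    }

    // pi (prob. of zero effect), uniform prior -> Beta posterior
    pi = R::rbeta(m - m_in + 1.0, m_in + 1.0);
    pi = std::min(std::max(pi, 1e-8), 1.0 - 1e-8);

    // variances
    sigma_a2 = (ss_a + nu * Sa) / R::rchisq(nu + m_in);
    double ss_e = 0.0;
    for (int i = 0; i < n; ++i) ss_e += e[i] * e[i];
    sigma_e2 = (ss_e + nu * Se) / R::rchisq(nu + n);

    // impute masked responses
    for (int j = 0; j < miss.size(); ++j) {
      int i = miss[j];
      double ynew = mu + g[i] + norm_rand() * std::sqrt(sigma_e2);
      e[i] += ynew - ycur[i];
      ycur[i] = ynew;
    }

    if (it > burn_in && (it - burn_in) % thinning == 0) {
      ++kept;
      double gm = 0.0;
      for (int i = 0; i < n; ++i) gm += g[i];
      gm /= n;
      double vg = 0.0;
      for (int i = 0; i < n; ++i) vg += (g[i] - gm) * (g[i] - gm);
      vg /= n;
      s_h2.push_back(vg / (vg + sigma_e2));
      s_pi.push_back(pi);
      s_se2.push_back(sigma_e2);
      s_sa2.push_back(sigma_a2);
      s_nin.push_back((double)m_in);
      s_mu.push_back(mu);
      for (int i = 0; i < n; ++i) u_sum[i] += g[i];
      for (int k = 0; k < m; ++k) {
        a_sum[k] += a[k];
        inc_sum[k] += delta[k];
      }
    }
  }
  if (kept == 0) stop("bayescpi_gibbs: no retained samples");

  for (int i = 0; i < n; ++i) u_sum[i] /= kept;
  for (int k = 0; k < m; ++k) { a_sum[k] /= kept; inc_sum[k] /= kept; }
  return List::create(
    _["u"] = u_sum, _["effects"] = a_sum, _["inclusion"] = inc_sum,
    _["samples"] = DataFrame::create(
      _["h2"] = s_h2, _["pi"] = s_pi, _["sigma_e2"] = s_se2,
      _["sigma_a2"] = s_sa2, _["n_included"] = s_nin, _["mu"] = s_mu),
    _["kept"] = kept);
}
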