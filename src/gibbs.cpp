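#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One draw from an inverse-Gaussian(mu, lambda) distribution
// (Michael, Schucany & Haas 1976), using R's RNG stream.
static double rinvgauss1(double mu, double lambda) {
  double nu = norm_rand();
  double y = nu * nu;
  double x = mu + 0.5 * mu * mu * y / lambda -
    0.5 * (mu / lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;  // numerical underflow guard
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// sigma2 ~ scaled-inverse-chi-square with df degrees of freedom and
// scale *sum* s (i.e. sigma2 = s / chisq_df).
static double rscinvchisq(double df, double s) {
  return s / R::rchisq(df);
}

// Single-site Gibbs sampler for
//   y = mu + sum_b X_b beta_b + e,   e ~ N(0, sigma2e I)
// with per-block priors: ridge  beta_j ~ N(0, sigma2b[b]),
//                        lasso  beta_j | tau2_j ~ N(0, tau2_j * sigma2e),
//                               1/tau2_j ~ InvGauss(sqrt(lambda2*sigma2e/beta_j^2), lambda2),
//                               lambda2 ~ Gamma(shape, rate) (one per lasso block).
// Variances sigma2e and sigma2b carry scaled-inv-chisq(nu, S) priors.
// Coefficients are updated coordinate-wise in fixed column order; the
// residual vector is maintained incrementally.
// [[Rcpp::export]]
List gibbs_sampler_cpp(NumericVector y, List Xlist, IntegerVector prior_code,
                       int n_iter, int burn_in, int thin,
                       double nu, double S,
                       double lambda_shape, double lambda_rate,
                       double mu0, List beta0, double sigma2e0,
                       NumericVector sigma2b0, NumericVector lambda20,
                       List tau20,
                       bool update_mu, bool update_beta,
                       bool update_sigma2e, bool update_prior,
                       bool store_tau2) {
  const int n = y.size();
  const int nb = Xlist.size();
  const int n_keep = (n_iter - burn_in) / thin;

  std::vector<NumericMatrix> X(nb);
  std::vector<const double*> Xp(nb);
  std::vector<NumericVector> beta(nb), tau2(nb), xtx(nb);
  std::vector<int> p(nb);
  int p_lasso_total = 0;
  for (int b = 0; b < nb; ++b) {
    X[b] = as<NumericMatrix>(Xlist[b]);
    Xp[b] = X[b].begin();
    p[b] = X[b].ncol();
    beta[b] = clone(as<NumericVector>(beta0[b]));
    xtx[b] = NumericVector(p[b]);
    for (int j = 0; j < p[b]; ++j) {
      double s = 0.0;
      const double* xj = Xp[b] + (std::size_t)j * n;
      for (int i = 0; i < n; ++i) s += xj[i] * xj[i];
      xtx[b][j] = s;
    }
    if (prior_code[b] == 1) {
      tau2[b] = clone(as<NumericVector>(tau20[b]));
      p_lasso_total += p[b];
    }
  }

  double mu = mu0, sigma2e = sigma2e0;
  NumericVector sigma2b = clone(sigma2b0), lambda2 = clone(lambda20);

  // residual e = y - mu - sum_b X_b beta_b
  NumericVector e(n);
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
  for (int b = 0; b < nb; ++b)
    for (int j = 0; j < p[b]; ++j) {
      double bj = beta[b][j];
      if (bj != 0.0) {
        const double* xj = Xp[b] + (std::size_t)j * n;
        for (int i = 0; i < n; ++i) e[i] -= xj[i] * bj;
      }
    }

  NumericVector mu_draws(n_keep), sigma2e_draws(n_keep), loglik_draws(n_keep);
  NumericMatrix sigma2b_draws(n_keep, nb), lambda2_draws(n_keep, nb);
  List beta_draws(nb), tau2_draws(nb);
  for (int b = 0; b < nb; ++b) {
    beta_draws[b] = NumericMatrix(n_keep, p[b]);
    if (prior_code[b] == 1 && store_tau2)
      tau2_draws[b] = NumericMatrix(n_keep, p[b]);
  }

  const double LOG2PI = std::log(2.0 * M_PI);
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    if (update_mu) {
      double se = 0.0;
      for (int i = 0; i < n; ++i) se += e[i];
      double mu_new = R::rnorm(se / n + mu, std::sqrt(sigma2e / n));
      double d = mu_new - mu;
      for (int i = 0; i < n; ++i) e[i] -= d;
      mu = mu_new;
    }

    if (update_beta) {
      double* ep = e.begin();
      for (int b = 0; b < nb; ++b) {
        const bool lasso = (prior_code[b] == 1);
        for (int j = 0; j < p[b]; ++j) {
          const double* xj = Xp[b] + (std::size_t)j * n;
          double prior_var = lasso ? tau2[b][j] * sigma2e : sigma2b[b];
          double rhs = 0.0;
          for (int i = 0; i < n; ++i) rhs += xj[i] * ep[i];
          rhs += xtx[b][j] * beta[b][j];
          double c = xtx[b][j] / sigma2e + 1.0 / prior_var;
          double mean = rhs / (sigma2e * c);
          double b_new = R::rnorm(mean, std::sqrt(1.0 / c));
          double d = b_new - beta[b][j];
          if (d != 0.0)
            for (int i = 0; i < n; ++i) ep[i] -= xj[i] * d;
          beta[b][j] = b_new;
        }
      }
    }

    if (update_prior) {
      for (int b = 0; b < nb; ++b) {
        if (prior_code[b] == 0) {
          double ssb = 0.0;
          for (int j = 0; j < p[b]; ++j) ssb += beta[b][j] * beta[b][j];
          sigma2b[b] = rscinvchisq(p[b] + nu, S + ssb);
        } else {
          double sum_tau2 = 0.0;
          for (int j = 0; j < p[b]; ++j) {
            double b2 = beta[b][j] * beta[b][j];
            if (b2 < 1e-10) b2 = 1e-10;  // keeps the IG mean finite
            double m_ig = std::sqrt(lambda2[b] * sigma2e / b2);
            double inv_tau2 = rinvgauss1(m_ig, lambda2[b]);
            tau2[b][j] = 1.0 / inv_tau2;
            sum_tau2 += tau2[b][j];
          }
          lambda2[b] = R::rgamma(lambda_shape + p[b],
                                 1.0 / (lambda_rate + 0.5 * sum_tau2));
        }
      }
    }

    if (update_sigma2e) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      double extra = 0.0;
      for (int b = 0; b < nb; ++b)
        if (prior_code[b] == 1)
          for (int j = 0; j < p[b]; ++j)
            extra += beta[b][j] * beta[b][j] / tau2[b][j];
      sigma2e = rscinvchisq(n + nu + p_lasso_total, S + sse + extra);
    }

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      mu_draws[keep] = mu;
      sigma2e_draws[keep] = sigma2e;
      loglik_draws[keep] = -0.5 * n * (LOG2PI + std::log(sigma2e)) -
        0.5 * sse / sigma2e;
      for (int b = 0; b < nb; ++b) {
        NumericMatrix bd = as<NumericMatrix>(beta_draws[b]);
        for (int j = 0; j < p[b]; ++j) bd(keep, j) = beta[b][j];
        sigma2b_draws(keep, b) = (prior_code[b] == 0) ? sigma2b[b] : NA_REAL;
        lambda2_draws(keep, b) = (prior_code[b] == 1) ? lambda2[b] : NA_REAL;
        if (prior_code[b] == 1 && store_tau2) {
          NumericMatrix td = as<NumericMatrix>(tau2_draws[b]);
          for (int j = 0; j < p[b]; ++j) td(keep, j) = tau2[b][j];
        }
      }
      ++keep;
    }
  }

  return List::create(_["mu"] = mu_draws,
                      _["beta"] = beta_draws,
                      _["sigma2_e"] = sigma2e_draws,
                      _["sigma2_beta"] = sigma2b_draws,
                      _["lambda2"] = lambda2_draws,
                      _["tau2"] = tau2_draws,
                      _["loglik"] = loglik_draws);
}
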