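// Gibbs sampler core for the heteroscedastic bivariate-normal
// repeated-measures model: per group k,
//   y_i ~ N(mu, Sigma),  mu_j ~ N(0, tau2) independently,
//   Sigma ~ inverse-Wishart(S0, nu0)  with density
//   |Sigma|^-(nu0+p+1)/2 exp(-tr(S0 Sigma^-1)/2),  p = 2.
// Groups are conditionally independent, so each group runs its own chain.
// Uses R's RNG (norm_rand / rchisq) so set.seed() on the R side makes
// every draw reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cholesky (lower) with a diagonal ridge fallback for nearly singular
// scale matrices accumulated from degenerate data. Returns the number of
// jitter attempts used via `jitters`.
static arma::mat safe_chol_lower(arma::mat S, int &jitters) {
  arma::mat L;
  S = 0.5 * (S + S.t()); // exact symmetry despite rounding in the inverses
  double ridge = 1e-10 * (S(0, 0) + S(1, 1) + 1e-300);
  for (int k = 0; k < 12; ++k) {
    if (arma::chol(L, S, "lower")) return L;
    S.diag() += ridge;
    ridge *= 10.0;
    ++jitters;
  }
  stop("covariance scale matrix is numerically singular");
  return L; // not reached
}

// W ~ Wishart_2(df, V) via the Bartlett decomposition; requires df > 1.
static arma::mat rwishart2(double df, const arma::mat &V, int &jitters) {
  arma::mat L = safe_chol_lower(V, jitters);
  arma::mat A(2, 2, arma::fill::zeros);
  A(0, 0) = std::sqrt(R::rchisq(df));
  A(1, 1) = std::sqrt(R::rchisq(df - 1.0));
  A(1, 0) = norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

static arma::mat inv2(const arma::mat &S) {
  double off = 0.5 * (S(0, 1) + S(1, 0)); // keep the inverse exactly symmetric
  double det = S(0, 0) * S(1, 1) - off * off;
  arma::mat out(2, 2);
  out(0, 0) = S(1, 1);
  out(1, 1) = S(0, 0);
  out(0, 1) = -off;
  out(1, 0) = -off;
  return out / det;
}

// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(const arma::mat &y, int n_iter, int burn_in, int thin,
                     double mean_prior_var, const arma::mat &wishart_scale,
                     double wishart_df, bool fix_sigma,
                     const arma::mat &sigma_fixed) {
  const int n = y.n_rows;
  int jitters = 0;

  arma::vec ybar(2, arma::fill::zeros);
  if (n > 0) ybar = arma::mean(y, 0).t();

  // initial Sigma: sample covariance when available, else the prior scale
  arma::mat sigma(2, 2);
  if (fix_sigma) {
    sigma = sigma_fixed;
  } else if (n >= 2) {
    sigma = arma::cov(y);
    // a rank-deficient sample covariance (tiny n, degenerate data) would
    // poison the first precision inversion; start from the prior scale then
    double det = sigma(0, 0) * sigma(1, 1) - sigma(0, 1) * sigma(1, 0);
    double tr = sigma(0, 0) + sigma(1, 1);
    if (!(det > 1e-10 * tr * tr) || !sigma.is_finite()) sigma = wishart_scale;
  } else {
    sigma = wishart_scale;
  }

  const int n_keep = (n_iter - burn_in) / thin;
  arma::mat mu_draws(n_keep, 2);
  arma::mat sigma_draws(n_keep, 3);

  arma::vec mu(2, arma::fill::zeros);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // mu | Sigma, y : precision n*Sigma^-1 + I/tau2
    arma::mat siginv = inv2(sigma);
    arma::mat prec = double(n) * siginv;
    prec(0, 0) += 1.0 / mean_prior_var;
    prec(1, 1) += 1.0 / mean_prior_var;
    arma::mat V = inv2(prec);
    arma::vec m(2, arma::fill::zeros);
    if (n > 0) m = V * (double(n) * (siginv * ybar));
    arma::mat Lv = safe_chol_lower(V, jitters);
    arma::vec z(2);
    z(0) = norm_rand();
    z(1) = norm_rand();
    mu = m + Lv * z;

    // Sigma | mu, y : inverse-Wishart(S0 + sum (y_i - mu)(y_i - mu)', nu0 + n)
    if (!fix_sigma) {
      arma::mat Spost = wishart_scale;
      for (int i = 0; i < n; ++i) {
        arma::vec d = y.row(i).t() - mu;
        Spost += d * d.t();
      }
      arma::mat W = rwishart2(wishart_df + double(n), inv2(Spost), jitters);
      sigma = inv2(W);
    }

    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      mu_draws(kept, 0) = mu(0);
      mu_draws(kept, 1) = mu(1);
      sigma_draws(kept, 0) = sigma(0, 0);
      sigma_draws(kept, 1) = sigma(0, 1);
      sigma_draws(kept, 2) = sigma(1, 1);
      ++kept;
    }
  }

  return List::create(_["mu"] = mu_draws, _["sigma"] = sigma_draws,
                      _["jitters"] = jitters);
}
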