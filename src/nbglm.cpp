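// IRLS fitting of negative-binomial GLMs (log link) for a matrix of genes
// sharing one design. Returns coefficients, fitted means, residual deviance
// and the Cox-Reid adjustment 0.5*log det(X' W X) per gene.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double ETA_LO = -30.0, ETA_HI = 30.0;

// NB unit deviance, phi >= 0 (phi == 0 is the Poisson limit).
static double nb_deviance(const arma::rowvec& y, const arma::rowvec& mu, double phi) {
  double dev = 0.0;
  const arma::uword n = y.n_elem;
  for (arma::uword j = 0; j < n; ++j) {
    double yj = y[j], mj = std::max(mu[j], 1e-10);
    double d;
    if (phi > 0) {
      double a = (yj > 0) ? yj * std::log(yj / mj) : 0.0;
      d = a - (yj + 1.0 / phi) * std::log((1.0 + phi * yj) / (1.0 + phi * mj));
    } else {
      double a = (yj > 0) ? yj * std::log(yj / mj) : 0.0;
      d = a - (yj - mj);
    }
    dev += 2.0 * d;
  }
  return dev;
}

// [[Rcpp::export(name = ".nbglm_fit_cpp")]]
List nbglm_fit_cpp(const arma::mat& counts,     // G x n
                   const arma::mat& X,          // n x p
                   const arma::mat& offset,     // G x n (already expanded)
                   const arma::vec& dispersion, // length G
                   double tol = 1e-8,
                   int maxit = 50) {
  const arma::uword G = counts.n_rows, n = counts.n_cols, p = X.n_cols;
  arma::mat beta(G, p, arma::fill::zeros);
  arma::mat mu(G, n, arma::fill::zeros);
  arma::vec deviance(G), cr_adj(G);
  arma::ivec iters(G), converged(G);

  for (arma::uword g = 0; g < G; ++g) {
    arma::rowvec y = counts.row(g), o = offset.row(g);
    double phi = dispersion[g];

    // initialize beta by unweighted least squares of damped log counts on X,
    // so the step-halving baseline is a point the model can represent
    arma::rowvec mug(n), etag(n);
    arma::vec z0(n);
    for (arma::uword j = 0; j < n; ++j)
      z0[j] = std::log(std::max(y[j], 1.0 / 6.0)) - o[j];
    arma::mat XtX = X.t() * X;
    XtX.diag() += 1e-10;
    arma::vec b;
    if (!arma::solve(b, XtX, X.t() * z0, arma::solve_opts::likely_sympd))
      b.zeros(p);
    {
      arma::vec eta_lin = X * b;
      for (arma::uword j = 0; j < n; ++j) {
        double e = std::min(std::max(eta_lin[j] + o[j], ETA_LO), ETA_HI);
        etag[j] = e;
        mug[j] = std::exp(e);
      }
    }
    double dev = nb_deviance(y, mug, phi);
    bool conv = false;
    int it = 0;

    for (it = 0; it < maxit; ++it) {
      // working weights and response
      arma::vec w(n), z(n);
      for (arma::uword j = 0; j < n; ++j) {
        double m = std::max(mug[j], 1e-10);
        w[j] = m / (1.0 + phi * m);
        z[j] = (etag[j] - o[j]) + (y[j] - m) / m;
      }
      arma::mat XtWX = X.t() * (X.each_col() % w);
      XtWX.diag() += 1e-10; // guard against numerically singular systems
      arma::vec XtWz = X.t() * (w % z);
      arma::vec b_new;
      if (!arma::solve(b_new, XtWX, XtWz, arma::solve_opts::likely_sympd)) {
        b_new = b; // give up on this step
      }

      // step halving on deviance increase
      double step = 1.0, dev_new = 0.0;
      arma::rowvec mu_new(n), eta_new(n);
      for (int h = 0; h < 12; ++h) {
        arma::vec b_try = b + step * (b_new - b);
        arma::vec eta_lin = X * b_try;
        for (arma::uword j = 0; j < n; ++j) {
          double e = eta_lin[j] + o[j];
          e = std::min(std::max(e, ETA_LO), ETA_HI);
          eta_new[j] = e;
          mu_new[j] = std::exp(e);
        }
        dev_new = nb_deviance(y, mu_new, phi);
        if (std::isfinite(dev_new) && dev_new <= dev + 1e-12) { b_new = b_try; break; }
        step *= 0.5;
        if (h == 11) { b_new = b; eta_new = etag; mu_new = mug; dev_new = dev; }
      }

      double delta = std::fabs(dev - dev_new) / (std::fabs(dev_new) + 1.0);
      b = b_new; etag = eta_new; mug = mu_new;
      double dev_prev = dev;
      dev = dev_new;
      if (delta < tol || (dev_prev == dev && it > 0)) { conv = true; ++it; break; }
    }

    // Cox-Reid adjustment at the solution
    arma::vec w(n);
    for (arma::uword j = 0; j < n; ++j) {
      double m = std::max(mug[j], 1e-10);
      w[j] = m / (1.0 + phi * m);
    }
    arma::mat XtWX = X.t() * (X.each_col() % w);
    XtWX.diag() += 1e-10;
    double ldet, sign;
    arma::log_det(ldet, sign, XtWX);

    beta.row(g) = b.t();
    mu.row(g) = mug;
    deviance[g] = dev;
    cr_adj[g] = 0.5 * ldet;
    iters[g] = it;
    converged[g] = conv ? 1 : 0;
  }

  return List::create(_["coefficients"] = beta, _["fitted"] = mu,
                      _["deviance"] = deviance, _["cr_adj"] = cr_adj,
                      _["iter"] = iters, _["converged"] = converged);
}

// NB log-likelihood per gene at given fitted means (phi = 0 -> Poisson).
// [[Rcpp::export(name = ".nbglm_loglik_cpp")]]
arma::vec nbglm_loglik_cpp(const arma::mat& counts, const arma::mat& mu,
                           const arma::vec& dispersion) {
  const arma::uword G = counts.n_rows, n = counts.n_cols;
  arma::vec ll(G, arma::fill::zeros);
  for (arma::uword g = 0; g < G; ++g) {
    double phi = dispersion[g], s = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      double y = counts(g, j), m = std::max(mu(g, j), 1e-10);
      if (phi > 0) {
        double r = 1.0 / phi;
        s += std::lgamma(y + r) - std::lgamma(r) - std::lgamma(y + 1.0);
        s += -r * std::log1p(phi * m);
        if (y > 0) s += y * (std::log(phi * m) - std::log1p(phi * m));
      } else {
        s += y * std::log(m) - m - std::lgamma(y + 1.0);
      }
    }
    ll[g] = s;
  }
  return ll;
}
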