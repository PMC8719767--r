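// Laplace-approximated marginal likelihood for the negative-binomial mixed
// model with scalar (nested-intercept) random-effect blocks and one optional
// correlated d-dimensional block per taxon.  The random effects use the
// "spherical" parameterization u = Lambda v, v ~ N(0, I), so the penalized
// inner objective is  -sum_i log NB2(y_i | mu_i, theta) + |v|^2 / 2  with
// log mu = X beta + offset + Z_eff v, and the Laplace marginal negative
// log-likelihood is  f(v_hat) + log det(H) / 2, H the inner Hessian at the
// mode.  Only v is integrated out; beta, theta and the variance parameters
// are outer parameters handled by the R-side optimizer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// NB2 log pmf summed over observations; optionally fills the working
// gradient g_i = dl/deta_i and weight w_i = -d2l/deta_i^2 (both >= 0 for w).
static double nb_loglik_eta(const arma::vec& y, const arma::vec& eta,
                            double theta, arma::vec* g, arma::vec* w) {
  const arma::uword n = y.n_elem;
  double ll = 0.0;
  for (arma::uword i = 0; i < n; ++i) {
    double mu = std::exp(eta[i]);
    if (!std::isfinite(mu)) return -std::numeric_limits<double>::infinity();
    double yi = y[i];
    ll += std::lgamma(yi + theta) - std::lgamma(theta) - std::lgamma(yi + 1.0)
        + yi * (eta[i] - std::log(theta + mu)) - theta * std::log1p(mu / theta);
    if (g) {
      double denom = theta + mu;
      (*g)[i] = yi - (yi + theta) * mu / denom;
      (*w)[i] = (yi + theta) * theta * mu / (denom * denom);
    }
  }
  return ll;
}

// Effective random-effect design row values: scalar entries are scaled by
// their block's lambda; the trailing d taxon entries hold the raw covariate
// vector r = (1, sex, color, sex*color) and map to r' Lt for that taxon's
// v-columns (Lt lower triangular, u_t = Lt v_t).
static void build_zeff(const arma::mat& Zv, const arma::imat& Zl,
                       const arma::vec& lambda, const arma::mat& Lt,
                       int d, arma::mat& Zeff) {
  const arma::uword n = Zv.n_rows, k = Zv.n_cols;
  Zeff.set_size(n, k);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < k; ++j) {
      int li = Zl(i, j);
      if (li >= 0) {
        Zeff(i, j) = Zv(i, j) * lambda[li];
      } else if (li == -1) {
        Zeff(i, j) = 0.0;  // taxon entry, filled below
      } else {
        Zeff(i, j) = 0.0;  // padding
      }
    }
    if (d > 0) {
      // taxon entries occupy the last d columns of the row layout
      for (int m = 0; m < d; ++m) {
        double acc = 0.0;
        for (int a = m; a < d; ++a)
          acc += Zv(i, k - d + a) * Lt(a, m);
        Zeff(i, k - d + m) = acc;
      }
    }
  }
}

static void add_eta_re(const arma::imat& Zi, const arma::mat& Zeff,
                       const arma::vec& v, arma::vec& eta) {
  const arma::uword n = Zi.n_rows, k = Zi.n_cols;
  for (arma::uword i = 0; i < n; ++i) {
    double acc = 0.0;
    for (arma::uword j = 0; j < k; ++j) {
      int c = Zi(i, j);
      if (c >= 0) acc += Zeff(i, j) * v[c];
    }
    eta[i] += acc;
  }
}

// [[Rcpp::export]]
List nbglmm_eval_cpp(const arma::vec& beta, double theta,
                     const arma::vec& lambda, const arma::mat& Lt,
                     const List& dat, const arma::vec& v_start,
                     double inner_tol, int max_inner,
                     bool want_mode_info) {
  const arma::vec y = dat["y"];
  const arma::mat X = dat["X"];
  const arma::vec off = dat["offset"];
  const arma::imat Zi = dat["Zi"];
  const arma::mat Zv = dat["Zv"];
  const arma::imat Zl = dat["Zl"];
  const int d = dat["d"];
  const int q = dat["q"];
  const int n_taxa = dat["n_taxa"];
  const arma::uword n = y.n_elem;

  arma::vec eta_base = off;
  if (X.n_cols > 0) eta_base += X * beta;

  const double BIG = 1e10;

  if (q == 0) {
    double ll = nb_loglik_eta(y, eta_base, theta, nullptr, nullptr);
    double nll = std::isfinite(ll) ? -ll : BIG;
    return List::create(_["nll"] = nll, _["v"] = arma::vec(),
                        _["converged"] = true, _["iterations"] = 0,
                        _["logdet"] = 0.0, _["ll_cond"] = ll,
                        _["grad_norm"] = 0.0);
  }

  arma::mat Zeff;
  build_zeff(Zv, Zl, lambda, Lt, d, Zeff);

  arma::vec v = (v_start.n_elem == (arma::uword)q) ? v_start
                                                   : arma::zeros(q);
  arma::vec g(n), w(n), eta(n);

  auto objective = [&](const arma::vec& vv, arma::vec* gg, arma::vec* ww,
                       double* ll_out) -> double {
    eta = eta_base;
    add_eta_re(Zi, Zeff, vv, eta);
    double ll = nb_loglik_eta(y, eta, theta, gg, ww);
    if (ll_out) *ll_out = ll;
    if (!std::isfinite(ll)) return BIG;
    return -ll + 0.5 * arma::dot(vv, vv);
  };

  double ll_cond = 0.0;
  double f = objective(v, &g, &w, &ll_cond);
  if (f >= BIG) { v.zeros(); f = objective(v, &g, &w, &ll_cond); }

  arma::mat H(q, q), R;
  arma::vec grad(q), delta(q);
  bool converged = false;
  int it = 0;
  double gnorm = NA_REAL;
  const arma::uword k = Zi.n_cols;

  for (it = 0; it < max_inner; ++it) {
    // gradient of the penalized deviance wrt v
    grad.zeros();
    for (arma::uword i = 0; i < n; ++i)
      for (arma::uword j = 0; j < k; ++j) {
        int c = Zi(i, j);
        if (c >= 0) grad[c] -= Zeff(i, j) * g[i];
      }
    grad += v;
    gnorm = arma::norm(grad, "inf");
    if (gnorm < inner_tol) { converged = true; break; }

    H.zeros();
    for (arma::uword i = 0; i < n; ++i) {
      double wi = w[i];
      for (arma::uword j1 = 0; j1 < k; ++j1) {
        int c1 = Zi(i, j1);
        if (c1 < 0) continue;
        double z1 = Zeff(i, j1) * wi;
        for (arma::uword j2 = 0; j2 <= j1; ++j2) {
          int c2 = Zi(i, j2);
          if (c2 < 0) continue;
          if (c1 >= c2) H(c1, c2) += z1 * Zeff(i, j2);
          else          H(c2, c1) += z1 * Zeff(i, j2);
        }
      }
    }
    H = arma::symmatl(H);
    H.diag() += 1.0;

    if (!arma::chol(R, H, "lower")) {
      return List::create(_["nll"] = BIG, _["v"] = v, _["converged"] = false,
                          _["iterations"] = it, _["logdet"] = NA_REAL,
                          _["ll_cond"] = ll_cond, _["grad_norm"] = gnorm);
    }
    delta = arma::solve(arma::trimatu(R.t()),
                        arma::solve(arma::trimatl(R), -grad));

    double step = 1.0;
    bool ok = false;
    for (int h = 0; h < 30; ++h) {
      arma::vec v_new = v + step * delta;
      double ll_new;
      double f_new = objective(v_new, &g, &w, &ll_new);
      if (f_new < f) { v = v_new; f = f_new; ll_cond = ll_new; ok = true; break; }
      step *= 0.5;
    }
    if (!ok) {  // no descent possible: treat as (near-)converged
      objective(v, &g, &w, &ll_cond);
      converged = gnorm < 1e-4;
      break;
    }
  }

  // Hessian and log-determinant at the mode
  H.zeros();
  for (arma::uword i = 0; i < n; ++i) {
    double wi = w[i];
    for (arma::uword j1 = 0; j1 < k; ++j1) {
      int c1 = Zi(i, j1);
      if (c1 < 0) continue;
      double z1 = Zeff(i, j1) * wi;
      for (arma::uword j2 = 0; j2 <= j1; ++j2) {
        int c2 = Zi(i, j2);
        if (c2 < 0) continue;
        if (c1 >= c2) H(c1, c2) += z1 * Zeff(i, j2);
        else          H(c2, c1) += z1 * Zeff(i, j2);
      }
    }
  }
  H = arma::symmatl(H);
  H.diag() += 1.0;
  double logdet = NA_REAL, nll = BIG;
  if (arma::chol(R, H, "lower")) {
    logdet = 2.0 * arma::sum(arma::log(R.diag()));
    nll = f + 0.5 * logdet;
  }

  List out = List::create(_["nll"] = nll, _["v"] = v,
                          _["converged"] = converged, _["iterations"] = it,
                          _["logdet"] = logdet, _["ll_cond"] = ll_cond,
                          _["grad_norm"] = gnorm);
  if (want_mode_info) {
    arma::mat Hinv = arma::inv_sympd(H);
    out["hinv_diag"] = arma::vec(Hinv.diag());
    if (d > 0 && n_taxa > 0) {
      // conditional covariance blocks of v for each taxon (v scale)
      arma::cube blocks(d, d, n_taxa);
      int c0 = q - n_taxa * d;
      for (int t = 0; t < n_taxa; ++t)
        blocks.slice(t) =
            Hinv.submat(c0 + t * d, c0 + t * d, c0 + t * d + d - 1,
                        c0 + t * d + d - 1);
      out["taxon_vcov_blocks"] = blocks;
    }
  }
  return out;
}
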