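// Fast-path objective for the outer optimizer: the model data and the
// warm-started inner mode live in a C++ context behind an external
// pointer, and the outer parameter vector is unpacked natively, so each
// objective evaluation costs one .Call with a scalar return.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

List nbglmm_eval_cpp(const arma::vec& beta, double theta,
                     const arma::vec& lambda, const arma::mat& Lt,
                     const List& dat, const arma::vec& v_start,
                     double inner_tol, int max_inner, bool want_mode_info);

struct NbglmmCtx {
  List dat;
  int p, s, d;
  arma::vec v_warm;
};

// [[Rcpp::export]]
SEXP nbglmm_make_ctx(List dat, int p, int s, int d) {
  NbglmmCtx* ctx = new NbglmmCtx;
  ctx->dat = dat;
  ctx->p = p; ctx->s = s; ctx->d = d;
  ctx->v_warm = arma::vec();
  XPtr<NbglmmCtx> ptr(ctx, true);
  return ptr;
}

static void unpack(const NbglmmCtx& ctx, const arma::vec& par,
                   arma::vec& beta, double& theta, arma::vec& lambda,
                   arma::mat& Lt) {
  int i = 0;
  beta = par.subvec(0, ctx.p - 1); i = ctx.p;
  theta = std::exp(par[i++]);
  lambda.set_size(ctx.s);
  for (int b = 0; b < ctx.s; ++b) lambda[b] = std::exp(par[i++]);
  int d = ctx.d;
  Lt.zeros(std::max(d, 1), std::max(d, 1));
  if (d > 0) {
    for (int m = 0; m < d; ++m) Lt(m, m) = std::exp(par[i++]);
    for (int c = 0; c < d; ++c)
      for (int r = c + 1; r < d; ++r) Lt(r, c) = par[i++];
  }
}

// [[Rcpp::export]]
double nbglmm_ctx_nll(SEXP ptr, const arma::vec& par, double inner_tol,
                      int max_inner) {
  XPtr<NbglmmCtx> ctx(ptr);
  arma::vec beta, lambda;
  double theta;
  arma::mat Lt;
  unpack(*ctx, par, beta, theta, lambda, Lt);
  List res = nbglmm_eval_cpp(beta, theta, lambda, Lt, ctx->dat, ctx->v_warm,
                             inner_tol, max_inner, false);
  double nll = as<double>(res["nll"]);
  if (std::isfinite(nll) && nll < 1e9)
    ctx->v_warm = as<arma::vec>(res["v"]);
  return nll;
}

// [[Rcpp::export]]
arma::vec nbglmm_ctx_v(SEXP ptr) {
  XPtr<NbglmmCtx> ctx(ptr);
  return ctx->v_warm;
}
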