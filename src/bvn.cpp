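// Bivariate-normal log-likelihood with link-function submodels:
//   mu_x = Zm %*% gx,  mu_y = Zm %*% gy
//   log sigma_x = Zx %*% dx,  log sigma_y = Zy %*% dy
//   log((1+rho)/(1-rho)) = Zr %*% dr
// Parameter vector order: c(gx, gy, dx, dy, dr).
// cpp_bvn_fit() runs the quasi-Newton optimisation entirely in C++ via R's
// vmmin (the BFGS used by stats::optim), avoiding per-iteration R overhead
// in simulation loops.
#include <RcppArmadillo.h>
#include <R_ext/Applic.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;
// |eta| cap corresponds to |rho| <= 1 - 1e-10 under rho = tanh(eta/2)
static const double ETA_MAX = 23.7;

struct BvnData {
  const mat *Zm, *Zx, *Zy, *Zr;
  const vec *x, *y;
};

// core evaluation; grad may be null
static double bvn_eval(const vec& par, const BvnData& d, vec* grad) {
  const mat &Zm = *d.Zm, &Zx = *d.Zx, &Zy = *d.Zy, &Zr = *d.Zr;
  const uword pm = Zm.n_cols, px = Zx.n_cols, py = Zy.n_cols;
  uword k = 0;
  vec gx = par.subvec(k, k + pm - 1); k += pm;
  vec gy = par.subvec(k, k + pm - 1); k += pm;
  vec dx = par.subvec(k, k + px - 1); k += px;
  vec dy = par.subvec(k, k + py - 1); k += py;
  vec dr = par.subvec(k, par.n_elem - 1);

  vec a = Zx * dx, b = Zy * dy, eta = Zr * dr;
  uvec clamped = (abs(eta) > ETA_MAX);
  eta = clamp(eta, -ETA_MAX, ETA_MAX);
  vec rho = tanh(eta / 2.0);
  vec ch = cosh(eta / 2.0);
  vec cc = 1.0 / (ch % ch);       // 1 - rho^2 without cancellation
  vec u = (*d.x - Zm * gx) / exp(a);
  vec v = (*d.y - Zm * gy) / exp(b);

  vec uv = u % v, u2 = u % u, v2 = v % v;
  vec Q = u2 - 2.0 * (rho % uv) + v2;
  double nll = accu(LOG2PI + a + b + 0.5 * log(cc) + Q / (2.0 * cc));
  if (!std::isfinite(nll)) nll = 1e10;

  if (grad) {
    vec g_a = 1.0 - (u2 - rho % uv) / cc;
    vec g_b = 1.0 - (v2 - rho % uv) / cc;
    vec g_eta = -(rho / 2.0 + uv / 2.0 - (rho % Q) / (2.0 * cc));
    g_eta.elem(find(clamped)).zeros();
    vec g_mux = -(u - rho % v) / (exp(a) % cc);
    vec g_muy = -(v - rho % u) / (exp(b) % cc);
    vec g(par.n_elem);
    uword j = 0;
    g.subvec(j, j + pm - 1) = Zm.t() * g_mux; j += pm;
    g.subvec(j, j + pm - 1) = Zm.t() * g_muy; j += pm;
    g.subvec(j, j + px - 1) = Zx.t() * g_a;  j += px;
    g.subvec(j, j + py - 1) = Zy.t() * g_b;  j += py;
    g.subvec(j, g.n_elem - 1) = Zr.t() * g_eta;
    g.elem(find_nonfinite(g)).zeros();
    *grad = g;
  }
  return nll;
}

// [[Rcpp::export]]
double cpp_bvn_nll(const arma::vec& par,
                   const arma::mat& Zm, const arma::mat& Zx,
                   const arma::mat& Zy, const arma::mat& Zr,
                   const arma::vec& x, const arma::vec& y) {
  BvnData d{&Zm, &Zx, &Zy, &Zr, &x, &y};
  return bvn_eval(par, d, nullptr);
}

// [[Rcpp::export]]
arma::vec cpp_bvn_nll_grad(const arma::vec& par,
                           const arma::mat& Zm, const arma::mat& Zx,
                           const arma::mat& Zy, const arma::mat& Zr,
                           const arma::vec& x, const arma::vec& y) {
  BvnData d{&Zm, &Zx, &Zy, &Zr, &x, &y};
  vec g;
  bvn_eval(par, d, &g);
  return g;
}

static double vm_fn(int n, double* p, void* ex) {
  vec par(p, n, false, true);
  return bvn_eval(par, *static_cast<BvnData*>(ex), nullptr);
}

static void vm_gr(int n, double* p, double* g, void* ex) {
  vec par(p, n, false, true);
  vec grad;
  bvn_eval(par, *static_cast<BvnData*>(ex), &grad);
  std::copy(grad.begin(), grad.end(), g);
}

// [[Rcpp::export]]
Rcpp::List cpp_bvn_fit(const arma::vec& start,
                       const arma::mat& Zm, const arma::mat& Zx,
                       const arma::mat& Zy, const arma::mat& Zr,
                       const arma::vec& x, const arma::vec& y,
                       int maxit = 300, double reltol = 1e-14) {
  BvnData d{&Zm, &Zx, &Zy, &Zr, &x, &y};
  int n = start.n_elem;
  std::vector<double> b(start.begin(), start.end());
  std::vector<int> mask(n, 1);
  double fmin = 0.0;
  int fncount = 0, grcount = 0, fail = 0;
  vmmin(n, b.data(), &fmin, vm_fn, vm_gr, maxit, 0, mask.data(),
        R_NegInf, reltol, 10, &d, &fncount, &grcount, &fail);
  vec par(b.data(), n);
  vec grad;
  bvn_eval(par, d, &grad);
  return Rcpp::List::create(
      Rcpp::Named("par") = par,
      Rcpp::Named("value") = fmin,
      Rcpp::Named("convergence") = fail,
      Rcpp::Named("fncount") = fncount,
      Rcpp::Named("grcount") = grcount,
      Rcpp::Named("gradient_norm") = grad.is_empty() ? NA_REAL
                                                     : abs(grad).max());
}
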