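// Newton-Raphson fitters used by the association layer and the shared
// permutation null, where every per-study SNP model is refit B times.
#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int    MAXIT   = 30;
static const double GRADTOL = 1e-10;
static const double BIGBETA = 25.0;   // divergence guard: treat as separation

// One logistic Newton solve. Returns convergence flag; beta/vcov in place.
static bool logistic_solve(const arma::mat& X, const arma::vec& y,
                           arma::vec& beta, arma::mat& vcov) {
  const arma::uword p = X.n_cols;
  beta.zeros(p);
  arma::mat XtWX(p, p);
  for (int it = 0; it < MAXIT; ++it) {
    arma::vec eta = X * beta;
    eta = arma::clamp(eta, -30.0, 30.0);
    arma::vec mu = 1.0 / (1.0 + arma::exp(-eta));
    arma::vec w  = mu % (1.0 - mu);
    arma::vec grad = X.t() * (y - mu);
    XtWX = X.t() * (X.each_col() % w);
    arma::vec step;
    if (!arma::solve(step, XtWX, grad, arma::solve_opts::no_approx))
      return false;
    beta += step;
    if (!beta.is_finite() || arma::norm(beta, "inf") > BIGBETA) return false;
    if (arma::norm(grad, "inf") < GRADTOL && arma::norm(step, "inf") < 1e-8) {
      XtWX = arma::symmatu(XtWX);
      if (!arma::inv_sympd(vcov, XtWX)) return false;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_logistic_newton(const arma::mat& X, const arma::vec& y) {
  arma::vec beta;
  arma::mat vcov;
  bool ok = logistic_solve(X, y, beta, vcov);
  if (!ok) {
    beta.zeros(X.n_cols);
    vcov.zeros(X.n_cols, X.n_cols);
  }
  return List::create(_["beta"] = beta, _["vcov"] = vcov,
                      _["converged"] = ok);
}

// Refit one SNP's logistic model against B permuted outcome vectors.
// Returns the coefficient (coef_idx, 1-based) and its SE per permutation.
// [[Rcpp::export]]
List cpp_logistic_perm(const arma::mat& X, const arma::mat& Y, int coef_idx) {
  const arma::uword B = Y.n_cols;
  const arma::uword j = coef_idx - 1;
  arma::vec beta(B), se(B);
  LogicalVector ok(B);
  arma::vec b;
  arma::mat v;
  for (arma::uword bcol = 0; bcol < B; ++bcol) {
    bool conv = logistic_solve(X, Y.col(bcol), b, v);
    ok[bcol] = conv;
    beta(bcol) = conv ? b(j) : NA_REAL;
    se(bcol)   = conv ? std::sqrt(v(j, j)) : NA_REAL;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = ok);
}

// Exact conditional logistic likelihood over enumerated case subsets.
// Xs: one row per candidate case-subset = the SUM of member covariates.
// starts/ends: 0-based row range of each stratum; obs: 0-based observed row.
static bool clogit_solve(const arma::mat& Xs,
                         const arma::ivec& starts, const arma::ivec& ends,
                         const arma::ivec& obs,
                         arma::vec& beta, arma::mat& vcov, double& loglik) {
  const arma::uword p = Xs.n_cols;
  const arma::uword S = starts.n_elem;
  beta.zeros(p);
  arma::mat info(p, p);
  for (int it = 0; it < MAXIT; ++it) {
    arma::vec eta = Xs * beta;
    arma::vec grad(p, arma::fill::zeros);
    info.zeros();
    loglik = 0.0;
    for (arma::uword s = 0; s < S; ++s) {
      const int a = starts(s), z = ends(s);
      arma::vec es = eta.subvec(a, z);
      double m = es.max();
      arma::vec w = arma::exp(es - m);
      double denom = arma::accu(w);
      w /= denom;
      loglik += eta(obs(s)) - (m + std::log(denom));
      arma::mat Xsub = Xs.rows(a, z);
      arma::rowvec xbar = w.t() * Xsub;
      grad += Xs.row(obs(s)).t() - xbar.t();
      info += Xsub.t() * (Xsub.each_col() % w) - xbar.t() * xbar;
    }
    arma::vec step;
    if (!arma::solve(step, info, grad, arma::solve_opts::no_approx))
      return false;
    beta += step;
    if (!beta.is_finite() || arma::norm(beta, "inf") > BIGBETA) return false;
    if (arma::norm(grad, "inf") < GRADTOL && arma::norm(step, "inf") < 1e-8) {
      info = arma::symmatu(info);
      if (!arma::inv_sympd(vcov, info)) return false;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_clogit_newton(const arma::mat& Xs, const arma::ivec& starts,
                       const arma::ivec& ends, const arma::ivec& obs) {
  arma::vec beta;
  arma::mat vcov;
  double ll = NA_REAL;
  bool ok = clogit_solve(Xs, starts, ends, obs, beta, vcov, ll);
  if (!ok) {
    beta.zeros(Xs.n_cols);
    vcov.zeros(Xs.n_cols, Xs.n_cols);
  }
  return List::create(_["beta"] = beta, _["vcov"] = vcov,
                      _["converged"] = ok, _["loglik"] = ll);
}

// Conditional-logistic log-likelihood at a fixed beta (for oracle checks).
// [[Rcpp::export]]
double cpp_clogit_loglik(const arma::mat& Xs, const arma::ivec& starts,
                         const arma::ivec& ends, const arma::ivec& obs,
                         const arma::vec& beta) {
  arma::vec eta = Xs * beta;
  double ll = 0.0;
  for (arma::uword s = 0; s < starts.n_elem; ++s) {
    arma::vec es = eta.subvec(starts(s), ends(s));
    double m = es.max();
    ll += eta(obs(s)) - (m + std::log(arma::accu(arma::exp(es - m))));
  }
  return ll;
}

// Permutation refits for conditional logistic: each column of ObsMat holds
// the 0-based observed-subset row per stratum for one permutation.
// [[Rcpp::export]]
List cpp_clogit_perm(const arma::mat& Xs, const arma::ivec& starts,
                     const arma::ivec& ends, const arma::imat& ObsMat,
                     int coef_idx) {
  const arma::uword B = ObsMat.n_cols;
  const arma::uword j = coef_idx - 1;
  arma::vec beta(B), se(B);
  LogicalVector ok(B);
  arma::vec b;
  arma::mat v;
  double ll;
  for (arma::uword bcol = 0; bcol < B; ++bcol) {
    arma::ivec obs = ObsMat.col(bcol);
    bool conv = clogit_solve(Xs, starts, ends, obs, b, v, ll);
    ok[bcol] = conv;
    beta(bcol) = conv ? b(j) : NA_REAL;
    se(bcol)   = conv ? std::sqrt(v(j, j)) : NA_REAL;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = ok);
}

// Poisson log-linear fit with a CR0-type cluster-robust sandwich variance
// (G/(G-1) small-sample factor, matching sandwich::vcovCL defaults).
static bool poisson_solve(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& cluster,
                          arma::vec& beta, arma::mat& vcov_rob,
                          arma::mat& vcov_mod) {
  const arma::uword p = X.n_cols;
  beta.zeros(p);
  // start the intercept at log(mean(y)) to keep early steps stable
  double ybar = arma::mean(y);
  if (ybar > 0) beta(0) = std::log(ybar);
  arma::mat XtWX(p, p);
  arma::vec mu;
  bool done = false;
  for (int it = 0; it < MAXIT && !done; ++it) {
    arma::vec eta = arma::clamp(X * beta, -30.0, 30.0);
    mu = arma::exp(eta);
    arma::vec grad = X.t() * (y - mu);
    XtWX = X.t() * (X.each_col() % mu);
    arma::vec step;
    if (!arma::solve(step, XtWX, grad, arma::solve_opts::no_approx))
      return false;
    // step-halving to keep eta in range
    double fac = 1.0;
    for (int h = 0; h < 5; ++h) {
      arma::vec cand = beta + fac * step;
      if (arma::norm(X * cand, "inf") < 30.0) { beta = cand; break; }
      fac *= 0.5;
      if (h == 4) beta += fac * step;
    }
    if (!beta.is_finite() || arma::norm(beta, "inf") > BIGBETA) return false;
    if (arma::norm(grad, "inf") < 1e-8 && arma::norm(step, "inf") < 1e-8)
      done = true;
  }
  if (!done) return false;
  arma::mat bread;
  XtWX = arma::symmatu(XtWX);
  if (!arma::inv_sympd(bread, XtWX)) return false;
  vcov_mod = bread;
  // cluster score sums
  int G = cluster.max() + 1;
  arma::mat Sc(G, p, arma::fill::zeros);
  arma::vec r = y - mu;
  for (arma::uword i = 0; i < X.n_rows; ++i)
    Sc.row(cluster(i)) += r(i) * X.row(i);
  arma::mat meat = Sc.t() * Sc;
  double adj = (G > 1) ? double(G) / double(G - 1) : 1.0;
  vcov_rob = adj * bread * meat * bread;
  return true;
}

// [[Rcpp::export]]
List cpp_poisson_newton(const arma::mat& X, const arma::vec& y,
                        const arma::ivec& cluster) {
  arma::vec beta;
  arma::mat vr, vm;
  bool ok = poisson_solve(X, y, cluster, beta, vr, vm);
  if (!ok) {
    beta.zeros(X.n_cols);
    vr.zeros(X.n_cols, X.n_cols);
    vm.zeros(X.n_cols, X.n_cols);
  }
  return List::create(_["beta"] = beta, _["vcov"] = vr,
                      _["vcov_model"] = vm, _["converged"] = ok);
}

// [[Rcpp::export]]
List cpp_poisson_perm(const arma::mat& X, const arma::mat& Y,
                      const arma::ivec& cluster, int coef_idx) {
  const arma::uword B = Y.n_cols;
  const arma::uword j = coef_idx - 1;
  arma::vec beta(B), se(B);
  LogicalVector ok(B);
  arma::vec b;
  arma::mat vr, vm;
  for (arma::uword bcol = 0; bcol < B; ++bcol) {
    bool conv = poisson_solve(X, Y.col(bcol), cluster, b, vr, vm);
    ok[bcol] = conv;
    beta(bcol) = conv ? b(j) : NA_REAL;
    se(bcol)   = conv ? std::sqrt(vr(j, j)) : NA_REAL;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["converged"] = ok);
}
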