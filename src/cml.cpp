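// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Constrained-ML fit for a fixed number K of invalid instruments.
//
// Model: beta_hat_j ~ N( (b'betaH_j + r_j, betaH_j'), Sigma_j ) with r_j = 0
// for valid IVs and exactly K nonzero r_j. Invalid IVs are fitted exactly
// (their likelihood contribution is zero once r_j is profiled out), so the
// log-likelihood is -1/2 * sum over valid IVs of the GLS quadratic form.
//
// Coordinate scheme per iteration, each step an exact partial maximisation:
//   1. given b, profile betaH out of each IV's quadratic; the per-IV
//      objective reduces to q_j = (betaY_j - b'betaH_hat_j)^2 / (v'Sigma_j v)
//      with v = (1, -b')'; the K IVs with the largest q_j (ties broken by
//      index) form the invalid set;
//   2. given b and the invalid set, betaH_j solves its GLS subproblem;
//   3. given {betaH_j}, b solves the weighted least-squares over valid IVs.
// Iterate until the log-likelihood changes by less than tol.

struct FitResult {
  arma::vec b;
  arma::mat betaH;
  arma::vec r;
  arma::uvec invalid;  // 0-based
  double loglik;
  bool converged;
  int n_iter;
  bool ok;
};

static FitResult fit_one_start(const arma::mat& bh, const arma::cube& Sigma,
                               const arma::cube& W, int K, arma::vec b,
                               double tol, int max_iter) {
  const int l = bh.n_rows;
  const int p = bh.n_cols - 1;
  FitResult res;
  res.ok = true;
  res.converged = false;
  arma::mat betaH(l, p, arma::fill::zeros);
  arma::vec r(l, arma::fill::zeros);
  arma::uvec invalid;
  double loglik = -std::numeric_limits<double>::infinity();
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // step 1: invalid set from profiled per-IV gains
    arma::vec v(p + 1);
    v[0] = 1.0;
    v.subvec(1, p) = -b;
    arma::vec q(l);
    for (int j = 0; j < l; ++j) {
      double denom = arma::as_scalar(v.t() * Sigma.slice(j) * v);
      double resid = bh(j, 0) - arma::dot(b, bh.row(j).subvec(1, p).t());
      q[j] = resid * resid / denom;
    }
    invalid.set_size(K);
    if (K > 0) {
      // stable sort: descending q, ties by ascending index
      arma::uvec idx = arma::stable_sort_index(q, "descend");
      invalid = arma::sort(idx.head(K));
    }
    std::vector<bool> is_invalid(l, false);
    for (int k = 0; k < K; ++k) is_invalid[invalid[k]] = true;

    // step 2: betaH updates
    arma::mat A(p + 1, p, arma::fill::zeros);
    A.row(0) = b.t();
    A.submat(1, 0, p, p - 1) = arma::eye(p, p);
    for (int j = 0; j < l; ++j) {
      arma::vec bj = bh.row(j).t();
      if (is_invalid[j]) {
        betaH.row(j) = bh.row(j).subvec(1, p);
        r[j] = bh(j, 0) - arma::dot(b, betaH.row(j).t());
      } else {
        const arma::mat& Wj = W.slice(j);
        arma::mat AtW = A.t() * Wj;
        arma::vec sol;
        if (!arma::solve(sol, AtW * A, AtW * bj)) { res.ok = false; return res; }
        betaH.row(j) = sol.t();
        r[j] = 0.0;
      }
    }

    // step 3: b update over valid IVs
    arma::mat M(p, p, arma::fill::zeros);
    arma::vec rhs(p, arma::fill::zeros);
    for (int j = 0; j < l; ++j) {
      if (is_invalid[j]) continue;
      const arma::mat& Wj = W.slice(j);
      arma::vec hj = betaH.row(j).t();
      arma::vec cj(p + 1, arma::fill::zeros);
      cj.subvec(1, p) = hj;
      arma::vec bj = bh.row(j).t();
      double g = arma::dot(Wj.row(0).t(), bj - cj);
      double s = Wj(0, 0);
      M += s * (hj * hj.t());
      rhs += hj * g;
    }
    arma::vec b_new;
    if (!arma::solve(b_new, M, rhs)) { res.ok = false; return res; }
    b = b_new;

    // log-likelihood at (b, betaH); invalid IVs contribute exactly 0
    double ll = 0.0;
    for (int j = 0; j < l; ++j) {
      if (is_invalid[j]) continue;
      arma::vec mj(p + 1);
      arma::vec hj = betaH.row(j).t();
      mj[0] = arma::dot(b, hj);
      mj.subvec(1, p) = hj;
      arma::vec e = bh.row(j).t() - mj;
      ll += arma::as_scalar(e.t() * W.slice(j) * e);
    }
    ll *= -0.5;
    if (std::abs(ll - loglik) < tol) {
      loglik = ll;
      res.converged = true;
      break;
    }
    loglik = ll;
  }
  res.b = b;
  res.betaH = betaH;
  res.r = r;
  res.invalid = invalid;
  res.loglik = loglik;
  res.n_iter = iter;
  return res;
}

// [[Rcpp::export]]
List cpp_cml_fixed_k(const arma::mat& beta_hat, const arma::cube& Sigma,
                     const arma::cube& W, int K, const arma::mat& starts,
                     double tol, int max_iter) {
  const int n_starts = starts.n_rows;
  FitResult best;
  best.loglik = -std::numeric_limits<double>::infinity();
  best.ok = false;
  std::vector<double> logliks;
  logliks.reserve(n_starts);
  for (int s = 0; s < n_starts; ++s) {
    FitResult f = fit_one_start(beta_hat, Sigma, W, K, starts.row(s).t(),
                                tol, max_iter);
    if (!f.ok) continue;
    logliks.push_back(f.loglik);
    if (!best.ok || f.loglik > best.loglik ||
        (f.loglik == best.loglik && f.converged && !best.converged)) {
      best = f;
      best.ok = true;
    }
  }
  if (!best.ok) stop("all coordinate-descent starts failed (singular system)");
  int agree = 0;
  for (double ll : logliks)
    if (std::abs(ll - best.loglik) < 1e-5 * (1.0 + std::abs(best.loglik))) ++agree;
  return List::create(
      _["b"] = best.b, _["betaH"] = best.betaH, _["r"] = best.r,
      _["invalid"] = IntegerVector(best.invalid.begin(), best.invalid.end()),
      _["loglik"] = best.loglik, _["converged"] = best.converged,
      _["n_iter"] = best.n_iter, _["n_starts_agreeing"] = agree);
}
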