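// Elastic-net penalized binomial-trials GLM.
//
// Outer loop: iteratively reweighted least squares (IRLS) on the binomial
// log-likelihood with m trials per subject. Inner loop: cyclic coordinate
// descent on the penalized weighted least-squares subproblem, restricted to
// an active set with vectorized KKT sweeps to admit new coordinates.
// Objective (X assumed standardized by the caller):
//   (1/n) * negloglik(b0, beta) + lambda * (w*||beta||_1 + (1-w)/2*||beta||_2^2)
// The intercept is unpenalized. A step-halving guard keeps the penalized
// objective non-increasing across accepted IRLS iterations.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

static double penalized_obj(const mat& X, const vec& y, double m,
                            double b0, const vec& beta,
                            double lambda, double w, double clip) {
  vec eta = b0 + X * beta;
  vec p = 1.0 / (1.0 + exp(-eta));
  p = clamp(p, clip, 1.0 - clip);
  double nll = -accu(y % log(p) + (m - y) % log(1.0 - p));
  double n = static_cast<double>(X.n_rows);
  double pen = lambda * (w * accu(abs(beta)) +
                         0.5 * (1.0 - w) * accu(square(beta)));
  return nll / n + pen;
}

// Coordinate descent on the weighted least-squares subproblem.
// r = z - b0 - X*beta is kept incrementally. The weighted active columns
// (X.col(j) % wgt) and diagonal terms xtwx_j = (1/n) sum_i wgt_i x_ij^2
// are cached per call, so each cycle is allocation-free; inactive
// coordinates are checked against the KKT conditions with one BLAS gemv
// per sweep and admitted as needed.
static void cd_solve(const mat& X, const vec& wgt, double wsum,
                     double& b0, vec& beta, vec& r,
                     double lambda, double w, double tol, int max_cycles,
                     std::vector<unsigned int>& active,
                     std::vector<char>& in_active) {
  const uword nr = X.n_rows;
  const double n = static_cast<double>(nr);
  const double lw = lambda * w;
  const double lr = lambda * (1.0 - w);

  auto build_cache = [&](mat& Xaw, vec& xtwx_a) {
    Xaw.set_size(nr, active.size());
    xtwx_a.set_size(active.size());
    for (size_t k = 0; k < active.size(); ++k) {
      Xaw.col(k) = X.col(active[k]) % wgt;
      xtwx_a[k] = dot(Xaw.col(k), X.col(active[k])) / n;
    }
  };
  mat Xaw;
  vec xtwx_a;
  build_cache(Xaw, xtwx_a);

  for (;;) {
    for (int cycle = 0; cycle < max_cycles; ++cycle) {
      double maxdel = 0.0;
      double db0 = dot(wgt, r) / n / wsum;
      if (db0 != 0.0) {
        b0 += db0;
        r -= db0;
        maxdel = std::abs(db0);
      }
      for (size_t k = 0; k < active.size(); ++k) {
        const uword idx = active[k];
        const double bj = beta[idx];
        const double* xw = Xaw.colptr(k);
        const double* rr = r.memptr();
        double acc = 0.0;
        for (uword i = 0; i < nr; ++i) acc += xw[i] * rr[i];
        const double rho = acc / n + xtwx_a[k] * bj;
        const double bnew = soft(rho, lw) / (xtwx_a[k] + lr);
        if (bnew != bj) {
          const double d = bnew - bj;
          const double* xj = X.colptr(idx);
          double* rm = r.memptr();
          for (uword i = 0; i < nr; ++i) rm[i] -= xj[i] * d;
          beta[idx] = bnew;
          maxdel = std::max(maxdel, std::abs(d));
        }
      }
      if (maxdel < tol) break;
    }
    // KKT sweep over inactive coordinates (one BLAS gemv)
    vec grad = X.t() * (wgt % r) / n;
    bool added = false;
    for (uword j = 0; j < X.n_cols; ++j) {
      if (!in_active[j] && std::abs(grad[j]) > lw) {
        active.push_back(j);
        in_active[j] = 1;
        added = true;
      }
    }
    if (!added) break;
    build_cache(Xaw, xtwx_a);
  }
}

// Fit a decreasing lambda path with warm starts.
// [[Rcpp::export]]
Rcpp::List enet_path_cpp(const arma::mat& X, const arma::vec& y, double m,
                         double w, const arma::vec& lambdas,
                         double b0_init, const arma::vec& beta_init,
                         int max_outer, double tol, double prob_clip,
                         int max_cycles) {
  const uword p = X.n_cols, L = lambdas.n_elem;
  const double n = static_cast<double>(X.n_rows);
  mat beta_out(p, L, fill::zeros);
  vec b0_out(L, fill::zeros);
  ivec niter(L, fill::zeros);
  ivec conv(L, fill::zeros);

  vec beta = beta_init;
  double b0 = b0_init;

  for (uword l = 0; l < L; ++l) {
    const double lambda = lambdas[l];
    std::vector<unsigned int> active;
    std::vector<char> in_active(p, 0);
    for (uword j = 0; j < p; ++j) {
      if (beta[j] != 0.0) { active.push_back(j); in_active[j] = 1; }
    }
    double obj = penalized_obj(X, y, m, b0, beta, lambda, w, prob_clip);
    bool converged = false;
    int it = 0;
    for (it = 1; it <= max_outer; ++it) {
      vec beta_old = beta;
      double b0_old = b0;

      vec eta = b0 + X * beta;
      vec pr = 1.0 / (1.0 + exp(-eta));
      pr = clamp(pr, prob_clip, 1.0 - prob_clip);
      vec wgt = m * pr % (1.0 - pr);
      wgt = clamp(wgt, 1e-10, datum::inf);
      vec z = eta + (y - m * pr) / wgt;
      vec r = z - eta;
      double wsum = accu(wgt) / n;

      cd_solve(X, wgt, wsum, b0, beta, r, lambda, w,
               tol, max_cycles, active, in_active);

      // step-halving guard on the penalized objective
      double obj_new = penalized_obj(X, y, m, b0, beta, lambda, w, prob_clip);
      int halvings = 0;
      while (obj_new > obj + 1e-12 && halvings < 20) {
        beta = 0.5 * (beta + beta_old);
        b0 = 0.5 * (b0 + b0_old);
        obj_new = penalized_obj(X, y, m, b0, beta, lambda, w, prob_clip);
        ++halvings;
      }
      obj = obj_new;

      double maxdel = std::abs(b0 - b0_old);
      if (p > 0) maxdel = std::max(maxdel, abs(beta - beta_old).max());
      if (maxdel < tol) { converged = true; break; }
    }
    beta_out.col(l) = beta;
    b0_out[l] = b0;
    niter[l] = std::min(it, max_outer);
    conv[l] = converged ? 1 : 0;
  }

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta_out,
    Rcpp::Named("b0") = b0_out,
    Rcpp::Named("n_iter") = niter,
    Rcpp::Named("converged") = conv);
}

// Unpenalized binomial-trials GLM by Newton-Raphson (used for the relaxed
// refits inside backward elimination). Returns coefficients (intercept
// first), Wald standard errors, the negative log-likelihood without the
// binomial constant, and a convergence flag.
// [[Rcpp::export]]
Rcpp::List glm_binom_cpp(const arma::mat& X, const arma::vec& y, double m,
                         int max_iter, double tol, double prob_clip) {
  const uword n = X.n_rows, p = X.n_cols;
  mat X1(n, p + 1, fill::ones);
  if (p > 0) X1.cols(1, p) = X;
  vec beta(p + 1, fill::zeros);
  double ybar = accu(y) / (m * static_cast<double>(n));
  ybar = std::min(std::max(ybar, prob_clip), 1.0 - prob_clip);
  beta[0] = std::log(ybar / (1.0 - ybar));

  auto nll = [&](const vec& b) {
    vec eta = X1 * b;
    vec pr = clamp(1.0 / (1.0 + exp(-eta)), prob_clip, 1.0 - prob_clip);
    return -accu(y % log(pr) + (m - y) % log(1.0 - pr));
  };

  double obj = nll(beta);
  bool converged = false;
  mat info(p + 1, p + 1);
  for (int it = 0; it < max_iter; ++it) {
    vec eta = X1 * beta;
    vec pr = clamp(1.0 / (1.0 + exp(-eta)), prob_clip, 1.0 - prob_clip);
    vec W = clamp(m * pr % (1.0 - pr), 1e-10, datum::inf);
    info = X1.t() * (X1.each_col() % W);
    info.diag() += 1e-9;
    vec score = X1.t() * (y - m * pr);
    vec delta = solve(info, score, solve_opts::likely_sympd);
    double step = 1.0;
    vec cand = beta + delta;
    double obj_new = nll(cand);
    int halvings = 0;
    while (obj_new > obj + 1e-12 && halvings < 30) {
      step *= 0.5;
      cand = beta + step * delta;
      obj_new = nll(cand);
      ++halvings;
    }
    double maxdel = abs(step * delta).max();
    beta = cand;
    obj = obj_new;
    if (maxdel < tol) { converged = true; break; }
  }
  vec se = sqrt(diagvec(inv_sympd(symmatu(info))));
  return Rcpp::List::create(
    Rcpp::Named("coef") = beta,
    Rcpp::Named("se") = se,
    Rcpp::Named("nll") = obj,
    Rcpp::Named("converged") = converged);
}
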