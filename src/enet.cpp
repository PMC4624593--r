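// Cyclic coordinate descent for the Gaussian elastic net
//
//   min_{b0,b} 1/(2n) * sum_j (y_j - b0 - x_j' b)^2
//              + lambda * ( alpha*||b||_1 + (1-alpha)/2 * ||b||_2^2 )
//
// The caller passes the problem in covariance form on centered data:
// H = X'X/n, c = X'y/n, yy = y'y/n. The intercept is recovered in R as
// ybar - xbar' b. Each coordinate update is the exact one-dimensional
// minimizer (soft-thresholding), so the objective is non-increasing
// across sweeps. The vector s = X'(y - Xb)/n is maintained
// incrementally, making a coordinate update O(p) regardless of n.
// Along a decreasing lambda path, solutions are warm started from the
// previous lambda; within each lambda an active-set strategy iterates
// over the nonzero coordinates until convergence, then runs one full
// sweep to catch newly activated coordinates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// 1/(2n)||y-Xb||^2 + penalty, expressed through s = c - H b:
// RSS/n = yy - 2 b'c + b'Hb = yy - b'c - b's.
static double objective(const arma::vec& s, const arma::vec& beta,
                        const arma::vec& c, double yy,
                        double lambda, double alpha) {
  double fit = 0.5 * (yy - arma::dot(beta, c) - arma::dot(beta, s));
  double l1 = arma::accu(arma::abs(beta));
  double l2 = arma::dot(beta, beta);
  return fit + lambda * (alpha * l1 + 0.5 * (1.0 - alpha) * l2);
}

// One sweep over the coordinates in `idx`; returns the largest absolute
// coefficient change.
static double sweep_set(const arma::mat& H, const arma::vec& xs,
                        arma::vec& beta, arma::vec& s,
                        const arma::uvec& idx,
                        double lambda, double alpha) {
  double maxdelta = 0.0;
  const double thr = lambda * alpha;
  const double ridge = lambda * (1.0 - alpha);
  for (arma::uword k = 0; k < idx.n_elem; ++k) {
    arma::uword j = idx[k];
    if (xs[j] == 0.0) { beta[j] = 0.0; continue; }
    double bj = beta[j];
    double rho = s[j] + xs[j] * bj;
    double bnew = soft(rho, thr) / (xs[j] + ridge);
    if (bnew != bj) {
      double d = bnew - bj;
      s -= H.col(j) * d;
      beta[j] = bnew;
      d = std::fabs(d);
      if (d > maxdelta) maxdelta = d;
    }
  }
  return maxdelta;
}

// [[Rcpp::export]]
List enet_cd_path(const arma::mat& H, const arma::vec& c, double yy,
                  double alpha, const arma::vec& lambdas,
                  double tol, int maxit, bool record_obj) {
  const arma::uword p = H.n_cols, L = lambdas.n_elem;
  arma::vec xs = H.diag();

  arma::mat betas(p, L, arma::fill::zeros);
  arma::ivec niter(L, arma::fill::zeros);
  arma::ivec conv(L, arma::fill::zeros);
  List obj_trace(L);

  arma::vec beta(p, arma::fill::zeros);
  arma::vec s = c;
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);

  for (arma::uword l = 0; l < L; ++l) {
    double lambda = lambdas[l];
    std::vector<double> trace;
    int it = 0;
    bool done = false;
    while (it < maxit && !done) {
      // full sweep (may activate coordinates)
      double d = sweep_set(H, xs, beta, s, all, lambda, alpha);
      ++it;
      if (record_obj) trace.push_back(objective(s, beta, c, yy, lambda, alpha));
      if (d < tol) { done = true; break; }
      // inner iterations restricted to the current active set
      arma::uvec act = arma::find(beta != 0.0);
      while (it < maxit && act.n_elem > 0) {
        double da = sweep_set(H, xs, beta, s, act, lambda, alpha);
        ++it;
        if (record_obj) trace.push_back(objective(s, beta, c, yy, lambda, alpha));
        if (da < tol) break;
      }
    }
    betas.col(l) = beta;
    niter[l] = it;
    conv[l] = done ? 1 : 0;
    if (record_obj) obj_trace[l] = wrap(trace);
  }

  return List::create(Named("beta") = betas,
                      Named("niter") = niter,
                      Named("converged") = conv,
                      Named("objective") = obj_trace);
}
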