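// Graphical LASSO by block coordinate descent on the penalized covariance
// (Friedman-style: each column update solves an L1 lasso subproblem by
// coordinate descent). Warm starts along a descending penalty path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double lam) {
  if (x > lam) return x - lam;
  if (x < -lam) return x + lam;
  return 0.0;
}

// Lasso subproblem: minimize 0.5 b' W11 b - s12' b + lam * ||b||_1,
// coordinate descent with warm-started beta. W11 has strictly positive
// diagonal (covariance plus ridge from the glasso penalty).
static void lasso_cd(const mat& W11, const vec& s12, vec& beta,
                     double lam, double tol, int maxit) {
  const uword q = s12.n_elem;
  for (int it = 0; it < maxit; ++it) {
    double max_delta = 0.0;
    for (uword k = 0; k < q; ++k) {
      double old = beta(k);
      // residual partial covariance excluding coordinate k
      double r = s12(k) - dot(W11.col(k), beta) + W11(k, k) * old;
      double bk = soft_threshold(r, lam) / W11(k, k);
      if (bk != old) {
        beta(k) = bk;
        double d = std::abs(bk - old);
        if (d > max_delta) max_delta = d;
      }
    }
    if (max_delta < tol) break;
  }
}

// One glasso fit. S is the (correlation) input matrix. Returns the precision
// estimate Theta with exact zeros preserved, plus convergence metadata.
// State (W, B) is carried by reference so a path can warm start.
static bool glasso_core(const mat& S, double lam, double tol, int maxit,
                        mat& W, mat& B, mat& Theta, int& iters) {
  const uword p = S.n_rows;
  if (p == 1) {
    Theta.set_size(1, 1);
    Theta(0, 0) = 1.0 / S(0, 0);
    iters = 0;
    return true;
  }
  // convergence threshold scaled by mean absolute off-diagonal of S
  double off_mean = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) off_mean += std::abs(S(i, j));
  off_mean /= (p * (p - 1) / 2.0);
  const double thr = tol * std::max(off_mean, 1e-12);
  const double inner_tol = thr / 10.0;

  bool converged = false;
  int it = 0;
  for (; it < maxit; ++it) {
    double max_delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      // partition: column j against the rest
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j);
      s12.shed_row(j);
      vec beta = B.col(j);
      beta.shed_row(j);
      lasso_cd(W11, s12, beta, lam, inner_tol, maxit);
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > max_delta) max_delta = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
      c = 0;
      for (uword k = 0; k < p; ++k) B(k, j) = (k == j) ? 0.0 : beta(c++);
    }
    if (max_delta < thr) { converged = true; ++it; break; }
  }
  iters = it;

  // Recover Theta from (W, B): theta_jj = 1/(w_jj - w12'beta),
  // theta_.j = -beta * theta_jj.  Exact zeros of beta propagate.
  Theta.zeros(p, p);
  for (uword j = 0; j < p; ++j) {
    double dot_wb = 0.0;
    for (uword k = 0; k < p; ++k) if (k != j) dot_wb += W(k, j) * B(k, j);
    double theta_jj = 1.0 / (W(j, j) - dot_wb);
    Theta(j, j) = theta_jj;
    for (uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * theta_jj;
  }
  // symmetrize without creating numerical dust on exact zeros
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j) {
      double a = Theta(i, j), b = Theta(j, i);
      double v = (a == 0.0 || b == 0.0) ? 0.0 : 0.5 * (a + b);
      Theta(i, j) = v;
      Theta(j, i) = v;
    }
  return converged;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lam, double tol, int maxit,
                      bool pen_diag) {
  const uword p = S.n_rows;
  mat W = S;
  if (pen_diag) W.diag() += lam;
  mat B = zeros<mat>(p, p);
  mat Theta;
  int iters = 0;
  bool conv = glasso_core(S, lam, tol, maxit, W, B, Theta, iters);
  return Rcpp::List::create(Rcpp::Named("theta") = Theta,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}

// Path fit with warm starts; lambdas must be sorted descending.
// Returns a cube of precision estimates (p x p x nlambda).
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           double tol, int maxit, bool pen_diag) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  cube thetas(p, p, nl);
  Rcpp::LogicalVector conv(nl);
  Rcpp::IntegerVector iters(nl);
  mat W = S;
  if (pen_diag) W.diag() += lambdas(0);
  mat B = zeros<mat>(p, p);
  mat Theta;
  for (uword l = 0; l < nl; ++l) {
    if (l > 0 && pen_diag) {
      // shift the penalized diagonal to the new lambda, keep W, B warm
      W.diag() += lambdas(l) - lambdas(l - 1);
    }
    int it = 0;
    conv[l] = glasso_core(S, lambdas(l), tol, maxit, W, B, Theta, it);
    iters[l] = it;
    thetas.slice(l) = Theta;
  }
  return Rcpp::List::create(Rcpp::Named("thetas") = thetas,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("iterations") = iters);
}
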