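// Core numerical routines for the graphical VAR estimator.
//
// The model is y_t = B y_{t-1} + e_t with e_t ~ N(0, K^{-1}).  Estimation
// alternates (i) a lasso-penalised update of the temporal matrix B given the
// innovation precision K (coordinate descent on the precision-weighted
// Gaussian loss, as in MRCE-type estimators) and (ii) a graphical-lasso
// update of K on the residual covariance.  Everything is expressed through
// the sufficient statistics Sxx = X'X/n, Sxy = X'Y/n, Syy = Y'Y/n so a
// single fit costs O(p^4) per sweep regardless of series length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat resid_cov(const mat& B, const mat& Sxx, const mat& Sxy,
                     const mat& Syy);

static inline double soft_threshold(double z, double lam) {
  if (z > lam) return z - lam;
  if (z < -lam) return z + lam;
  return 0.0;
}

// Graphical lasso (Friedman/Hastie/Tibshirani block coordinate descent),
// element-wise off-diagonal penalties Lambda (diagonal of W kept at diag(S)).
// Zero-constrained MLE refits are obtained with Lambda = 0 on the support and
// a huge penalty elsewhere. Writes the estimated covariance into W and
// returns the precision K; jittered is set when a ridge was needed.
static mat glasso_core_m(const mat& S_in, const mat& Lambda, int maxit,
                         double tol, mat& W, bool& jittered) {
  const uword p = S_in.n_rows;
  mat S = S_in;
  jittered = false;

  // guard: S must be (numerically) PD enough for the lambda = 0 limit
  if (Lambda.min() <= 0.0) {
    vec ev = eig_sym(symmatu(S));
    double floor_ev = 1e-8 * std::max(1.0, ev.max());
    if (ev.min() < floor_ev) {
      S.diag() += (floor_ev - ev.min()) + floor_ev;
      jittered = true;
    }
  }

  if (p == 1) {
    W = S;
    mat K(1, 1);
    K(0, 0) = 1.0 / S(0, 0);
    return K;
  }

  W = S;                       // penalise.diagonal = FALSE convention
  mat Beta(p - 1, p, fill::zeros);   // lasso coefficients per column problem

  double offscale = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = i + 1; j < p; ++j)
      offscale += std::abs(S(i, j));
  offscale = std::max(offscale / std::max(1.0, double(p * (p - 1) / 2)), 1e-12);
  const double thr = tol * offscale;

  uvec all = regspace<uvec>(0, p - 1);
  for (int cycle = 0; cycle < maxit; ++cycle) {
    double max_dW = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat W11 = W.submat(idx, idx);
      vec s12 = S.col(j);
      s12 = s12.elem(idx);
      vec lam12 = Lambda.col(j);
      lam12 = lam12.elem(idx);
      vec b = Beta.col(j);

      // inner lasso coordinate descent: min 1/2 b'W11 b - s12'b + lam.|b|
      for (int it = 0; it < 200; ++it) {
        double max_db = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double wkk = W11(k, k);
          double grad = s12(k) - dot(W11.col(k), b) + wkk * b(k);
          double bk = soft_threshold(grad, lam12(k)) / wkk;
          double db = std::abs(bk - b(k));
          if (db > max_db) max_db = db;
          b(k) = bk;
        }
        if (max_db < 0.5 * thr) break;
      }
      Beta.col(j) = b;
      vec w12 = W11 * b;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > max_dW) max_dW = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (max_dW < thr) break;
  }

  // back out K column by column; zeros in Beta stay exact zeros in K
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(all != j);
    vec b = Beta.col(j);
    vec w12 = W.col(j);
    w12 = w12.elem(idx);
    double denom = W(j, j) - dot(w12, b);
    if (denom < 1e-12) { denom = 1e-12; jittered = true; }
    double kjj = 1.0 / denom;
    K(j, j) = kjj;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -b(k) * kjj;
  }
  K = symmatu(0.5 * (K + K.t()));
  // snap floating dust at the soft-threshold boundary to exact zero
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j && std::abs(K(i, j)) < 1e-10 * std::sqrt(K(i, i) * K(j, j)))
        K(i, j) = 0.0;
  return K;
}

static mat glasso_core(const mat& S_in, double lambda, int maxit, double tol,
                       mat& W, bool& jittered) {
  mat Lambda(S_in.n_rows, S_in.n_cols);
  Lambda.fill(lambda);
  return glasso_core_m(S_in, Lambda, maxit, tol, W, jittered);
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      int maxit = 200, double tol = 1e-4) {
  mat W;
  bool jittered = false;
  mat K = glasso_core(S, lambda, maxit, tol, W, jittered);
  return Rcpp::List::create(Rcpp::Named("K") = K,
                            Rcpp::Named("W") = W,
                            Rcpp::Named("jittered") = jittered);
}

// Unpenalised refit of B and K restricted to a selected support.
// B entries outside Bmask are fixed at zero (per-row OLS on the support via
// coordinate descent with zero penalty); K off-diagonals outside Kmask are
// forced to zero through an effectively infinite penalty.
// [[Rcpp::export(name = ".gvar_refit_cpp")]]
Rcpp::List gvar_refit_cpp(const arma::mat& Sxx, const arma::mat& Sxy,
                          const arma::mat& Syy, int n,
                          const arma::umat& Bmask, const arma::umat& Kmask,
                          int max_iter = 100, double tol = 1e-6,
                          int glasso_maxit = 200, double glasso_tol = 1e-5) {
  const uword p = Syy.n_rows;
  mat B(p, p, fill::zeros);
  bool any_jitter = false;

  // B: coordinate descent on the support only (K drops out of the
  // unpenalised row-wise least squares solution)
  for (int it = 0; it < 500; ++it) {
    double max_db = 0.0;
    for (uword i = 0; i < p; ++i) {
      for (uword j = 0; j < p; ++j) {
        if (!Bmask(i, j)) continue;
        double h = Sxx(j, j);
        if (h < 1e-12) continue;
        double grad = Sxy(j, i) - dot(Sxx.col(j), B.row(i).t());
        double bnew = B(i, j) + grad / h;
        double d = std::abs(bnew - B(i, j));
        if (d > max_db) max_db = d;
        B(i, j) = bnew;
      }
    }
    if (max_db < tol) break;
  }

  mat S = resid_cov(B, Sxx, Sxy, Syy);
  const double BIG = 1e10;
  mat Lambda(p, p);
  Lambda.fill(BIG);
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i == j || Kmask(i, j)) Lambda(i, j) = 0.0;
  mat W;
  bool jit = false;
  mat K = glasso_core_m(S, Lambda, glasso_maxit, glasso_tol, W, jit);
  any_jitter = any_jitter || jit;

  double ld, sign;
  log_det(ld, sign, K);
  double loglik = 0.5 * double(n) * (ld - trace(S * K));
  return Rcpp::List::create(Rcpp::Named("B") = B, Rcpp::Named("K") = K,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("jittered") = any_jitter);
}

// One full coordinate-descent pass over B given K.  G = (Sxy - Sxx B') K is
// maintained by rank-one updates.  Returns max absolute coefficient change.
static double b_sweep(mat& B, mat& G, const mat& Sxx, const mat& K,
                      double lambda) {
  const uword p = B.n_rows;
  double max_db = 0.0;
  for (uword i = 0; i < p; ++i) {        // response (row of B)
    for (uword j = 0; j < p; ++j) {      // predictor (column of B)
      double h = K(i, i) * Sxx(j, j);
      if (h < 1e-12) continue;
      double z = B(i, j) * h + G(j, i);
      double bnew = soft_threshold(z, lambda) / h;
      double d = bnew - B(i, j);
      if (d != 0.0) {
        B(i, j) = bnew;
        // B'(j,i) += d  =>  G -= d * Sxx.col(j) * K.row(i)
        G -= d * (Sxx.col(j) * K.row(i));
        double ad = std::abs(d);
        if (ad > max_db) max_db = ad;
      }
    }
  }
  return max_db;
}

// Residual covariance S(B) = Syy - Syx B' - B Sxy + B Sxx B'  (Syx = Sxy')
static mat resid_cov(const mat& B, const mat& Sxx, const mat& Sxy,
                     const mat& Syy) {
  mat S = Syy - Sxy.t() * B.t() - B * Sxy + B * Sxx * B.t();
  return symmatu(0.5 * (S + S.t()));
}

// [[Rcpp::export(name = ".gvar_fit_cpp")]]
Rcpp::List gvar_fit_cpp(const arma::mat& Sxx, const arma::mat& Sxy,
                        const arma::mat& Syy, int n,
                        double lambda_beta, double lambda_kappa,
                        const arma::mat& B0, const arma::mat& K0,
                        int max_iter = 100, double tol = 1e-4,
                        int glasso_maxit = 200, double glasso_tol = 1e-4) {
  const uword p = Syy.n_rows;
  mat B = B0;
  mat K = K0;
  mat W;
  bool any_jitter = false;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    mat B_old = B;
    mat K_old = K;

    // (i) B update: coordinate descent to (near) convergence given K
    mat G = (Sxy - Sxx * B.t()) * K;
    for (int it = 0; it < 200; ++it) {
      double d = b_sweep(B, G, Sxx, K, lambda_beta);
      if (d < 0.1 * tol) break;
    }

    // (ii) K update: graphical lasso on the residual covariance
    mat S = resid_cov(B, Sxx, Sxy, Syy);
    bool jit = false;
    K = glasso_core(S, lambda_kappa, glasso_maxit, glasso_tol, W, jit);
    any_jitter = any_jitter || jit;

    double change = std::max(abs(B - B_old).max(), abs(K - K_old).max());
    if (change < tol) { converged = true; break; }
  }

  B.clean(1e-12);   // snap numerically-null temporal coefficients

  mat S = resid_cov(B, Sxx, Sxy, Syy);
  double ld, sign;
  log_det(ld, sign, K);
  double loglik = 0.5 * double(n) * (ld - trace(S * K));

  return Rcpp::List::create(
      Rcpp::Named("B") = B, Rcpp::Named("K") = K,
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("iterations") = std::min(iter, max_iter),
      Rcpp::Named("jittered") = any_jitter);
}
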