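#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft_threshold(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// Block coordinate descent for the graphical lasso:
//   max_{Theta > 0}  log det Theta - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// with an unpenalized diagonal, so the working covariance W keeps W_ii = S_ii.
// Each column update solves a lasso problem
//   min_beta 1/2 beta' W11 beta - s12' beta + lambda ||beta||_1
// by coordinate descent, then w12 = W11 beta.  Block updates perform exact
// coordinate ascent on the dual objective log det W, recorded per sweep.
//
// [[Rcpp::export(name = ".glasso_cd")]]
Rcpp::List glasso_cd(const arma::mat& S, double lambda, double tol,
                     int max_iter, double inner_tol, int inner_max,
                     Rcpp::Nullable<Rcpp::NumericMatrix> W_init,
                     Rcpp::Nullable<Rcpp::NumericMatrix> B_init) {
  const int p = S.n_rows;
  mat W = W_init.isNotNull() ? mat(Rcpp::as<mat>(W_init)) : mat(S);
  W.diag() = S.diag();  // diagonal never penalized
  // B(k, j) holds the lasso coefficient of variable k in column j's problem
  mat B = B_init.isNotNull() ? mat(Rcpp::as<mat>(B_init))
                             : mat(p, p, fill::zeros);
  B.diag().zeros();

  std::vector<double> dual_trace;
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      // inner lasso over k != j, warm-started from the previous sweep
      for (int ii = 0; ii < inner_max; ++ii) {
        double delta = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * B(l, j);
          }
          double bk = soft_threshold(grad, lambda) / W(k, k);
          double d = std::fabs(bk - B(k, j));
          if (d > delta) delta = d;
          B(k, j) = bk;
        }
        if (delta < inner_tol) break;
      }
      // w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        double d = std::fabs(w - W(k, j));
        if (d > max_change) max_change = d;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    double ld, sgn;
    log_det(ld, sgn, W);
    dual_trace.push_back(ld);
    if (max_change < tol) {
      converged = true;
      break;
    }
  }
  if (iter > max_iter) iter = max_iter;

  // Recover Theta from the final (W, B):
  //   theta_jj = 1 / (w_jj - w12' beta_j),  theta_12 = -beta_j * theta_jj
  mat Theta(p, p, fill::zeros);
  for (int j = 0; j < p; ++j) {
    double quad = 0.0;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      quad += W(k, j) * B(k, j);
    }
    double tjj = 1.0 / (W(j, j) - quad);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k) {
      if (k == j) continue;
      if (B(k, j) != 0.0) Theta(k, j) = -B(k, j) * tjj;
    }
  }
  Theta = 0.5 * (Theta + Theta.t());

  return Rcpp::List::create(
      Rcpp::Named("w") = W, Rcpp::Named("theta") = Theta,
      Rcpp::Named("beta") = B, Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("dual_trace") = dual_trace);
}
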