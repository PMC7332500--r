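// Graphical lasso: L1-penalized sparse precision-matrix estimation by
// block coordinate descent (one lasso regression per variable per sweep,
// solved by coordinate descent on the current working covariance W).
// Off-diagonal entries are penalized; the diagonal of W is fixed at
// S_jj + lambda. Exact zeros in the lasso coefficients become exact
// zeros (non-edges) in the returned precision matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export]]
Rcpp::List cpp_glasso(const arma::mat& S, double lambda, double tol,
                      int max_iter) {
  const uword p = S.n_rows;
  mat W = S;
  W.diag() += lambda;
  mat Beta(p, p, fill::zeros);  // Beta(i, j): lasso coefficient of var i in column j's problem

  // convergence scale: average absolute off-diagonal of S
  double s_off = 0.0;
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) s_off += std::fabs(S(i, j));
  s_off /= std::max(1.0, (double) (p * p - p));
  const double thr = tol * std::max(s_off, 1e-12);

  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter && p > 1; ++it) {
    double maxdiff = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec nj(p - 1);
      uword c = 0;
      for (uword i = 0; i < p; ++i) if (i != j) nj(c++) = i;

      mat W11 = W.submat(nj, nj);
      vec s12 = S.col(j);
      s12 = s12(nj);
      vec b = Beta.col(j);
      b = b(nj);

      // coordinate descent on 0.5 b'W11 b - s12'b + lambda ||b||_1
      for (int cd = 0; cd < 200; ++cd) {
        double del = 0.0;
        for (uword t = 0; t < p - 1; ++t) {
          double r = s12(t) - dot(W11.row(t), b) + W11(t, t) * b(t);
          double bn = soft(r, lambda) / W11(t, t);
          del = std::max(del, std::fabs(bn - b(t)));
          b(t) = bn;
        }
        if (del < 0.1 * thr) break;
      }

      vec w12 = W11 * b;
      for (uword t = 0; t < p - 1; ++t) {
        maxdiff = std::max(maxdiff, std::fabs(W(nj(t), j) - w12(t)));
        W(nj(t), j) = w12(t);
        W(j, nj(t)) = w12(t);
        Beta(nj(t), j) = b(t);
      }
    }
    if (maxdiff < thr) { converged = true; ++it; break; }
  }

  // recover Theta from the final W and regression coefficients
  mat Theta(p, p, fill::zeros);
  if (p == 1) {
    Theta(0, 0) = 1.0 / W(0, 0);
  } else {
    for (uword j = 0; j < p; ++j) {
      double dot_wb = 0.0;
      for (uword i = 0; i < p; ++i)
        if (i != j) dot_wb += W(i, j) * Beta(i, j);
      double tjj = 1.0 / (W(j, j) - dot_wb);
      Theta(j, j) = tjj;
      for (uword i = 0; i < p; ++i)
        if (i != j && Beta(i, j) != 0.0) Theta(i, j) = -Beta(i, j) * tjj;
    }
    // symmetrize; an entry is a structural zero only when both column
    // problems excluded it
    for (uword i = 0; i < p; ++i) {
      for (uword j = i + 1; j < p; ++j) {
        if (Theta(i, j) == 0.0 && Theta(j, i) == 0.0) continue;
        double v = 0.5 * (Theta(i, j) + Theta(j, i));
        Theta(i, j) = v;
        Theta(j, i) = v;
      }
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("Theta") = Theta,
    Rcpp::Named("W") = W,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("converged") = converged);
}
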