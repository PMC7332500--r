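// Small dense active-set QP solvers used by the constrained alternating
// least-squares factorization (methylation deconvolution) and the
// proportion-conditioned expression regression. Problem sizes are tiny
// (k cell types, k <= ~10); exactness of the KKT conditions matters more
// than asymptotic speed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double KKT_EPS = 1e-10;

// min 0.5 x'Gx - a'x  s.t.  sum(x) = 1, x >= 0.
// Active-set on the nonnegativity bounds; the equality constraint is kept
// in the KKT system throughout, so sum(x) == 1 holds exactly at return.
static vec simplex_qp(const mat& G, const vec& a, int maxit = 500) {
  const uword k = G.n_rows;
  std::vector<int> state(k, 0);  // 0 free, 1 clamped at zero
  vec x(k, fill::zeros);

  for (int it = 0; it < maxit; ++it) {
    uvec F(k);
    uword nf = 0;
    for (uword i = 0; i < k; ++i) if (state[i] == 0) F(nf++) = i;
    F.resize(nf);

    mat K(nf + 1, nf + 1, fill::zeros);
    K.submat(0, 0, nf - 1, nf - 1) = G.submat(F, F);
    for (uword i = 0; i < nf; ++i) { K(i, nf) = 1.0; K(nf, i) = 1.0; }
    vec rhs(nf + 1);
    rhs.head(nf) = a(F);
    rhs(nf) = 1.0;

    vec sol;
    if (!solve(sol, K, rhs, solve_opts::no_approx)) sol = pinv(K) * rhs;
    vec xf = sol.head(nf);
    double mu = sol(nf);

    if (nf > 1 && xf.min() < -KKT_EPS) {
      uword j = xf.index_min();
      state[F(j)] = 1;
      continue;
    }

    x.zeros();
    x(F) = clamp(xf, 0.0, datum::inf);
    x /= accu(x);  // guard: exact simplex under roundoff

    // dual feasibility of clamped coordinates: lambda_i = (Gx - a)_i + mu >= 0
    vec g = G * x - a;
    double worst = -KKT_EPS;
    int wi = -1;
    for (uword i = 0; i < k; ++i) {
      if (state[i] == 1) {
        double lam = g(i) + mu;
        if (lam < worst) { worst = lam; wi = (int) i; }
      }
    }
    if (wi < 0) return x;
    state[wi] = 0;
  }
  return x;
}

// min 0.5 x'Gx - a'x  s.t.  lo <= x <= hi (hi entries may be +Inf).
static vec box_qp(const mat& G, const vec& a, const vec& lo, const vec& hi,
                  int maxit = 500) {
  const uword k = G.n_rows;
  std::vector<int> state(k, 0);  // 0 free, -1 at lo, +1 at hi
  vec x(k, fill::zeros);

  for (int it = 0; it < maxit; ++it) {
    uvec F(k), Bnd(k);
    uword nf = 0, nb = 0;
    for (uword i = 0; i < k; ++i) {
      if (state[i] == 0) F(nf++) = i; else Bnd(nb++) = i;
    }
    F.resize(nf); Bnd.resize(nb);

    x.zeros();
    for (uword b = 0; b < nb; ++b) {
      uword i = Bnd(b);
      x(i) = (state[i] < 0) ? lo(i) : hi(i);
    }

    if (nf > 0) {
      vec rhs = a(F);
      if (nb > 0) rhs -= G.submat(F, Bnd) * x(Bnd);
      vec xf;
      if (!solve(xf, G.submat(F, F), rhs, solve_opts::no_approx))
        xf = pinv(G.submat(F, F)) * rhs;
      x(F) = xf;

      // primal feasibility: clamp the worst violator
      double worst = KKT_EPS;
      int wi = -1, dir = 0;
      for (uword f = 0; f < nf; ++f) {
        uword i = F(f);
        if (lo(i) - x(i) > worst) { worst = lo(i) - x(i); wi = (int) i; dir = -1; }
        if (std::isfinite(hi(i)) && x(i) - hi(i) > worst) {
          worst = x(i) - hi(i); wi = (int) i; dir = 1;
        }
      }
      if (wi >= 0) { state[wi] = dir; continue; }
    }

    // dual feasibility: at lo need gradient >= 0, at hi need gradient <= 0
    vec g = G * x - a;
    double worst = KKT_EPS;
    int wi = -1;
    for (uword b = 0; b < nb; ++b) {
      uword i = Bnd(b);
      double viol = (state[i] < 0) ? -g(i) : g(i);
      if (viol > worst) { worst = viol; wi = (int) i; }
    }
    if (wi < 0) {
      for (uword i = 0; i < k; ++i) {
        if (std::isfinite(lo(i)) && x(i) < lo(i)) x(i) = lo(i);
        if (std::isfinite(hi(i)) && x(i) > hi(i)) x(i) = hi(i);
      }
      return x;
    }
    state[wi] = 0;
  }
  return x;
}

// [[Rcpp::export]]
arma::vec cpp_simplex_ls(const arma::mat& A, const arma::vec& b) {
  return simplex_qp(A.t() * A, A.t() * b);
}

// [[Rcpp::export]]
arma::vec cpp_box_ls(const arma::mat& A, const arma::vec& b,
                     const arma::vec& lo, const arma::vec& hi) {
  return box_qp(A.t() * A, A.t() * b, lo, hi);
}

// Nonnegative least squares for every row of Y against the rows of P:
// per row y, min || y - e P ||^2 s.t. e >= 0. Returns genes x k matrix.
// [[Rcpp::export]]
arma::mat cpp_nnls_rows(const arma::mat& Y, const arma::mat& P) {
  const uword k = P.n_rows, ng = Y.n_rows;
  mat G = P * P.t();
  vec lo(k, fill::zeros), hi(k); hi.fill(datum::inf);
  mat E(ng, k);
  for (uword g = 0; g < ng; ++g) {
    vec a = P * Y.row(g).t();
    E.row(g) = box_qp(G, a, lo, hi).t();
  }
  return E;
}

// Simplex-constrained least squares for every column of B against M:
// per column b, min || b - M p ||^2 s.t. p on the probability simplex.
// [[Rcpp::export]]
arma::mat cpp_simplex_cols(const arma::mat& B, const arma::mat& M) {
  const uword k = M.n_cols, n = B.n_cols;
  mat G = M.t() * M;
  mat P(k, n);
  for (uword j = 0; j < n; ++j) {
    vec a = M.t() * B.col(j);
    P.col(j) = simplex_qp(G, a);
  }
  return P;
}

// Alternating constrained least squares for B ~ M P with M in [0,1] and
// P columns on the simplex. Returns the factorization together with the
// RSS trace (non-increasing by construction: each half step is an exact
// constrained least-squares solve).
// [[Rcpp::export]]
Rcpp::List cpp_als_deconv(const arma::mat& B, const arma::mat& Pinit,
                          double tol, int max_iter) {
  const uword np = B.n_rows, n = B.n_cols, k = Pinit.n_rows;
  mat P = Pinit;
  mat M(np, k, fill::zeros);
  vec lo(k, fill::zeros), hi(k, fill::ones);

  std::vector<double> rss_trace;
  double rss_prev = datum::inf;
  bool converged = false;
  int it = 0;

  for (it = 0; it < max_iter; ++it) {
    // M-step: per probe, box-constrained LS against rows of P
    mat Gp = P * P.t();
    for (uword i = 0; i < np; ++i) {
      vec a = P * B.row(i).t();
      M.row(i) = box_qp(Gp, a, lo, hi).t();
    }
    // P-step: per sample, simplex-constrained LS against columns of M
    mat Gm = M.t() * M;
    for (uword j = 0; j < n; ++j) {
      vec a = M.t() * B.col(j);
      P.col(j) = simplex_qp(Gm, a);
    }
    double rss = accu(square(B - M * P));
    rss_trace.push_back(rss);
    if (std::isfinite(rss_prev)) {
      double rel = (rss_prev - rss) / std::max(rss_prev, 1e-300);
      if (rel < tol) { converged = true; ++it; break; }
    }
    rss_prev = rss;
  }

  return Rcpp::List::create(
    Rcpp::Named("M") = M,
    Rcpp::Named("P") = P,
    Rcpp::Named("rss") = rss_trace.empty() ? datum::nan : rss_trace.back(),
    Rcpp::Named("rss_trace") = rss_trace,
    Rcpp::Named("n_iter") = it,
    Rcpp::Named("converged") = converged);
}
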