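// Linear quantile regression by check-loss minimization.
//
// Core solver: Frisch-Newton primal-dual interior point with Mehrotra
// predictor-corrector steps on the bounded-variables dual LP
//
//   max_a  y'a   s.t.  X'a = (1 - tau) X'1,   0 <= a <= 1,
//
// whose equality multipliers are the regression coefficients. A vertex
// "polish" finishes the job: a minimizer interpolates p observations
// exactly (barring degeneracy), so the p rows with the smallest absolute
// residuals are solved through exactly and kept when that lowers the
// loss. The contract is the check-loss post-condition, not a particular
// algorithm; a Hunter-Lange MM fallback covers pathological instances.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double check_loss_cpp(const arma::vec& r, double tau) {
  double s = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i)
    s += r[i] * (tau - (r[i] < 0.0 ? 1.0 : 0.0));
  return s;
}

// Largest step in [0, 1] keeping v + alpha*dv >= (1 - 0.9995) * v.
static double step_len(const arma::vec& v, const arma::vec& dv) {
  double a = 1.0;
  for (arma::uword i = 0; i < v.n_elem; ++i)
    if (dv[i] < 0.0) a = std::min(a, -0.9995 * v[i] / dv[i]);
  return a;
}

// Interior point; returns true on convergence, beta holds the solution.
static bool ip_fit(const arma::mat& X, const arma::vec& y, double tau,
                   arma::vec& beta, int maxit, double tol) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  // LP in x = a: min c'x, Ax = b, 0 <= x <= 1, with A = X', c = -y.
  arma::vec c = -y;
  arma::vec x(n); x.fill(1.0 - tau);          // exactly feasible interior
  arma::vec s(n); s.fill(tau);
  arma::vec yd;                                // equality duals (= -beta)
  if (!arma::solve(yd, X.t() * X, X.t() * c, arma::solve_opts::likely_sympd))
    return false;
  arma::vec rd = c - X * yd;
  arma::vec z = arma::clamp(rd, 0.0, arma::datum::inf) + 1e-4;
  arma::vec w = z - rd;                        // so A'y + z - w = c exactly
  const double cscale = 1.0 + arma::norm(c, "inf");

  for (int it = 0; it < maxit; ++it) {
    arma::vec rb = (1.0 - tau) * arma::sum(X, 0).t() - X.t() * x;
    arma::vec rc = c - X * yd - z + w;
    double mu = (arma::dot(x, z) + arma::dot(s, w)) / (2.0 * n);
    double gap = mu * 2.0 * n / (1.0 + std::abs(arma::dot(c, x)));
    if (gap < tol && arma::norm(rb, "inf") / cscale < tol &&
        arma::norm(rc, "inf") / cscale < tol) {
      beta = -yd;
      return true;
    }
    arma::vec d = 1.0 / (z / x + w / s);       // diagonal scaling
    arma::mat ADA = X.t() * (X.each_col() % d);
    ADA.diag() += 1e-12 * (1.0 + arma::trace(ADA) / p);
    ADA = arma::symmatu(ADA);          // exact symmetry for chol
    arma::mat R;
    if (!arma::chol(R, ADA)) return false;

    // predictor (affine) direction; r_u = 1 - x - s = 0 is maintained
    arma::vec rhs_c = rc + z - w;
    arma::vec t1 = rb + X.t() * (d % rhs_c);
    arma::vec dy = arma::solve(arma::trimatu(R),
                   arma::solve(arma::trimatl(R.t()), t1));
    arma::vec dx = d % (X * dy - rhs_c);
    arma::vec ds = -dx;
    arma::vec dz = -z - (z / x) % dx;
    arma::vec dw = -w - (w / s) % ds;
    double ap = std::min(step_len(x, dx), step_len(s, ds));
    double ad = std::min(step_len(z, dz), step_len(w, dw));
    double mu_aff = (arma::dot(x + ap * dx, z + ad * dz) +
                     arma::dot(s + ap * ds, w + ad * dw)) / (2.0 * n);
    double sigma = std::pow(mu_aff / mu, 3.0);
    sigma = std::min(sigma, 1.0);

    // corrector: add centering + second-order terms, reuse factorization
    arma::vec cx = (sigma * mu - dx % dz) / x;
    arma::vec cs = (sigma * mu - ds % dw) / s;
    rhs_c = rc + z - w - cx + cs;
    t1 = rb + X.t() * (d % rhs_c);
    dy = arma::solve(arma::trimatu(R),
         arma::solve(arma::trimatl(R.t()), t1));
    dx = d % (X * dy - rhs_c);
    ds = -dx;
    dz = -z - (z / x) % dx + cx;
    dw = -w - (w / s) % ds + cs;
    ap = std::min(step_len(x, dx), step_len(s, ds));
    ad = std::min(step_len(z, dz), step_len(w, dw));

    x += ap * dx; s += ap * ds;
    yd += ad * dy; z += ad * dz; w += ad * dw;
  }
  beta = -yd;
  return false;
}

// Hunter-Lange MM stage at fixed smoothing eps (fallback refinement).
static void mm_stage(const arma::mat& X, const arma::vec& y, double tau,
                     arma::vec& beta, double eps, int maxit, double tol) {
  const arma::uword p = X.n_cols;
  arma::vec xt1 = arma::sum(X, 0).t() * (2.0 * tau - 1.0);
  double loss_old = check_loss_cpp(y - X * beta, tau);
  for (int it = 0; it < maxit; ++it) {
    arma::vec r = y - X * beta;
    arma::vec w = 1.0 / arma::clamp(arma::abs(r), eps, arma::datum::inf);
    arma::mat Xw = X.each_col() % w;
    arma::mat A = X.t() * Xw;
    arma::vec b = Xw.t() * y + xt1;
    A.diag() += 1e-10 * arma::trace(A) / p;
    arma::vec beta_new;
    if (!arma::solve(beta_new, A, b, arma::solve_opts::likely_sympd))
      break;
    double loss_new = check_loss_cpp(y - X * beta_new, tau);
    if (loss_new <= loss_old) beta = beta_new;
    if (std::abs(loss_old - loss_new) <= tol * (1.0 + std::abs(loss_old)))
      break;
    loss_old = std::min(loss_old, loss_new);
  }
}

// Exact fit through the p full-rank rows with smallest |residual|.
static bool vertex_polish(const arma::mat& X, const arma::vec& y, double tau,
                          arma::vec& beta, double& loss) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  if (n < p) return false;
  arma::vec r = arma::abs(y - X * beta);
  arma::uvec ord = arma::stable_sort_index(r);       // ties: lowest index first
  // Greedily collect p rows whose span has full rank (modified Gram-Schmidt).
  arma::mat basis(p, p, arma::fill::zeros);
  arma::uvec pick(p);
  arma::uword got = 0;
  double scal = arma::norm(X, "fro") / std::sqrt((double)n) + 1e-300;
  for (arma::uword k = 0; k < n && got < p; ++k) {
    arma::vec v = X.row(ord[k]).t();
    for (arma::uword j = 0; j < got; ++j)
      v -= arma::dot(basis.col(j), v) * basis.col(j);
    double nv = arma::norm(v);
    if (nv > 1e-8 * scal) {
      basis.col(got) = v / nv;
      pick[got] = ord[k];
      ++got;
    }
  }
  if (got < p) return false;
  arma::mat Xs = X.rows(pick);
  arma::vec beta_v;
  if (!arma::solve(beta_v, Xs, y.elem(pick))) return false;
  double loss_v = check_loss_cpp(y - X * beta_v, tau);
  if (loss_v <= loss) { beta = beta_v; loss = loss_v; return true; }
  return false;
}

static arma::vec fit_one(const arma::mat& X, const arma::vec& y, double tau,
                         int maxit, double tol, double& loss_out) {
  const arma::uword p = X.n_cols;
  arma::vec beta;
  bool ok = ip_fit(X, y, tau, beta, maxit, tol);
  if (!ok || !beta.is_finite()) {
    if (!beta.is_finite() || beta.n_elem != p) {
      if (!arma::solve(beta, X, y)) beta = arma::zeros<arma::vec>(p);
    }
    double scale = arma::stddev(y);
    if (!std::isfinite(scale) || scale <= 0.0) scale = 1.0;
    const double stages[3] = {1e-3, 1e-6, 1e-10};
    for (int s = 0; s < 3; ++s)
      mm_stage(X, y, tau, beta, stages[s] * scale, 200, 1e-12);
  }
  double loss = check_loss_cpp(y - X * beta, tau);
  vertex_polish(X, y, tau, beta, loss);
  loss_out = loss;
  return beta;
}

// Column standardization for solver conditioning: non-constant columns
// are centred and scaled to unit sd, a constant column (the intercept)
// absorbs the centring shift on back-transform. The fitted loss is
// invariant (same column space); coefficients are mapped back exactly.
struct ColStd {
  arma::vec m, s;
  arma::sword icept;          // index of the constant column, -1 if none
};

static ColStd make_std(const arma::mat& X, arma::mat& Xs) {
  const arma::uword p = X.n_cols;
  ColStd st;
  st.m = arma::zeros<arma::vec>(p);
  st.s = arma::ones<arma::vec>(p);
  st.icept = -1;
  Xs = X;
  for (arma::uword j = 0; j < p; ++j) {
    double sj = arma::stddev(X.col(j));
    if (sj > 0.0) continue;
    double c = X(0, j);
    if (st.icept < 0 && c != 0.0) { st.icept = j; st.s[j] = c; }
  }
  for (arma::uword j = 0; j < p; ++j) {
    if ((arma::sword)j == st.icept) { Xs.col(j).fill(1.0); continue; }
    double sj = arma::stddev(X.col(j));
    if (sj > 0.0) {
      if (st.icept >= 0) st.m[j] = arma::mean(X.col(j));
      st.s[j] = sj;
      Xs.col(j) = (X.col(j) - st.m[j]) / sj;
    }
  }
  return st;
}

static arma::vec unstd_beta(const arma::vec& bs, const ColStd& st) {
  arma::vec b = bs / st.s;
  if (st.icept >= 0) {
    double shift = 0.0;
    for (arma::uword j = 0; j < bs.n_elem; ++j)
      if ((arma::sword)j != st.icept) shift += st.m[j] * bs[j] / st.s[j];
    b[st.icept] -= shift / st.s[st.icept];
  }
  return b;
}

//' @noRd
// [[Rcpp::export(name = ".qr_fit_cpp")]]
List qr_fit_cpp(const arma::mat& X, const arma::vec& y, double tau,
                int maxit = 50, double tol = 1e-10) {
  arma::mat Xs;
  ColStd st = make_std(X, Xs);
  double loss;
  arma::vec beta = unstd_beta(fit_one(Xs, y, tau, maxit, tol, loss), st);
  loss = check_loss_cpp(y - X * beta, tau);
  return List::create(_["coefficients"] = beta, _["loss"] = loss);
}

//' @noRd
// [[Rcpp::export(name = ".qr_process_cpp")]]
List qr_process_cpp(const arma::mat& X, const arma::vec& y,
                    const arma::vec& taus, int maxit = 50,
                    double tol = 1e-10) {
  const arma::uword M = taus.n_elem, p = X.n_cols;
  arma::mat Xs;
  ColStd st = make_std(X, Xs);
  arma::mat coef(M, p);
  arma::vec loss(M);
  for (arma::uword m = 0; m < M; ++m) {
    double l;
    arma::vec b = unstd_beta(fit_one(Xs, y, taus[m], maxit, tol, l), st);
    coef.row(m) = b.t();
    loss[m] = check_loss_cpp(y - X * b, taus[m]);
  }
  return List::create(_["coef"] = coef, _["loss"] = loss);
}
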