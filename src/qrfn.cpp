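#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Frisch-Newton primal-dual interior point for quantile regression.
//
// The check-loss minimisation min_b sum_i rho_tau(y_i - x_i'b) is the
// dual of the bounded linear program
//     min c'a  s.t.  X'a = (1-tau) X'1,  0 <= a <= 1,   c = -y,
// and the multiplier on the equality constraint is -b.  We run a
// Mehrotra predictor-corrector on that LP; the per-iteration cost is
// one p x p normal-equation solve, so n in the tens of thousands with
// a handful of terms is cheap.
static vec qr_fn_core(const mat& X, const vec& y, double tau,
                      double eps, int maxit, bool& ok, int& iters,
                      double* final_gap = nullptr) {
  const uword n = X.n_rows;
  const vec c = -y;
  const vec b_ = (1.0 - tau) * sum(X, 0).t();
  vec x(n); x.fill(1.0 - tau);       // strictly interior start
  vec s(n); s.fill(tau);
  vec beta_d = solve(X.t() * X, X.t() * c);
  vec r = c - X * beta_d;
  const double d0 = 0.1 * mean(abs(r)) + 1e-4;
  vec z = clamp(r, 0.0, datum::inf) + d0;
  vec w = z - r;                     // keeps z - w = r with w > 0
  double gap = dot(x, z) + dot(s, w);
  ok = false;

  auto maxstep = [](const vec& v, const vec& dv) {
    double a = std::numeric_limits<double>::infinity();
    for (uword i = 0; i < v.n_elem; ++i)
      if (dv(i) < 0) a = std::min(a, -v(i) / dv(i));
    return a;
  };

  int it = 0;
  double rel = datum::inf;
  for (; it < maxit; ++it) {
    const double pobj = dot(c, x);
    const double dobj = dot(b_, beta_d) - accu(w);
    rel = std::abs(pobj - dobj) / (1.0 + std::abs(pobj));
    if (rel < eps) {
      ok = true;
      break;
    }
    const vec q = 1.0 / (z / x + w / s);
    const vec rc = c - X * beta_d - z + w;
    const vec rb = b_ - X.t() * x;
    const mat XQ = X.each_col() % q;
    mat M = X.t() * XQ;

    // affine predictor (mu = 0)
    vec rhat = rc + z - w;
    vec dy;
    if (!solve(dy, M, rb + XQ.t() * rhat, solve_opts::no_approx)) break;
    vec dx = q % (X * dy - rhat);
    vec dz = -z - z % dx / x;
    vec dw = -w + w % dx / s;
    double a0 = std::min({1.0,
                          maxstep(x, dx), maxstep(s, -dx),
                          maxstep(z, dz), maxstep(w, dw)});
    const double mu = gap / (2.0 * n);
    const double ga = dot(x + a0 * dx, z + a0 * dz) +
                      dot(s - a0 * dx, w + a0 * dw);
    const double mus = std::pow(ga / gap, 3.0) * mu;

    // corrector with second-order terms (ds = -dx)
    const vec v1x = (mus - dx % dz) / x - z;
    const vec v2s = (mus + dx % dw) / s - w;
    rhat = rc - v1x + v2s;
    if (!solve(dy, M, rb + XQ.t() * rhat, solve_opts::no_approx)) break;
    dx = q % (X * dy - rhat);
    dz = v1x - z % dx / x;
    dw = v2s + w % dx / s;
    const double ap = 0.9995 * std::min(maxstep(x, dx), maxstep(s, -dx));
    const double ad = 0.9995 * std::min(maxstep(z, dz), maxstep(w, dw));
    const double a = std::min({1.0, ap, ad});
    x += a * dx;  s -= a * dx;
    z += a * dz;  w += a * dw;
    beta_d += a * dy;
    gap = dot(x, z) + dot(s, w);
  }
  iters = it;
  if (final_gap) *final_gap = rel;
  return -beta_d;
}

// [[Rcpp::export]]
Rcpp::List qrfn_fit(const arma::mat& X, const arma::vec& y, double tau,
                    double eps = 1e-10, int maxit = 100) {
  bool ok = false;
  int iters = 0;
  double gap = 0.0;
  vec beta = qr_fn_core(X, y, tau, eps, maxit, ok, iters, &gap);
  return Rcpp::List::create(Rcpp::Named("coefficients") = beta,
                            Rcpp::Named("converged") = ok,
                            Rcpp::Named("iterations") = iters,
                            Rcpp::Named("rel_gap") = gap);
}

// Nonparametric pair bootstrap: resample rows with replacement and
// refit.  Uses R's RNG so results are reproducible under set.seed().
// Resamples that lose rank or fail to converge are redrawn (counted).
// [[Rcpp::export]]
Rcpp::List qrfn_boot(const arma::mat& X, const arma::vec& y, double tau,
                     int B, double eps = 1e-8, int maxit = 100,
                     int max_redraw = 50) {
  const uword n = X.n_rows, p = X.n_cols;
  mat out(B, p);
  int redraws = 0;
  Rcpp::RNGScope scope;
  for (int b = 0; b < B; ++b) {
    bool ok = false;
    int tries = 0;
    vec beta(p, fill::value(datum::nan));
    while (!ok && tries <= max_redraw) {
      uvec idx(n);
      for (uword i = 0; i < n; ++i)
        idx(i) = static_cast<uword>(unif_rand() * n);
      mat Xb = X.rows(idx);
      vec yb = y(idx);
      if (arma::rank(Xb) < p) {   // degenerate resample: redraw
        ++tries; ++redraws;
        continue;
      }
      int iters = 0;
      beta = qr_fn_core(Xb, yb, tau, eps, maxit, ok, iters);
      if (!ok) { ++tries; ++redraws; }
    }
    out.row(b) = beta.t();
    if (b % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("draws") = out,
                            Rcpp::Named("redraws") = redraws);
}
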