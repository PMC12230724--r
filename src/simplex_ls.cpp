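// Simplex-constrained least squares and the alternating solver for the
// quadratic basis-matrix spectral model.
//
// simplex_ls: min ||A x - y||^2  s.t.  x >= 0, sum(x) = 1
// solved exactly by a Lawson–Hanson style active-set method with the
// equality constraint kept in the KKT system at every subproblem.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double KKT_TOL = 1e-12;

// Solve the equality-constrained LS subproblem restricted to the free set:
//   min ||A_F z - y||  s.t. 1' z = 1
// via the KKT system [ G 1 ; 1' 0 ] [z; mu] = [ A_F' y ; 1 ].
static bool solve_eq_subproblem(const mat& G, const vec& Aty,
                                const uvec& F, vec& zF, double& mu) {
  const uword k = F.n_elem;
  mat K(k + 1, k + 1, fill::zeros);
  K.submat(0, 0, k - 1, k - 1) = G.submat(F, F);
  K.submat(0, k, k - 1, k).fill(1.0);
  K.submat(k, 0, k, k - 1).fill(1.0);
  vec rhs(k + 1);
  rhs.subvec(0, k - 1) = Aty.elem(F);
  rhs(k) = 1.0;
  vec sol;
  bool ok = solve(sol, K, rhs, solve_opts::no_approx);
  if (!ok) {
    // rank-deficient free set: minimum-norm KKT solution
    sol = pinv(K) * rhs;
  }
  zF = sol.subvec(0, k - 1);
  mu = sol(k);
  return ok;
}

// Core routine operating on precomputed G = A'A and Aty = A'y.
static vec simplex_ls_core(const mat& G, const vec& Aty, double scale,
                           bool& rank_flag) {
  const uword p = G.n_rows;
  vec x(p);
  x.fill(1.0 / p);
  uvec inF(p, fill::ones);          // start with all coordinates free
  rank_flag = false;
  const double tol = KKT_TOL * std::max(scale, 1.0);
  // stall guard: degenerate vertices can cycle between releasing and
  // re-pinning zero-weight coordinates; keep the best iterate and stop
  // when the quadratic objective stops improving
  auto qobj = [&](const vec& v) {
    return 0.5 * as_scalar(v.t() * G * v) - dot(Aty, v);
  };
  vec best_x = x; double best_f = qobj(x); int stall = 0;

  for (uword outer = 0; outer < 200 * p; ++outer) {
    uvec F = find(inF == 1);
    vec zF; double mu;
    bool ok = solve_eq_subproblem(G, Aty, F, zF, mu);
    if (!ok) rank_flag = true;

    if (zF.min() >= -tol) {
      x.zeros();
      x.elem(F) = clamp(zF, 0.0, datum::inf);
      x /= accu(x);
      double f = qobj(x);
      if (f < best_f - tol * 1e-3) { best_f = f; best_x = x; stall = 0; }
      else if (++stall > 3) return best_x;
      // dual feasibility for coordinates pinned at zero
      vec g = G * x - Aty;
      uvec Z = find(inF == 0);
      if (Z.n_elem == 0) return x;
      vec w = g.elem(Z) - mu;
      uword j_rel = w.index_min();
      if (w(j_rel) >= -tol) return x;
      inF(Z(j_rel)) = 1;            // release the most violating bound
      continue;
    }

    // step from the current feasible x toward z, stopping at the boundary
    vec z(p, fill::zeros);
    z.elem(F) = zF;
    double alpha = 1.0;
    for (uword idx = 0; idx < F.n_elem; ++idx) {
      uword i = F(idx);
      if (z(i) < x(i)) {
        double a = x(i) / (x(i) - z(i));
        if (a < alpha) alpha = a;
      }
    }
    x += alpha * (z - x);
    for (uword i = 0; i < p; ++i) {
      if (inF(i) == 1 && x(i) <= tol) { x(i) = 0.0; inF(i) = 0; }
    }
    if (accu(inF) == 0) {           // safeguard: re-open the best coordinate
      uword j = (G.diag() * 0 + Aty).index_max();
      inF(j) = 1; x.zeros(); x(j) = 1.0;
    }
  }
  return (qobj(x) < best_f) ? x : best_x;
}

// [[Rcpp::export]]
Rcpp::List cpp_simplex_ls(const arma::mat& A, const arma::vec& y) {
  mat G = A.t() * A;
  vec Aty = A.t() * y;
  double scale = norm(G, "fro");
  bool rank_flag = false;
  vec x = simplex_ls_core(G, Aty, scale, rank_flag);
  double obj = 0.5 * std::pow(norm(A * x - y), 2.0);
  return Rcpp::List::create(Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = obj,
                            Rcpp::Named("rank_deficient") = rank_flag);
}

// Batch solve with a shared design matrix (one column of Y per problem).
// [[Rcpp::export]]
arma::mat cpp_simplex_ls_batch(const arma::mat& A, const arma::mat& Y) {
  mat G = A.t() * A;
  double scale = norm(G, "fro");
  mat X(A.n_cols, Y.n_cols);
  for (uword j = 0; j < Y.n_cols; ++j) {
    vec Aty = A.t() * Y.col(j);
    bool flag = false;
    X.col(j) = simplex_ls_core(G, Aty, scale, flag);
  }
  return X;
}

// ---- alternating solver for the quadratic model --------------------------
//
// objective f(x) = 0.5 * sum_l ( x' M_l x - cd_l )^2 over the probability
// simplex.  Each iteration linearizes to the effective basis B[l,i] =
// (M_l x)_i, solves the simplex-constrained linear problem, and takes an
// exact line search along the simplex segment so the true objective never
// increases.

static double quartic_obj(const cube& M, const vec& x, const vec& cd) {
  double s = 0.0;
  for (uword l = 0; l < M.n_slices; ++l) {
    double q = as_scalar(x.t() * M.slice(l) * x) - cd(l);
    s += q * q;
  }
  return 0.5 * s;
}

// minimize f(x + t d) for t in [0,1]; f is quartic in t
static double line_search(const cube& M, const vec& x, const vec& d,
                          const vec& cd) {
  const uword L = M.n_slices;
  vec a(L), b(L), c(L);
  for (uword l = 0; l < L; ++l) {
    const mat& S = M.slice(l);
    a(l) = as_scalar(x.t() * S * x) - cd(l);
    b(l) = 2.0 * as_scalar(x.t() * S * d);
    c(l) = as_scalar(d.t() * S * d);
  }
  // f(t) = 0.5 sum (a + b t + c t^2)^2 ; f'(t) cubic: k0 + k1 t + k2 t^2 + k3 t^3
  double k0 = accu(a % b);
  double k1 = accu(b % b + 2.0 * a % c);
  double k2 = 3.0 * accu(b % c);
  double k3 = 2.0 * accu(c % c);
  std::vector<double> cand = {0.0, 1.0};
  if (std::abs(k3) > 0) {
    mat comp(3, 3, fill::zeros);
    comp(1, 0) = 1.0; comp(2, 1) = 1.0;
    comp(0, 2) = -k0 / k3; comp(1, 2) = -k1 / k3; comp(2, 2) = -k2 / k3;
    cx_vec ev = eig_gen(comp);
    for (uword i = 0; i < 3; ++i) {
      if (std::abs(ev(i).imag()) < 1e-9) {
        double t = ev(i).real();
        if (t > 0.0 && t < 1.0) cand.push_back(t);
      }
    }
  } else if (std::abs(k2) > 0) {
    double disc = k1 * k1 - 4.0 * k2 * k0;
    if (disc >= 0) {
      for (double s : { -1.0, 1.0 }) {
        double t = (-k1 + s * std::sqrt(disc)) / (2.0 * k2);
        if (t > 0.0 && t < 1.0) cand.push_back(t);
      }
    }
  } else if (std::abs(k1) > 0) {
    double t = -k0 / k1;
    if (t > 0.0 && t < 1.0) cand.push_back(t);
  }
  double best_t = 0.0, best_f = datum::inf;
  for (double t : cand) {
    vec poly = a + b * t + c * (t * t);
    double f = 0.5 * accu(poly % poly);
    if (f < best_f) { best_f = f; best_t = t; }
  }
  return best_t;
}

// [[Rcpp::export]]
Rcpp::List cpp_quadratic_fit(const arma::cube& M, const arma::vec& cd,
                             const arma::mat& starts, int max_iter,
                             double tol) {
  const uword L = M.n_slices, p = M.n_rows;
  vec best_x; double best_obj = datum::inf;
  int best_start = -1; bool best_conv = false;
  double mscale = 0.0;
  for (uword l = 0; l < L; ++l) mscale = std::max(mscale, norm(M.slice(l), "fro"));

  for (uword s = 0; s < starts.n_cols; ++s) {
    vec x = starts.col(s);
    double f = quartic_obj(M, x, cd);
    bool conv = false;
    for (int it = 0; it < max_iter; ++it) {
      mat B(L, p);
      for (uword l = 0; l < L; ++l) B.row(l) = (M.slice(l) * x).t();
      mat G = B.t() * B;
      vec Bty = B.t() * cd;
      bool flag = false;
      vec z = simplex_ls_core(G, Bty, norm(G, "fro"), flag);
      vec d = z - x;
      if (norm(d, "inf") < 1e-14) { conv = true; break; }
      double t = line_search(M, x, d, cd);
      if (t <= 0.0) { conv = true; break; }
      x += t * d;
      x = clamp(x, 0.0, datum::inf); x /= accu(x);
      double fnew = quartic_obj(M, x, cd);
      if (f - fnew < tol * std::max(1.0, f)) { f = fnew; conv = true; break; }
      f = fnew;
    }
    if (f < best_obj - 1e-15) {
      best_obj = f; best_x = x; best_start = (int)s; best_conv = conv;
    }
  }
  return Rcpp::List::create(Rcpp::Named("x") = best_x,
                            Rcpp::Named("objective") = best_obj,
                            Rcpp::Named("start") = best_start + 1,
                            Rcpp::Named("converged") = best_conv);
}
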