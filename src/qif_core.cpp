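// Quadratic inference function engine for the gFVICM.
//
// theta layout (length k = 2p + 2d, d = q + K + 1):
//   [ beta0 (p) | beta1 (p) | gamma0 (d) | gamma1 (d) ]
// Extended score per subject stacks h blocks of length k (r = h*k):
//   g_i^(l) = mudot_i' A_i^{-1/2} M_l A_i^{-1/2} (y_i - mu_i)
// with M_1 = I and M_2 the exchangeable (ones off-diagonal) or AR(1)
// (ones on the two subdiagonals) basis matrix.
//
// All quantities are computed on the stacked observation vectors; the
// within-subject basis-matrix products are segmented shift/sum operators
// so no per-subject temporaries are allocated.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double MU_EPS = 1e-10;

// truncated power basis and its first two derivatives at values u
static void tp_basis_all(const vec& u, int q, const vec& knots,
                         mat& B, mat& Bd, mat& Bdd) {
  const uword n = u.n_elem, K = knots.n_elem, d = q + K + 1;
  B.set_size(n, d);  Bd.set_size(n, d);  Bdd.set_size(n, d);
  B.col(0).ones();   Bd.col(0).zeros();  Bdd.col(0).zeros();
  if (q >= 1) { B.col(1) = u; Bd.col(1).ones(); Bdd.col(1).zeros(); }
  for (int j = 2; j <= q; ++j) {
    B.col(j)   = B.col(j - 1) % u;
    Bd.col(j)  = j * B.col(j - 1);
    Bdd.col(j) = double(j) * (j - 1) * B.col(j - 2);
  }
  for (uword kk = 0; kk < K; ++kk) {
    uword col = q + 1 + kk;
    const double kap = knots(kk);
    double* b = B.colptr(col);
    double* bd = Bd.colptr(col);
    double* bdd = Bdd.colptr(col);
    for (uword j = 0; j < n; ++j) {
      double w = u(j) - kap;
      if (w > 0.0) {
        // w^(q-2), w^(q-1), w^q by repeated multiplication
        double wq2 = 1.0;
        for (int e = 0; e < q - 2; ++e) wq2 *= w;
        double wq1 = (q >= 2) ? wq2 * w : 1.0;
        b[j] = wq1 * w;
        bd[j] = q * wq1;
        bdd[j] = (q >= 2) ? double(q) * (q - 1) * wq2 : 0.0;
      } else {
        // value and derivatives are 0 at u <= knot
        b[j] = 0.0; bd[j] = 0.0; bdd[j] = 0.0;
      }
    }
  }
}

// segmented second-basis-matrix product: per-subject M2 applied to each
// column of V (subjects are contiguous row blocks starts..ends)
static mat mseg(const mat& V, const uvec& starts, const uvec& ends,
                int structure) {
  const uword n = V.n_rows;
  mat out(size(V), fill::zeros);
  if (structure == 1) {            // exchangeable: J - I per subject
    for (uword i = 0; i < starts.n_elem; ++i) {
      rowvec s = sum(V.rows(starts(i), ends(i)), 0);
      out.rows(starts(i), ends(i)) =
          repmat(s, ends(i) - starts(i) + 1, 1) - V.rows(starts(i), ends(i));
    }
    return out;
  }
  // ar1: ones on the two subdiagonals, blocked by subject
  if (n >= 2) {
    out.rows(1, n - 1) += V.rows(0, n - 2);
    out.rows(0, n - 2) += V.rows(1, n - 1);
    for (uword i = 0; i < starts.n_elem; ++i) {
      uword s = starts(i), e = ends(i);
      if (s > 0) out.row(s) -= V.row(s - 1);
      if (e + 1 < n) out.row(e) -= V.row(e + 1);
    }
  }
  return out;
}

// Solve Cbar x = b with a ridge-jitter fallback when Cbar is numerically
// singular.
static vec safe_solve(mat C, const vec& b, bool& jitter) {
  const uword r = C.n_rows;
  vec x;
  jitter = false;
  double delta = 1e-8 * trace(C) / double(r);
  for (int attempt = 0; attempt < 6; ++attempt) {
    bool ok = solve(x, C, b, solve_opts::likely_sympd + solve_opts::no_approx);
    if (ok && x.is_finite()) return x;
    jitter = true;
    C.diag() += delta;
    delta *= 10.0;
  }
  x = pinv(C) * b;  // last resort
  return x;
}

static mat safe_solve_mat(mat C, const mat& B, bool& jitter) {
  const uword r = C.n_rows;
  mat x;
  double delta = 1e-8 * trace(C) / double(r);
  for (int attempt = 0; attempt < 6; ++attempt) {
    bool ok = solve(x, C, B, solve_opts::likely_sympd + solve_opts::no_approx);
    if (ok && x.is_finite()) return x;
    jitter = true;
    C.diag() += delta;
    delta *= 10.0;
  }
  return pinv(C) * B;
}

// [[Rcpp::export]]
Rcpp::List qif_eval_cpp(const arma::vec& beta0, const arma::vec& beta1,
                        const arma::vec& gamma0, const arma::vec& gamma1,
                        const arma::vec& y, const arma::mat& X,
                        const arma::vec& G, const arma::ivec& ni,
                        int degree, const arma::vec& knots0,
                        const arma::vec& knots1, int structure,
                        bool want_grad, const arma::uvec& grad_cols,
                        bool want_gdot, bool want_scores,
                        bool want_hess, const arma::mat& Cfix) {
  const uword p = X.n_cols, d = gamma0.n_elem, N = ni.n_elem;
  const uword k = 2 * p + 2 * d, n = y.n_elem;
  const int h = (structure == 0) ? 1 : 2;
  const uword r = h * k;

  // subject segmentation and per-row expansions
  uvec starts(N), ends(N), subj(n);
  vec Grow(n), crow(n);
  {
    uword pos = 0;
    for (uword i = 0; i < N; ++i) {
      starts(i) = pos;
      ends(i) = pos + ni(i) - 1;
      for (int j = 0; j < ni(i); ++j) { subj(pos) = i; Grow(pos) = G(i); ++pos; }
    }
  }

  vec u0 = X * beta0, u1 = X * beta1;
  mat B0, Bd0, Bdd0, B1, Bd1, Bdd1;
  tp_basis_all(u0, degree, knots0, B0, Bd0, Bdd0);
  tp_basis_all(u1, degree, knots1, B1, Bd1, Bdd1);

  vec eta = B0 * gamma0 + Grow % (B1 * gamma1);
  uword clamped = 0;
  vec mu(n);
  for (uword j = 0; j < n; ++j) {
    double e = eta(j);
    double m = (e >= 0.0) ? 1.0 / (1.0 + std::exp(-e))
                          : std::exp(e) / (1.0 + std::exp(e));
    if (m < MU_EPS) { m = MU_EPS; ++clamped; }
    if (m > 1.0 - MU_EPS) { m = 1.0 - MU_EPS; ++clamped; }
    mu(j) = m;
  }
  vec v = mu % (1.0 - mu), a = sqrt(v);
  vec resid = y - mu, rr = resid / a;

  vec c0 = Bd0 * gamma0, c1 = Bd1 * gamma1;
  mat etadot(n, k);
  etadot.cols(0, p - 1) = X.each_col() % c0;
  etadot.cols(p, 2 * p - 1) = (X.each_col() % c1).each_col() % Grow;
  etadot.cols(2 * p, 2 * p + d - 1) = B0;
  etadot.cols(2 * p + d, k - 1) = B1.each_col() % Grow;

  // score blocks: z_l = a .* (M_l rr); g_i^(l) = etadot_i' z_l,i
  std::vector<vec> zl(h);
  zl[0] = a % rr;
  if (h == 2) zl[1] = a % mseg(mat(rr), starts, ends, structure).col(0);

  mat gmat(r, N, fill::zeros);
  for (int l = 0; l < h; ++l) {
    const double* z = zl[l].memptr();
    for (uword c = 0; c < k; ++c) {
      const double* col = etadot.colptr(c);
      double* grow_ptr = gmat.memptr() + (l * k + c);
      for (uword j = 0; j < n; ++j)
        grow_ptr[subj(j) * r] += col[j] * z[j];
    }
  }

  // a fixed weight matrix (the GMM distance-statistic convention for
  // nested tests) replaces the empirical second-moment matrix when given
  const bool fixedC = (Cfix.n_rows == r);
  vec gbar = mean(gmat, 1);
  mat Cbar = fixedC ? Cfix : mat(gmat * gmat.t() / double(N));
  bool jitter = false;
  vec w = safe_solve(Cbar, gbar, jitter);
  double Q = double(N) * dot(gbar, w);

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("Q") = Q, Rcpp::Named("gbar") = gbar,
      Rcpp::Named("Cbar") = Cbar, Rcpp::Named("clamped") = (int)clamped,
      Rcpp::Named("jitter") = jitter);

  const bool need_D = want_grad || want_gdot || want_hess;
  if (!need_D) {
    if (want_scores) out["scores"] = gmat;
    return out;
  }

  uvec cols = (grad_cols.n_elem > 0) ? grad_cols : regspace<uvec>(0, k - 1);
  const uword kc = cols.n_elem;

  vec vprime = v % (1.0 - 2.0 * mu);
  vec dv2 = vprime / (2.0 * a);
  vec crv = -(v / a + resid % vprime / (2.0 * pow(a, 3)));
  vec w0 = Bdd0 * gamma0, w1 = Bdd1 * gamma1;

  if (want_grad) {
    // grad Q = 2 sum_i D_i' w (1 - g_i' w), contracted without forming
    // D_i; with a fixed weight matrix the Cbar-variation term drops
    if (fixedC) {
      crow.ones();
    } else {
      vec ti = gmat.t() * w;
      for (uword j = 0; j < n; ++j) crow(j) = 1.0 - ti(subj(j));
    }
    vec grad_full(k, fill::zeros);
    for (int l = 0; l < h; ++l) {
      vec wl = w.subvec(l * k, (l + 1) * k - 1);
      vec wb0 = wl.subvec(0, p - 1), wb1 = wl.subvec(p, 2 * p - 1);
      vec wg0 = wl.subvec(2 * p, 2 * p + d - 1),
          wg1 = wl.subvec(2 * p + d, k - 1);
      vec ew = etadot * wl;
      vec tl = zl[l] / a;
      vec Xwb0 = X * wb0, Xwb1 = X * wb1;
      vec Bd0wg0 = Bd0 * wg0, Bd1wg1 = Bd1 * wg1;
      // term2: da/dtheta contribution
      grad_full += etadot.t() * (crow % ew % dv2 % tl);
      // term3: M d(resid/a) contribution
      vec base = crow % a % ew;
      vec sl = (l == 0) ? base : mseg(mat(base), starts, ends, structure).col(0);
      grad_full += etadot.t() * (crv % sl);
      // term1: d(etadot) contribution, blockwise
      vec base0 = crow % zl[l] % (w0 % Xwb0 + Bd0wg0);
      vec base1 = crow % zl[l] % Grow % (w1 % Xwb1 + Bd1wg1);
      grad_full.subvec(0, p - 1) += X.t() * base0;
      grad_full.subvec(p, 2 * p - 1) += X.t() * base1;
      grad_full.subvec(2 * p, 2 * p + d - 1) +=
          Bd0.t() * (crow % zl[l] % Xwb0);
      grad_full.subvec(2 * p + d, k - 1) +=
          Bd1.t() * (crow % zl[l] % Grow % Xwb1);
    }
    grad_full *= 2.0;
    out["grad"] = vec(grad_full.elem(cols));
  }

  if (want_hess || want_gdot) {
    // expectation-form score derivative (residual terms dropped):
    // Ge^(l) = -(1/N) etadot' diag(a) M_l diag(a) etadot; this is the
    // standard QIF information ingredient and also the Gauss-Newton
    // Hessian building block
    uvec ecols = (grad_cols.n_elem > 0 && !want_gdot) ? grad_cols
                                                      : regspace<uvec>(0, k - 1);
    mat easub = mat(etadot.cols(ecols)).each_col() % a;
    mat ea = etadot.each_col() % a;
    mat Ge(r, ecols.n_elem);
    for (int l = 0; l < h; ++l) {
      mat Min = (l == 0) ? easub : mseg(easub, starts, ends, structure);
      Ge.rows(l * k, (l + 1) * k - 1) = -(ea.t() * Min) / double(N);
    }
    out["Gdot_e"] = Ge;
    if (want_hess) {
      bool j2 = false;
      mat CG = safe_solve_mat(Cbar, Ge, j2);
      out["hess"] = mat(2.0 * double(N) * Ge.t() * CG);
      out["jitter"] = (jitter || j2);
    }
  }

  if (want_gdot) {
    // Gdot = (1/N) sum_i d g_i / d theta, columns `cols`
    mat Gdot(r, kc, fill::zeros);
    mat esub = etadot.cols(cols);
    for (int l = 0; l < h; ++l) {
      vec tl = zl[l] / a;
      mat T = etadot.t() * (esub.each_col() % (dv2 % tl));      // term2
      mat inner = esub.each_col() % crv;
      mat Minner = (l == 0) ? inner : mseg(inner, starts, ends, structure);
      T += (etadot.each_col() % a).t() * Minner;                // term3
      // term1 columnwise
      for (uword cidx = 0; cidx < kc; ++cidx) {
        uword m = cols(cidx);
        if (m < p) {
          vec xz = X.col(m) % zl[l];
          T.submat(0, cidx, p - 1, cidx) += X.t() * (w0 % xz);
          T.submat(2 * p, cidx, 2 * p + d - 1, cidx) += Bd0.t() * xz;
        } else if (m < 2 * p) {
          vec xz = Grow % X.col(m - p) % zl[l];
          T.submat(p, cidx, 2 * p - 1, cidx) += X.t() * (w1 % xz);
          T.submat(2 * p + d, cidx, k - 1, cidx) += Bd1.t() * xz;
        } else if (m < 2 * p + d) {
          T.submat(0, cidx, p - 1, cidx) +=
              X.t() * (Bd0.col(m - 2 * p) % zl[l]);
        } else {
          T.submat(p, cidx, 2 * p - 1, cidx) +=
              X.t() * (Grow % Bd1.col(m - 2 * p - d) % zl[l]);
        }
      }
      Gdot.rows(l * k, (l + 1) * k - 1) = T / double(N);
    }
    out["Gdot"] = Gdot;
  }
  if (want_scores) out["scores"] = gmat;
  return out;
}
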