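// Gaussian-copula machinery for correlated binary longitudinal responses.
//
// A binary vector with marginals p_j and target pairwise correlations is
// generated by thresholding a latent multivariate normal; each latent
// pairwise correlation is solved so the implied binary correlation matches
// its target (the Emrich-Piedmonte construction).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Gauss-Legendre nodes/weights on [-1, 1] via Golub-Welsch, cached
static void gl_rule(int m, vec& nodes, vec& weights) {
  static std::map<int, std::pair<vec, vec>> cache;
  auto it = cache.find(m);
  if (it == cache.end()) {
    mat J(m, m, fill::zeros);
    for (int i = 1; i < m; ++i) {
      double b = i / std::sqrt(4.0 * i * i - 1.0);
      J(i, i - 1) = b;
      J(i - 1, i) = b;
    }
    vec eval;
    mat evec;
    eig_sym(eval, evec, J);
    vec w = 2.0 * square(evec.row(0).t());
    cache[m] = std::make_pair(eval, w);
    it = cache.find(m);
  }
  nodes = it->second.first;
  weights = it->second.second;
}

static inline double phi(double x) {
  return std::exp(-0.5 * x * x) / 2.5066282746310002;
}
static inline double Phi_upper(double x) {  // P(Z > x)
  return 0.5 * std::erfc(x / 1.4142135623730951);
}
static inline double Phi(double x) { return 0.5 * std::erfc(-x / 1.4142135623730951); }

// P(Z1 > h, Z2 > k) for standard bivariate normal with correlation r,
// by Gauss-Legendre quadrature of P(Z2 > k | Z1 = t) phi(t) over t > h.
// [[Rcpp::export]]
double bvn_upper_cpp(double h, double k, double r) {
  if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
  if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
  if (std::abs(r) < 1e-14) return Phi_upper(h) * Phi_upper(k);
  // integrate over the larger threshold for accuracy
  if (std::abs(k) > std::abs(h)) std::swap(h, k);
  double s = std::sqrt(1.0 - r * r);
  double lo = h, hi = std::max(h, -8.5) + 9.0;
  if (hi <= lo) return 0.0;
  vec x, w;
  gl_rule(48, x, w);
  double mid = 0.5 * (lo + hi), half = 0.5 * (hi - lo);
  double acc = 0.0;
  for (uword i = 0; i < x.n_elem; ++i) {
    double t = mid + half * x(i);
    acc += w(i) * phi(t) * Phi_upper((k - r * t) / s);
  }
  return std::max(0.0, std::min(1.0, acc * half));
}

// bivariate normal density at (h, k) with correlation r
static inline double bvn_dens(double h, double k, double r) {
  double s2 = 1.0 - r * r;
  return std::exp(-(h * h - 2.0 * r * h * k + k * k) / (2.0 * s2)) /
         (2.0 * M_PI * std::sqrt(s2));
}

// Solve for the latent Gaussian correlation giving binary correlation
// `target` between thresholded Bernoulli(p1), Bernoulli(p2).
// Returns latent correlation; sets clipped=true if target was outside the
// Frechet-feasible range and had to be clipped.
// [[Rcpp::export]]
Rcpp::List latent_corr_solve_cpp(double p1, double p2, double target,
                                 double tol = 1e-8) {
  double q1 = 1.0 - p1, q2 = 1.0 - p2;
  double z1 = -R::qnorm(p1, 0.0, 1.0, 1, 0);  // P(Z > z1) = p1
  double z2 = -R::qnorm(p2, 0.0, 1.0, 1, 0);
  double sd12 = std::sqrt(p1 * q1 * p2 * q2);
  // Frechet bounds on P11 translate to bounds on the correlation
  double p11_max = std::min(p1, p2), p11_min = std::max(0.0, p1 + p2 - 1.0);
  double cmax = (p11_max - p1 * p2) / sd12, cmin = (p11_min - p1 * p2) / sd12;
  bool clipped = false;
  double tgt = target;
  double margin = 1e-9;
  if (tgt > cmax - margin) { tgt = cmax - margin; clipped = (target > cmax + 1e-12); }
  if (tgt < cmin + margin) { tgt = cmin + margin; clipped = clipped || (target < cmin - 1e-12); }
  double p11_t = tgt * sd12 + p1 * p2;

  // f(r) = P11(r) - p11_t, increasing in r; Newton with bisection safeguard
  double lo = -1.0 + 1e-9, hi = 1.0 - 1e-9;
  // start from the p = 1/2 closed form r = sin(pi rho / 2), a good guess
  // for moderate marginals
  double rr = std::sin(M_PI * tgt / 2.0);
  if (!(rr > lo && rr < hi)) rr = tgt;
  double f = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    f = bvn_upper_cpp(z1, z2, rr) - p11_t;
    if (std::abs(f) < tol * sd12 || (hi - lo) < 1e-14) break;
    if (f > 0) hi = rr; else lo = rr;
    double df = bvn_dens(z1, z2, rr);
    double step = (df > 1e-300) ? f / df : 0.0;
    double cand = rr - step;
    if (!(cand > lo && cand < hi) || step == 0.0) cand = 0.5 * (lo + hi);
    rr = cand;
  }
  return Rcpp::List::create(Rcpp::Named("rho") = rr,
                            Rcpp::Named("clipped") = clipped);
}

// Latent correlation matrix for one subject: marginals pvec (length T),
// target binary correlations rho^|j-l|. Projects to the nearest
// positive-definite correlation matrix (eigenvalue floor) if needed.
// [[Rcpp::export]]
Rcpp::List latent_sigma_cpp(const arma::vec& pvec, double rho,
                            double tol = 1e-8) {
  const uword T = pvec.n_elem;
  mat S(T, T, fill::eye);
  int nclip = 0;
  for (uword j = 0; j + 1 < T; ++j) {
    for (uword l = j + 1; l < T; ++l) {
      double tgt = std::pow(rho, double(l - j));
      Rcpp::List sol = latent_corr_solve_cpp(pvec(j), pvec(l), tgt, tol);
      double rr = Rcpp::as<double>(sol["rho"]);
      if (Rcpp::as<bool>(sol["clipped"])) ++nclip;
      S(j, l) = rr;
      S(l, j) = rr;
    }
  }
  bool pd_fixed = false;
  vec eval;
  mat evec;
  eig_sym(eval, evec, S);
  if (eval.min() < 1e-8) {
    pd_fixed = true;
    eval.transform([](double x) { return x < 1e-8 ? 1e-8 : x; });
    S = evec * diagmat(eval) * evec.t();
    vec dsqrt = 1.0 / sqrt(S.diag());
    S = diagmat(dsqrt) * S * diagmat(dsqrt);
  }
  return Rcpp::List::create(Rcpp::Named("sigma") = S,
                            Rcpp::Named("n_clipped") = nclip,
                            Rcpp::Named("pd_fixed") = pd_fixed);
}
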