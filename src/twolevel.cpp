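// Two-level multivariate-normal likelihood for unbalanced clusters.
//
// The -2 log-likelihood is evaluated from per-cluster sufficient statistics:
// within-cluster deviations load on Sigma_W with n_j - 1 degrees of freedom,
// and each cluster mean is one observation with covariance
// V_j = Sigma_B + Sigma_W / n_j.  Writing Sigma_W = L L' and
// L^{-1} Sigma_B L^{-T} = Q diag(lambda) Q', all V_j share the basis
// T = L^{-T} Q, so V_j^{-1} = T diag(1/(lambda + 1/n_j)) T' and the cluster
// loop reduces to elementwise operations.  The grand means are profiled out
// by GLS at every evaluation.

#define ARMA_WARN_LEVEL 1
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double BIG = 1e12;

// Build one level's implied covariance matrix from its parameter segment.
// type 0: structured path model (path coefficients + log-Cholesky exogenous
//         block + log residual variances), type 1: saturated log-Cholesky.
static bool build_level(const vec& th, int type, const imat& edges,
                        int p, int nexog, mat& Sigma) {
  if (type == 1) {
    mat L(p, p, fill::zeros);
    int idx = 0;
    for (int j = 0; j < p; ++j)
      for (int i = j; i < p; ++i) {
        double v = th(idx++);
        L(i, j) = (i == j) ? std::exp(v) : v;
      }
    Sigma = L * L.t();
    return Sigma.is_finite();
  }
  int ne = edges.n_rows;
  mat B(p, p, fill::zeros);
  for (int e = 0; e < ne; ++e) B(edges(e, 0), edges(e, 1)) = th(e);
  mat Psi(p, p, fill::zeros);
  int idx = ne;
  mat Lx(nexog, nexog, fill::zeros);
  for (int j = 0; j < nexog; ++j)
    for (int i = j; i < nexog; ++i) {
      double v = th(idx++);
      Lx(i, j) = (i == j) ? std::exp(v) : v;
    }
  Psi.submat(0, 0, nexog - 1, nexog - 1) = Lx * Lx.t();
  for (int j = nexog; j < p; ++j) Psi(j, j) = std::exp(th(idx++));
  mat IB = eye(p, p) - B;
  mat A;
  if (!solve(A, IB, eye(p, p), solve_opts::no_approx)) return false;
  Sigma = A * Psi * A.t();
  return Sigma.is_finite();
}

// Core evaluation on covariance matrices; mu of length 0 requests profiling.
static double m2ll_mats(const mat& SW, const mat& SB, const vec& mu,
                        const Rcpp::List& stats) {
  const Rcpp::List groups = stats["groups"];
  const double cst = Rcpp::as<double>(stats["const_term"]);
  const int p = Rcpp::as<int>(stats["p"]);
  const int ng = groups.size();
  const bool profile = (mu.n_elem == 0);

  double within = 0.0, sum_logdet = 0.0, ytVy = 0.0, qf = 0.0;
  mat P(p, p, fill::zeros);
  vec q(p, fill::zeros);
  std::vector<mat> Ts(ng), Wm(ng), Yt(ng);
  std::vector<uvec> obsl(ng);

  for (int g = 0; g < ng; ++g) {
    Rcpp::List gr = groups[g];
    uvec obs = Rcpp::as<uvec>(gr["obs"]);        // 0-based observed indices
    mat ybar = Rcpp::as<mat>(gr["ybar"]);        // k_g x pg cluster means
    vec n = Rcpp::as<vec>(gr["n"]);
    mat Spool = Rcpp::as<mat>(gr["spool"]);      // pooled within scatter
    double dfw = Rcpp::as<double>(gr["dfw"]);

    mat SWg = SW.submat(obs, obs), SBg = SB.submat(obs, obs);
    mat Lw;
    if (!chol(Lw, SWg, "lower")) return BIG;
    double logdetSW = 2.0 * accu(log(Lw.diag()));

    if (Lw.diag().min() < 1e-12) return BIG;
    mat K;
    if (!solve(K, trimatl(Lw), Spool, solve_opts::no_approx)) return BIG;
    // tr(SWg^{-1} Spool) = tr(Lw^{-T} Lw^{-1} Spool)
    mat K2 = solve(trimatl(Lw), K.t());
    within += dfw * logdetSW + trace(K2);

    mat M = solve(trimatl(Lw), SBg.t());
    M = solve(trimatl(Lw), M.t());               // Lw^{-1} SBg Lw^{-T}
    if (!M.is_finite()) return BIG;
    vec lambda; mat Q;
    if (!eig_sym(lambda, Q, symmatu(M))) return BIG;
    if (lambda.min() < -1e-7) return BIG;        // Sigma_B must be PSD
    lambda.transform([](double x) { return x < 0.0 ? 0.0 : x; });

    mat T = solve(trimatu(Lw.t()), Q);           // L^{-T} Q
    int kg = ybar.n_rows, pg = obs.n_elem;
    mat Ytil = ybar * T;
    mat W(kg, pg);
    for (int j = 0; j < kg; ++j) {
      double inv_n = 1.0 / n(j);
      // Helmert-transform Jacobian: the cluster mean is used in place of
      // its orthonormalized version sqrt(n_j) * ybar_j
      sum_logdet += pg * std::log(n(j));
      for (int m = 0; m < pg; ++m) {
        double d = lambda(m) + inv_n;
        if (d <= 0.0) return BIG;
        W(j, m) = 1.0 / d;
        sum_logdet += std::log(d);
      }
    }
    sum_logdet += kg * logdetSW;

    if (profile) {
      rowvec cw = sum(W, 0);
      P.submat(obs, obs) += T * diagmat(cw.t()) * T.t();
      q(obs) += T * sum(W % Ytil, 0).t();
      ytVy += accu(W % Ytil % Ytil);
      Ts[g] = T; Wm[g] = W; Yt[g] = Ytil; obsl[g] = obs;
    } else {
      rowvec mt = (mu(obs).t() * T);
      mat D = Ytil.each_row() - mt;
      qf += accu(W % D % D);
    }
  }

  if (profile) {
    vec muhat;
    if (!solve(muhat, symmatu(P), q,
               solve_opts::no_approx + solve_opts::likely_sympd))
      return BIG;
    qf = ytVy - dot(q, muhat);
    // guard against indefinite P (should not occur with PD within level)
    if (!std::isfinite(qf)) return BIG;
  }

  double out = cst + within + sum_logdet + qf;
  return std::isfinite(out) ? out : BIG;
}

static bool theta_to_mats(const vec& theta, const Rcpp::List& spec,
                          mat& SW, mat& SB) {
  const int p = Rcpp::as<int>(spec["p"]);
  const int nexog = Rcpp::as<int>(spec["nexog"]);
  const int wtype = Rcpp::as<int>(spec["w_type"]);
  const int btype = Rcpp::as<int>(spec["b_type"]);
  const int nw = Rcpp::as<int>(spec["npar_w"]);
  const int nb = Rcpp::as<int>(spec["npar_b"]);
  imat ew = Rcpp::as<imat>(spec["edges_w"]);
  imat eb = Rcpp::as<imat>(spec["edges_b"]);
  if ((int)theta.n_elem != nw + nb) Rcpp::stop("theta has wrong length");
  if (!build_level(theta.subvec(0, nw - 1), wtype, ew, p, nexog, SW))
    return false;
  if (!build_level(theta.subvec(nw, nw + nb - 1), btype, eb, p, nexog, SB))
    return false;
  return true;
}

// [[Rcpp::export]]
double cpp_tl_m2ll_mats(const arma::mat& SW, const arma::mat& SB,
                        const arma::vec& mu, const Rcpp::List& stats) {
  return m2ll_mats(SW, SB, mu, stats);
}

// [[Rcpp::export]]
Rcpp::List cpp_tl_build(const arma::vec& theta, const Rcpp::List& spec) {
  mat SW, SB;
  if (!theta_to_mats(theta, spec, SW, SB))
    Rcpp::stop("parameter vector maps to a non-finite covariance matrix");
  return Rcpp::List::create(Rcpp::Named("sigma_w") = SW,
                            Rcpp::Named("sigma_b") = SB);
}

// [[Rcpp::export]]
double cpp_tl_m2ll(const arma::vec& theta, const Rcpp::List& spec,
                   const Rcpp::List& stats) {
  mat SW, SB;
  if (!theta_to_mats(theta, spec, SW, SB)) return BIG;
  vec mu;
  return m2ll_mats(SW, SB, mu, stats);
}

// [[Rcpp::export]]
arma::vec cpp_tl_grad(const arma::vec& theta, const Rcpp::List& spec,
                      const Rcpp::List& stats, double h = 1e-5,
                      bool central = false) {
  int d = theta.n_elem;
  vec g(d);
  vec th = theta;
  double f0 = central ? 0.0 : cpp_tl_m2ll(theta, spec, stats);
  for (int i = 0; i < d; ++i) {
    double hi = h * (1.0 + std::abs(theta(i)));
    th(i) = theta(i) + hi;
    double fp = cpp_tl_m2ll(th, spec, stats);
    if (central) {
      th(i) = theta(i) - hi;
      double fm = cpp_tl_m2ll(th, spec, stats);
      g(i) = (fp - fm) / (2.0 * hi);
    } else {
      g(i) = (fp - f0) / hi;
    }
    th(i) = theta(i);
  }
  return g;
}
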