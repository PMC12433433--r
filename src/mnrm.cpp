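// Computational core for marginal-maximum-likelihood estimation of the
// scoring-matrix MNRM: category log-probability tables over a quadrature
// grid, the Bock-Aitkin E-step (person posteriors over nodes and expected
// item-category counts), and the per-item Newton update of the M-step.
//
// Conventions: Y is N x J with internal codes 0..K-1 and NA for missing;
// A is J x T (zeros on substantive dimensions an item does not load on);
// C is J x K with C(j,0) fixed at 0 under the estimation convention;
// S is T x K; Theta is Q x T (quadrature nodes, already rotated); logw are
// log prior weights of the nodes.

#include <RcppArmadillo.h>
#include <climits>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static cube log_prob_cube(const mat& A, const mat& C, const mat& S,
                          const mat& Theta) {
  const uword J = A.n_rows, K = S.n_cols, Q = Theta.n_rows;
  cube logP(Q, K, J);
  for (uword j = 0; j < J; ++j) {
    mat M = S.each_col() % A.row(j).t();      // T x K, a_j (.) s
    mat eta = Theta * M;                      // Q x K
    eta.each_row() += C.row(j);
    vec m = max(eta, 1);
    eta.each_col() -= m;
    vec lse = log(sum(exp(eta), 1));
    eta.each_col() -= lse;
    logP.slice(j) = eta;
  }
  return logP;
}

// [[Rcpp::export]]
arma::cube cpp_log_probs(const arma::mat& A, const arma::mat& C,
                         const arma::mat& S, const arma::mat& Theta) {
  return log_prob_cube(A, C, S, Theta);
}

// E-step quantities, fused in one pass over persons. Returns the total
// marginal log-likelihood, per-person log-likelihoods and, optionally,
// node posteriors (Q x N) and expected counts (Q x K x J). Missing
// responses contribute no likelihood factor.
// [[Rcpp::export]]
Rcpp::List cpp_estep(const arma::imat& Y, const arma::mat& A,
                     const arma::mat& C, const arma::mat& S,
                     const arma::mat& Theta, const arma::vec& logw,
                     const bool want_post, const bool want_counts) {
  const uword N = Y.n_rows, J = Y.n_cols, Q = Theta.n_rows;
  const uword K = S.n_cols;
  cube logP = log_prob_cube(A, C, S, Theta);
  vec person_ll(N);
  mat post;
  cube counts;
  const bool need_post = want_post || want_counts;
  if (need_post) post.set_size(Q, N);
  if (want_counts) counts.zeros(Q, K, J);
  vec acc_v(Q), p_v(Q);
  double* acc = acc_v.memptr();
  double* pv = p_v.memptr();
  const double* lw = logw.memptr();
  for (uword n = 0; n < N; ++n) {
    std::copy(lw, lw + Q, acc);
    for (uword j = 0; j < J; ++j) {
      const int y = Y(n, j);
      if (y == INT_MIN) continue;            // NA
      const double* lp = logP.slice_colptr(j, static_cast<uword>(y));
      for (uword q = 0; q < Q; ++q) acc[q] += lp[q];
    }
    double m = acc[0];
    for (uword q = 1; q < Q; ++q) m = std::max(m, acc[q]);
    double s = 0.0;
    for (uword q = 0; q < Q; ++q) { pv[q] = std::exp(acc[q] - m); s += pv[q]; }
    person_ll(n) = m + std::log(s);
    if (need_post) {
      double* pc = post.colptr(n);
      const double inv = 1.0 / s;
      for (uword q = 0; q < Q; ++q) pc[q] = pv[q] * inv;
      if (want_counts) {
        for (uword j = 0; j < J; ++j) {
          const int y = Y(n, j);
          if (y == INT_MIN) continue;
          double* ct = counts.slice_colptr(j, static_cast<uword>(y));
          for (uword q = 0; q < Q; ++q) ct[q] += pc[q];
        }
      }
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = accu(person_ll),
      Rcpp::Named("person_loglik") = person_ll);
  if (want_post) out["post"] = post;
  if (want_counts) out["counts"] = counts;
  return out;
}

// Design matrix over (node, category) pairs for an item loading on the
// given 0-based latent dimensions: slope columns, then K-1 intercept
// indicator columns. Shared by all items with the same loading pattern.
// [[Rcpp::export]]
arma::mat cpp_build_design(const arma::mat& Theta, const arma::mat& S,
                           const arma::uvec& loaded) {
  const uword Q = Theta.n_rows, K = S.n_cols, L = loaded.n_elem;
  mat X(Q * K, L + (K - 1), fill::zeros);
  for (uword l = 0; l < L; ++l) {
    const uword d = loaded(l);
    for (uword k = 0; k < K; ++k)
      X.col(l).subvec(k * Q, k * Q + Q - 1) = S(d, k) * Theta.col(d);
  }
  for (uword k = 1; k < K; ++k)
    X.col(L + k - 1).subvec(k * Q, k * Q + Q - 1).ones();
  return X;
}

static double item_ell(const vec& nvec, const mat& eta) {
  mat e = eta;
  vec m = max(e, 1);
  e.each_col() -= m;
  vec lse = log(sum(exp(e), 1));
  e.each_col() -= lse;
  return dot(nvec, vectorise(e));
}

// Newton update of one item's free parameters (slopes on the loaded
// dimensions, intercepts 2..K) maximizing the expected complete-data
// multinomial-logit log-likelihood, with step-halving and box constraints.
// X must come from cpp_build_design with the same `loaded`.
// [[Rcpp::export]]
Rcpp::List cpp_newton_item(const arma::mat& counts, const arma::mat& X,
                           const arma::uvec& loaded, const arma::uword K,
                           const arma::vec& a0, const arma::vec& c0,
                           const double slope_lb, const double slope_ub,
                           const double c_max, const int maxit) {
  const uword Q = counts.n_rows, L = loaded.n_elem;
  const uword p = L + (K - 1);
  vec Nq = sum(counts, 1);
  vec Nq_safe = Nq + 1e-100;                  // guard nodes with ~zero mass
  vec nvec = vectorise(counts);
  vec beta(p);
  for (uword l = 0; l < L; ++l) beta(l) = a0(loaded(l));
  for (uword k = 1; k < K; ++k) beta(L + k - 1) = c0(k);

  auto clamp = [&](vec b) {
    for (uword l = 0; l < L; ++l)
      b(l) = std::min(slope_ub, std::max(slope_lb, b(l)));
    for (uword m = L; m < p; ++m)
      b(m) = std::min(c_max, std::max(-c_max, b(m)));
    return b;
  };
  auto ell_at = [&](const vec& b) {
    return item_ell(nvec, reshape(X * b, Q, K));
  };

  double ell = ell_at(beta);
  bool at_bound = false;
  for (int it = 0; it < maxit; ++it) {
    mat eta = reshape(X * beta, Q, K);
    vec m = max(eta, 1);
    mat P = exp(eta.each_col() - m);
    P.each_col() /= sum(P, 1);
    vec d = vectorise(P.each_col() % Nq);
    vec g = X.t() * (nvec - d);
    mat H1 = X.t() * (X.each_col() % d);
    mat B(Q, p, fill::zeros);
    for (uword k = 0; k < K; ++k) {
      mat Xk = X.rows(k * Q, k * Q + Q - 1);
      B += Xk.each_col() % d.subvec(k * Q, k * Q + Q - 1);
    }
    mat H2 = B.t() * (B.each_col() / Nq_safe);
    mat H = H1 - H2;
    H.diag() += 1e-8;
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd + solve_opts::no_approx))
      step = g / (H.diag().max() + 1.0);
    double fac = 1.0;
    vec cand;
    double ell_new = ell;
    for (int h = 0; h < 20; ++h) {
      cand = clamp(beta + fac * step);
      ell_new = ell_at(cand);
      if (ell_new >= ell - 1e-10) break;
      fac *= 0.5;
    }
    if (ell_new < ell) break;                 // no ascent possible
    double delta = abs(cand - beta).max();
    beta = cand;
    ell = ell_new;
    if (delta < 1e-8) break;
  }
  vec a(a0.n_elem, fill::zeros);
  for (uword l = 0; l < L; ++l) {
    a(loaded(l)) = beta(l);
    if (beta(l) <= slope_lb + 1e-12 || beta(l) >= slope_ub - 1e-12)
      at_bound = true;
  }
  vec c(K, fill::zeros);
  for (uword k = 1; k < K; ++k) {
    c(k) = beta(L + k - 1);
    if (std::abs(c(k)) >= c_max - 1e-12) at_bound = true;
  }
  return Rcpp::List::create(Rcpp::Named("slopes") = a,
                            Rcpp::Named("intercepts") = c,
                            Rcpp::Named("ell") = ell,
                            Rcpp::Named("at_bound") = at_bound);
}
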