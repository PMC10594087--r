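// Graphical lasso by block coordinate descent (Friedman-style column sweeps)
// with an EBIC-scored lambda path.  The diagonal of the precision matrix is
// never penalized, so lambda >= max off-diagonal |S| gives an exactly
// diagonal solution (KKT).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// One glasso fit at penalty matrix Lam (off-diagonal entries used).
// W and Beta are warm-start state, updated in place; Beta.col(j) holds the
// lasso coefficients of column j's subproblem, with Beta(j, j) == 0.
// Returns true on convergence.
static bool glasso_core(const mat &S, const mat &Lam, mat &W, mat &Beta,
                        const double tol, const int max_sweeps,
                        double &last_change) {
  const uword p = S.n_rows;
  W.diag() = S.diag(); // diagonal unpenalized
  const double itol = tol * 0.1;
  vec b(p);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double maxd = 0.0;
    for (uword j = 0; j < p; ++j) {
      b = Beta.col(j);
      b(j) = 0.0;
      // coordinate-descent lasso on the column subproblem
      // min_b 0.5 b' W11 b - s12' b + sum |Lam_kj b_k|; b(j) stays 0, so
      // full-length dot products over W columns skip column j implicitly.
      for (int it = 0; it < 1000; ++it) {
        double mx = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          const double g = S(k, j) - dot(W.col(k), b) + W(k, k) * b(k);
          const double l = Lam(k, j);
          double bk = 0.0;
          if (g > l)
            bk = (g - l) / W(k, k);
          else if (g < -l)
            bk = (g + l) / W(k, k);
          const double d = std::abs(bk - b(k));
          if (d > mx) mx = d;
          b(k) = bk;
        }
        if (mx < itol) break;
      }
      // w12 = W11 * b; entries of row/column j are excluded via b(j) == 0
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        const double v = dot(W.col(k), b);
        const double d = std::abs(W(k, j) - v);
        if (d > maxd) maxd = d;
        W(k, j) = v;
        W(j, k) = v;
        Beta(k, j) = b(k);
      }
    }
    last_change = maxd;
    if (maxd < tol) return true;
  }
  return false;
}

// Recover Theta from (W, Beta); Beta(j, j) == 0.
static mat recover_theta(const mat &W, const mat &Beta) {
  const uword p = W.n_rows;
  mat Theta(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    const double theta_jj = 1.0 / (W(j, j) - dot(W.col(j), Beta.col(j)));
    Theta(j, j) = theta_jj;
    for (uword k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -Beta(k, j) * theta_jj;
  }
  return 0.5 * (Theta + Theta.t());
}

static mat theta_to_pcor(const mat &Theta, const double zero_tol) {
  const uword p = Theta.n_rows;
  mat P(p, p, fill::zeros);
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j) {
        double e = -Theta(i, j) / std::sqrt(Theta(i, i) * Theta(j, j));
        if (std::abs(e) < zero_tol) e = 0.0;
        P(i, j) = e;
      }
  return P;
}

// [[Rcpp::export(name = ".glasso_fit_cpp")]]
Rcpp::List glasso_fit_cpp(const arma::mat &S, const arma::mat &Lam,
                          const double tol, const int max_sweeps) {
  const uword p = S.n_rows;
  if (Lam.max() <= 1e-14) {
    // unpenalized maximum likelihood: Theta = S^-1
    mat Theta = inv_sympd(symmatu(S));
    Theta = 0.5 * (Theta + Theta.t());
    return Rcpp::List::create(
        Rcpp::Named("theta") = Theta,
        Rcpp::Named("pcor") = theta_to_pcor(Theta, 1e-10),
        Rcpp::Named("converged") = true, Rcpp::Named("last_change") = 0.0);
  }
  mat W = S, Beta(p, p, fill::zeros);
  double last_change = datum::inf;
  bool conv = glasso_core(S, Lam, W, Beta, tol, max_sweeps, last_change);
  mat Theta = recover_theta(W, Beta);
  return Rcpp::List::create(
      Rcpp::Named("theta") = Theta,
      Rcpp::Named("pcor") = theta_to_pcor(Theta, 1e-10),
      Rcpp::Named("converged") = conv,
      Rcpp::Named("last_change") = last_change);
}

// Lambda path with warm starts.  lam_weights is a matrix of per-entry
// multiplicative penalty weights (all ones for plain glasso; 1/|theta_ij|
// for the adaptive variant); effective penalty is lambda * lam_weights.
// [[Rcpp::export(name = ".glasso_path_cpp")]]
Rcpp::List glasso_path_cpp(const arma::mat &S, const double n,
                           const arma::vec &lambdas,
                           const arma::mat &lam_weights, const double gamma,
                           const double tol, const int max_sweeps) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  mat W = S, Beta(p, p, fill::zeros);
  cube thetas(p, p, L), pcors(p, p, L);
  vec loglik(L), ebic(L);
  ivec nedge(L);
  Rcpp::LogicalVector conv(L);
  double last_change = 0.0;

  for (uword l = 0; l < L; ++l) {
    mat Lam = lambdas(l) * lam_weights;
    mat Theta;
    if (lambdas(l) <= 1e-14 && lam_weights.max() < datum::inf) {
      Theta = inv_sympd(symmatu(S));
      Theta = 0.5 * (Theta + Theta.t());
      conv(l) = true;
    } else {
      conv(l) = glasso_core(S, Lam, W, Beta, tol, max_sweeps, last_change);
      Theta = recover_theta(W, Beta);
    }
    mat P = theta_to_pcor(Theta, 1e-10);
    int E = 0;
    for (uword i = 0; i < p; ++i)
      for (uword j = i + 1; j < p; ++j)
        if (P(i, j) != 0.0) ++E;
    double ld, sign;
    log_det(ld, sign, Theta);
    const double ll = 0.5 * n * (ld - trace(S * Theta));
    thetas.slice(l) = Theta;
    pcors.slice(l) = P;
    loglik(l) = ll;
    nedge(l) = E;
    ebic(l) = -2.0 * ll + E * std::log(n) + 4.0 * gamma * E * std::log((double)p);
  }
  return Rcpp::List::create(
      Rcpp::Named("lambdas") = lambdas, Rcpp::Named("thetas") = thetas,
      Rcpp::Named("pcors") = pcors, Rcpp::Named("loglik") = loglik,
      Rcpp::Named("nedge") = nedge, Rcpp::Named("ebic") = ebic,
      Rcpp::Named("converged") = conv);
}
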