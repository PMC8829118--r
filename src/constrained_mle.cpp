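#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Gaussian MLE of the precision matrix under a fixed zero pattern.
// Cyclic per-node regression on the working covariance W (initialized at S):
// for node j with skeleton neighbors nb, solve W[nb,nb] b = S[nb,j] and set
// the off-diagonal column j of W to W[,nb] b. At a fixed point W agrees with
// S on skeleton edges and the diagonal, and the implied precision has exact
// zeros off the skeleton (the stationarity condition of the constrained MLE).
// [[Rcpp::export(name = ".cmle_cpp")]]
List cmle_cpp(const arma::mat& S, const arma::imat& A, double tol,
              int max_iter) {
  const arma::uword p = S.n_rows;
  arma::mat W = S;
  std::vector<arma::uvec> nbs(p);
  for (arma::uword j = 0; j < p; ++j) {
    nbs[j] = arma::find(A.col(j) != 0);
  }
  double jitter = 1e-8 * arma::trace(S) / p;
  bool jittered = false;
  int it = 0;
  double delta = R_PosInf;
  for (it = 1; it <= max_iter; ++it) {
    delta = 0.0;
    for (arma::uword j = 0; j < p; ++j) {
      const arma::uvec& nb = nbs[j];
      arma::vec w_new(p, arma::fill::zeros);
      if (nb.n_elem > 0) {
        arma::mat W11 = W.submat(nb, nb);
        arma::vec s12 = S.col(j);
        s12 = s12.elem(nb);
        arma::vec beta;
        bool ok = arma::solve(beta, W11, s12,
                              arma::solve_opts::no_approx);
        if (!ok || !beta.is_finite()) {
          W11.diag() += jitter;
          jittered = true;
          if (!arma::solve(beta, W11, s12) || !beta.is_finite()) {
            continue;  // leave column untouched this sweep
          }
        }
        w_new = W.cols(nb) * beta;
      }
      w_new(j) = W(j, j);
      double d = arma::abs(w_new - W.col(j)).max();
      if (d > delta) delta = d;
      W.col(j) = w_new;
      W.row(j) = w_new.t();
    }
    if (delta <= tol) break;
  }
  bool converged = (delta <= tol);
  int n_iter = std::min(it, max_iter);

  // recover the precision matrix column by column
  arma::mat Omega(p, p, arma::fill::zeros);
  for (arma::uword j = 0; j < p; ++j) {
    const arma::uvec& nb = nbs[j];
    if (nb.n_elem == 0) {
      Omega(j, j) = 1.0 / W(j, j);
      continue;
    }
    arma::mat W11 = W.submat(nb, nb);
    arma::vec s12 = S.col(j);
    s12 = s12.elem(nb);
    arma::vec beta;
    if (!arma::solve(beta, W11, s12, arma::solve_opts::no_approx)) {
      W11.diag() += jitter;
      jittered = true;
      arma::solve(beta, W11, s12);
    }
    double t22 = W(j, j) - arma::dot(s12, beta);
    if (t22 <= 0) t22 = 1e-12;
    double th22 = 1.0 / t22;
    Omega(j, j) = th22;
    arma::vec th12 = -beta * th22;
    for (arma::uword k = 0; k < nb.n_elem; ++k) {
      Omega(nb(k), j) = th12(k);
    }
  }
  Omega = 0.5 * (Omega + Omega.t());

  return List::create(_["Omega"] = Omega, _["Sigma"] = W,
                      _["converged"] = converged, _["n_iter"] = n_iter,
                      _["delta"] = delta, _["jittered"] = jittered);
}
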