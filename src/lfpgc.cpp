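// Numerical kernels: VAR simulation and the multivariate Levinson-Durbin
// (Whittle) recursion. Both are tight loops over small matrices, so they
// live in C++; all random numbers are drawn in R and passed in, keeping
// reproducibility under R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Simulate X_t = sum_j A_j X_{t-j} + e_t. `noise` is (burnin + T) x n,
// already drawn (and correlated) in R. Returns the last T rows.
// [[Rcpp::export(name = ".var_simulate_cpp")]]
arma::mat var_simulate_cpp(const arma::cube& A, const arma::mat& noise,
                           int burnin) {
  const int n = A.n_rows;
  const int p = A.n_slices;
  const int total = noise.n_rows;
  arma::mat X(total, n, arma::fill::zeros);
  for (int t = 0; t < total; ++t) {
    arma::rowvec acc = noise.row(t);
    for (int j = 0; j < p; ++j) {
      int tl = t - j - 1;
      if (tl >= 0) acc += X.row(tl) * A.slice(j).t();
    }
    X.row(t) = acc;
  }
  return X.rows(burnin, total - 1);
}

// Whittle recursion: solve the multivariate Yule-Walker system for the best
// linear predictor of order p given autocovariances Gamma_0..Gamma_p
// (G slice k holds Gamma_k = E[X_t X_{t-k}']). Returns forward coefficients
// A_1..A_p and the innovation covariance V.
// [[Rcpp::export(name = ".whittle_cpp")]]
List whittle_cpp(const arma::cube& G, int p) {
  const int n = G.n_rows;
  arma::mat G0 = G.slice(0);
  // order-1 initialization
  arma::cube Af(n, n, p, arma::fill::zeros);
  arma::cube Ab(n, n, p, arma::fill::zeros);
  arma::mat G1 = G.slice(1);
  Af.slice(0) = arma::solve(G0.t(), G1.t()).t();      // G1 * G0^-1
  Ab.slice(0) = arma::solve(G0.t(), G1).t();          // G1' * G0^-1
  arma::mat V  = G0 - Af.slice(0) * G1.t();
  arma::mat Vb = G0 - Ab.slice(0) * G1;
  for (int k = 1; k < p; ++k) {
    arma::mat D = G.slice(k + 1);
    for (int j = 0; j < k; ++j) D -= Af.slice(j) * G.slice(k - j);
    arma::mat Akk = arma::solve(Vb.t(), D.t()).t();   // D * Vb^-1
    arma::mat Bkk = arma::solve(V.t(), D).t();        // D' * V^-1
    arma::cube Afold = Af, Abold = Ab;
    Af.slice(k) = Akk;
    Ab.slice(k) = Bkk;
    for (int j = 0; j < k; ++j) {
      Af.slice(j) = Afold.slice(j) - Akk * Abold.slice(k - 1 - j);
      Ab.slice(j) = Abold.slice(j) - Bkk * Afold.slice(k - 1 - j);
    }
    V  = V  - Akk * D.t();
    Vb = Vb - Bkk * D;
  }
  V = 0.5 * (V + V.t());
  return List::create(Named("A") = Af, Named("V") = V);
}
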