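// Natural-gradient Infomax ICA inner loop with sub/super-Gaussian switching.
//
// Update rule per block (natural gradient):
//   W <- W + lr * [ I - E( K tanh(u) u' + u u' ) ] W
// with K = diag(k_i), k_i = sign of the kurtosis of source i, re-estimated
// on the full current sources each sweep. Randomness (sample shuffling)
// comes from R's RNG via Rcpp::sample so seeds set in R are honoured.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::export]]
List infomax_core(const arma::mat& X, arma::mat W, double lr, int max_iter,
                  double tol, int block, double anneal_deg,
                  double anneal_factor) {
  const arma::uword N = X.n_rows, T = X.n_cols;
  const arma::mat I = arma::eye<arma::mat>(N, N);
  arma::vec ksign(N, arma::fill::ones);
  arma::mat delta_prev;
  bool converged = false, blowup = false;
  int iter = 0;
  const double deg = 180.0 / M_PI;

  for (iter = 1; iter <= max_iter; ++iter) {
    // kurtosis signs on the full current sources
    arma::mat U = W * X;
    for (arma::uword i = 0; i < N; ++i) {
      arma::rowvec u = U.row(i);
      double m2 = arma::mean(arma::square(u));
      double m4 = arma::mean(arma::square(arma::square(u)));
      double k = m4 / (m2 * m2) - 3.0;
      ksign(i) = (k >= 0.0) ? 1.0 : -1.0;
    }

    // shuffled block sweep
    IntegerVector perm = sample(static_cast<int>(T), static_cast<int>(T),
                                false);
    arma::uvec ord(T);
    for (arma::uword t = 0; t < T; ++t)
      ord(t) = static_cast<arma::uword>(perm[t] - 1);

    arma::mat W_old = W;
    for (arma::uword t0 = 0; t0 < T; t0 += block) {
      arma::uword t1 = std::min<arma::uword>(t0 + block, T) - 1;
      arma::uvec idx = ord.subvec(t0, t1);
      arma::mat Xb = X.cols(idx);
      arma::mat Ub = W * Xb;
      arma::mat Yb = arma::tanh(Ub);
      Yb.each_col() %= ksign;
      double nb = static_cast<double>(Xb.n_cols);
      arma::mat grad = I - (Yb * Ub.t() + Ub * Ub.t()) / nb;
      W += lr * grad * W;
      if (!W.is_finite()) { blowup = true; break; }
    }
    if (blowup || arma::abs(W).max() > 1e8) { blowup = true; break; }

    arma::mat delta = W - W_old;
    double change = arma::abs(delta).max();
    if (!delta_prev.is_empty()) {
      double num = arma::accu(delta % delta_prev);
      double den = arma::norm(arma::vectorise(delta), 2) *
                   arma::norm(arma::vectorise(delta_prev), 2);
      if (den > 0) {
        double ang = std::acos(std::min(1.0, std::max(-1.0, num / den))) * deg;
        if (ang > anneal_deg) lr *= anneal_factor;
      }
    }
    delta_prev = delta;
    if (change < tol) { converged = true; break; }
  }

  return List::create(_["W"] = W,
                      _["n_iter"] = std::min(iter, max_iter),
                      _["converged"] = converged,
                      _["blowup"] = blowup,
                      _["lr_final"] = lr);
}
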