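#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Gradient-descent iterations of exact t-SNE with early exaggeration,
// momentum and per-coordinate adaptive gains. P is the symmetrized joint
// probability matrix; Y the initial embedding. Deterministic.
// [[Rcpp::export]]
arma::mat tsne_iterate_cpp(const arma::mat& P, arma::mat Y, int iters,
                           double eta, double exaggeration, int stop_exag,
                           int momentum_switch) {
  const uword n = Y.n_rows;
  const uword d = Y.n_cols;
  mat G(n, d, fill::zeros);
  mat gains(n, d, fill::ones);

  for (int it = 1; it <= iters; ++it) {
    colvec ss = sum(square(Y), 1);
    mat num = -2.0 * (Y * Y.t());
    num.each_col() += ss;
    num.each_row() += ss.t();
    num.transform([](double v) { return 1.0 / (1.0 + (v > 0.0 ? v : 0.0)); });
    num.diag().zeros();
    const double qsum = accu(num);
    const double pmul = (it <= stop_exag) ? exaggeration : 1.0;
    mat W = (pmul * P - num / qsum) % num;
    colvec wr = sum(W, 1);
    mat grad = 4.0 * (Y.each_col() % wr - W * Y);
    const double momentum = (it < momentum_switch) ? 0.5 : 0.8;
    for (uword j = 0; j < n * d; ++j) {
      const double sg = (grad(j) > 0.0) - (grad(j) < 0.0);
      const double sv = (G(j) > 0.0) - (G(j) < 0.0);
      gains(j) = (sg != sv) ? gains(j) + 0.2 : gains(j) * 0.8;
      if (gains(j) < 0.01) gains(j) = 0.01;
      G(j) = momentum * G(j) - eta * gains(j) * grad(j);
      Y(j) += G(j);
    }
    rowvec cm = mean(Y, 0);
    Y.each_row() -= cm;
  }
  return Y;
}
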