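// Feed-forward probabilistic classifier: one logistic hidden layer and a
// sigmoid output unit with an additive output bias term ("biased sigmoid",
// zero by default). Training is full-sweep SGD with per-sample updates; the
// visiting order per epoch is supplied by the caller so all randomness
// stays in R's RNG.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double sigmoid(double z) {
  return 1.0 / (1.0 + std::exp(-z));
}

// loss_code: 0 = binary cross-entropy, 1 = squared error (0.5 (p - y)^2)
static inline double loss_value(double p, double y, int loss_code) {
  if (loss_code == 0) {
    const double eps = 1e-12;
    double pc = std::min(std::max(p, eps), 1.0 - eps);
    return -(y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
  }
  return 0.5 * (p - y) * (p - y);
}

static inline double dloss_dz(double p, double y, int loss_code) {
  if (loss_code == 0) return p - y;          // sigmoid + BCE
  return (p - y) * p * (1.0 - p);            // sigmoid + squared error
}

// [[Rcpp::export]]
arma::vec cpp_mlp_forward(const arma::mat& W1, const arma::vec& b1,
                          const arma::vec& w2, double b2, double out_bias,
                          const arma::mat& X) {
  // X: d x n (one column per sample)
  mat H = W1 * X;
  H.each_col() += b1;
  H = 1.0 / (1.0 + exp(-H));
  rowvec z = w2.t() * H;
  vec p(X.n_cols);
  for (uword i = 0; i < X.n_cols; ++i) {
    p(i) = sigmoid(z(i) + b2 + out_bias);
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_gradient(const arma::mat& W1, const arma::vec& b1,
                            const arma::vec& w2, double b2, double out_bias,
                            const arma::vec& x, double y, int loss_code) {
  vec a1 = W1 * x + b1;
  vec h = 1.0 / (1.0 + exp(-a1));
  double p = sigmoid(dot(w2, h) + b2 + out_bias);
  double dz2 = dloss_dz(p, y, loss_code);
  vec gw2 = dz2 * h;
  double gb2 = dz2;
  vec dz1 = (dz2 * w2) % h % (1.0 - h);
  mat gW1 = dz1 * x.t();
  return Rcpp::List::create(
      Rcpp::Named("gW1") = gW1, Rcpp::Named("gb1") = dz1,
      Rcpp::Named("gw2") = gw2, Rcpp::Named("gb2") = gb2,
      Rcpp::Named("loss") = loss_value(p, y, loss_code),
      Rcpp::Named("p") = p);
}

// [[Rcpp::export]]
Rcpp::List cpp_mlp_sgd(arma::mat W1, arma::vec b1, arma::vec w2, double b2,
                       double out_bias, const arma::mat& X,
                       const arma::vec& y, const arma::imat& order,
                       double lr, int loss_code) {
  // X: d x n; order: epochs x n, 0-based sample indices
  const uword n_epochs = order.n_rows;
  const uword n = X.n_cols;
  vec trace(n_epochs, fill::zeros);
  for (uword e = 0; e < n_epochs; ++e) {
    double acc = 0.0;
    for (uword k = 0; k < n; ++k) {
      uword i = static_cast<uword>(order(e, k));
      vec x = X.col(i);
      vec a1 = W1 * x + b1;
      vec h = 1.0 / (1.0 + exp(-a1));
      double p = sigmoid(dot(w2, h) + b2 + out_bias);
      double yi = y(i);
      acc += loss_value(p, yi, loss_code);
      double dz2 = dloss_dz(p, yi, loss_code);
      vec dz1 = (dz2 * w2) % h % (1.0 - h);
      // rank-1 update of the hidden weights, then the output layer
      W1 -= lr * dz1 * x.t();
      b1 -= lr * dz1;
      w2 -= lr * dz2 * h;
      b2 -= lr * dz2;
    }
    trace(e) = acc / static_cast<double>(n);
    if (!std::isfinite(trace(e))) {
      Rcpp::stop("Training diverged: non-finite loss at epoch %d.",
                 static_cast<int>(e + 1));
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
      Rcpp::Named("w2") = w2, Rcpp::Named("b2") = b2,
      Rcpp::Named("loss_trace") = trace);
}
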