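// Per-instance SGD with momentum for the one-hidden-layer perceptron.
// Inputs are one-hot hexapeptide encodings given as 6 active column
// indices per instance (0-based), so the input layer never materializes.
// Uses R's RNG for the per-epoch shuffle; seeding happens in R.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// forward pass for one instance; fills h (hidden activations), returns output
static double forward_one(const int* act, int nact,
                          const NumericMatrix& W1, const NumericVector& b1,
                          const NumericVector& W2, double b2,
                          std::vector<double>& h) {
  const int H = W1.ncol();
  double o_in = b2;
  for (int j = 0; j < H; ++j) {
    double s = b1[j];
    for (int a = 0; a < nact; ++a) s += W1(act[a], j);
    h[j] = sigmoid(s);
    o_in += W2[j] * h[j];
  }
  return sigmoid(o_in);
}

// [[Rcpp::export]]
List mlp_train_cpp(IntegerMatrix idx, NumericVector y,
                   NumericMatrix W1, NumericVector b1,
                   NumericVector W2, NumericVector b2,
                   double lr, double momentum, int epochs) {
  const int n = idx.nrow(), P = idx.ncol(), H = W1.ncol(), D = W1.nrow();
  if (P > 16) stop("at most 16 active inputs per instance are supported");
  NumericMatrix W1c(clone(W1));
  NumericVector b1c(clone(b1)), W2c(clone(W2));
  double b2c = b2[0];

  // momentum velocities (vW1 stored column-major to match W1)
  std::vector<double> vW1((size_t)D * H, 0.0), vb1(H, 0.0), vW2(H, 0.0);
  double vb2 = 0.0;
  std::vector<double> h(H);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector lossTrace(epochs);
  int actbuf[16];

  RNGScope scope;
  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double sse = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = order[t];
      for (int p = 0; p < P; ++p) actbuf[p] = idx(i, p);
      double o = forward_one(actbuf, P, W1c, b1c, W2c, b2c, h);
      double err = y[i] - o;
      sse += err * err;
      double delta_o = err * o * (1.0 - o);   // descent direction at output
      for (int j = 0; j < H; ++j) {
        double dhj = delta_o * W2c[j] * h[j] * (1.0 - h[j]);
        double* vcol = &vW1[(size_t)j * D];
        // momentum keeps moving weights whose instantaneous gradient is zero
        for (int d = 0; d < D; ++d) vcol[d] *= momentum;
        for (int p = 0; p < P; ++p) vcol[actbuf[p]] += lr * dhj;
        for (int d = 0; d < D; ++d) W1c(d, j) += vcol[d];
        vb1[j] = momentum * vb1[j] + lr * dhj;
        b1c[j] += vb1[j];
        vW2[j] = momentum * vW2[j] + lr * delta_o * h[j];
        W2c[j] += vW2[j];
      }
      vb2 = momentum * vb2 + lr * delta_o;
      b2c += vb2;
    }
    lossTrace[e] = sse / n;
    if (e % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["W1"] = W1c, _["b1"] = b1c, _["W2"] = W2c,
                      _["b2"] = NumericVector::create(b2c),
                      _["lossTrace"] = lossTrace);
}

// Analytic gradient of the per-instance squared-error loss (E = err^2 / 2),
// exposed so the training step can be cross-checked against finite
// differences.
// [[Rcpp::export]]
List mlp_instance_grad_cpp(IntegerVector act0, double y,
                           NumericMatrix W1, NumericVector b1,
                           NumericVector W2, double b2) {
  const int H = W1.ncol(), D = W1.nrow(), P = act0.size();
  if (P > 16) stop("at most 16 active inputs are supported");
  std::vector<double> h(H);
  int actbuf[16];
  for (int p = 0; p < P; ++p) actbuf[p] = act0[p];
  double o = forward_one(actbuf, P, W1, b1, W2, b2, h);
  double err = y - o;
  double delta_o = -err * o * (1.0 - o);    // dE/do_in
  NumericMatrix dW1(D, H);
  NumericVector db1(H), dW2(H);
  for (int j = 0; j < H; ++j) {
    double dhj = delta_o * W2[j] * h[j] * (1.0 - h[j]);
    db1[j] = dhj;
    dW2[j] = delta_o * h[j];
    for (int p = 0; p < P; ++p) dW1(actbuf[p], j) = dhj;
  }
  return List::create(_["loss"] = 0.5 * err * err, _["dW1"] = dW1,
                      _["db1"] = db1, _["dW2"] = dW2, _["db2"] = delta_o,
                      _["output"] = o);
}

// [[Rcpp::export]]
double mlp_instance_loss_cpp(IntegerVector act0, double y,
                             NumericMatrix W1, NumericVector b1,
                             NumericVector W2, double b2) {
  const int H = W1.ncol(), P = act0.size();
  if (P > 16) stop("at most 16 active inputs are supported");
  std::vector<double> h(H);
  int actbuf[16];
  for (int p = 0; p < P; ++p) actbuf[p] = act0[p];
  double o = forward_one(actbuf, P, W1, b1, W2, b2, h);
  double err = y - o;
  return 0.5 * err * err;
}
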