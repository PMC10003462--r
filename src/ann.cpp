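// Small feed-forward network for SNP-subset fitness evaluation.
// Two ReLU hidden layers of equal width, sigmoid output, binary
// cross-entropy loss, Adam with hyperbolic learning-rate decay
// lr_t = lr0 / (1 + decay * t).  All randomness (weight init, batch
// shuffling) comes from a private mt19937 seeded per call, so results
// are bit-reproducible for a fixed seed on a fixed build.

#include <RcppArmadillo.h>
#include <random>

// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;

namespace {

struct Params {
  mat W1, W2, W3;      // W3 is width x 1
  vec b1, b2, b3;      // b3 length 1
};

struct Adam {
  mat mW1, vW1, mW2, vW2, mW3, vW3;
  vec mb1, vb1, mb2, vb2, mb3, vb3;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  explicit Adam(const Params& p) {
    mW1.zeros(arma::size(p.W1)); vW1.zeros(arma::size(p.W1));
    mW2.zeros(arma::size(p.W2)); vW2.zeros(arma::size(p.W2));
    mW3.zeros(arma::size(p.W3)); vW3.zeros(arma::size(p.W3));
    mb1.zeros(p.b1.n_elem); vb1.zeros(p.b1.n_elem);
    mb2.zeros(p.b2.n_elem); vb2.zeros(p.b2.n_elem);
    mb3.zeros(p.b3.n_elem); vb3.zeros(p.b3.n_elem);
  }

  template <typename T>
  void upd(T& theta, T& m, T& v, const T& g, double lr) {
    m = beta1 * m + (1.0 - beta1) * g;
    v = beta2 * v + (1.0 - beta2) * (g % g);
    const double bc1 = 1.0 - std::pow(beta1, (double)t);
    const double bc2 = 1.0 - std::pow(beta2, (double)t);
    theta -= lr * (m / bc1) / (arma::sqrt(v / bc2) + eps);
  }
};

// Glorot-uniform init, Keras-style default for dense layers.
mat glorot(std::mt19937& rng, arma::uword n_in, arma::uword n_out) {
  const double lim = std::sqrt(6.0 / (double)(n_in + n_out));
  std::uniform_real_distribution<double> u(-lim, lim);
  mat W(n_in, n_out);
  for (arma::uword j = 0; j < n_out; ++j)
    for (arma::uword i = 0; i < n_in; ++i) W(i, j) = u(rng);
  return W;
}

mat relu(const mat& z) { return arma::clamp(z, 0.0, arma::datum::inf); }

vec sigmoid(const vec& z) { return 1.0 / (1.0 + arma::exp(-z)); }

vec forward(const Params& p, const mat& X) {
  mat a1 = relu((X * p.W1).eval().each_row() + p.b1.t());
  mat a2 = relu((a1 * p.W2).eval().each_row() + p.b2.t());
  vec z = a2 * p.W3 + p.b3(0);
  return sigmoid(z);
}

double bce(const vec& prob, const vec& y) {
  const double eps = 1e-12;
  vec p = arma::clamp(prob, eps, 1.0 - eps);
  return arma::mean(-(y % arma::log(p) + (1.0 - y) % arma::log(1.0 - p)));
}

} // namespace

// [[Rcpp::export(name = ".ann_train_cpp")]]
Rcpp::List ann_train_cpp(const arma::mat& X, const arma::vec& y,
                         const arma::mat& Xval, const arma::vec& yval,
                         int hidden, int epochs, int batch_size,
                         double lr0, double decay, int seed) {
  const arma::uword n = X.n_rows, d = X.n_cols, h = (arma::uword)hidden;
  std::mt19937 rng((unsigned)seed);

  Params p;
  p.W1 = glorot(rng, d, h); p.b1.zeros(h);
  p.W2 = glorot(rng, h, h); p.b2.zeros(h);
  p.W3 = glorot(rng, h, 1); p.b3.zeros(1);
  Adam opt(p);

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  vec train_loss(epochs), val_loss(epochs), train_acc(epochs);
  Params best = p;
  double best_val = arma::datum::inf, best_tracc = -1.0;
  int best_epoch = -1;
  bool diverged = false;
  double bad_lr = NA_REAL; int bad_epoch = NA_INTEGER;

  for (int e = 0; e < epochs && !diverged; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (arma::uword start = 0; start < n; start += (arma::uword)batch_size) {
      const arma::uword stop = std::min(n, start + (arma::uword)batch_size);
      uvec b(stop - start);
      for (arma::uword k = start; k < stop; ++k) b(k - start) = idx[k];
      const mat Xb = X.rows(b);
      const vec yb = y.elem(b);
      const double m = (double)Xb.n_rows;

      // forward pass, keeping activations
      mat z1 = (Xb * p.W1).eval().each_row() + p.b1.t();
      mat a1 = relu(z1);
      mat z2 = (a1 * p.W2).eval().each_row() + p.b2.t();
      mat a2 = relu(z2);
      vec z3 = a2 * p.W3 + p.b3(0);
      vec prob = sigmoid(z3);

      // backward: dL/dz3 = (prob - y)/m for mean BCE + sigmoid
      vec d3 = (prob - yb) / m;
      mat gW3 = a2.t() * d3;
      vec gb3(1); gb3(0) = arma::accu(d3);
      mat d2 = (d3 * p.W3.t()) % arma::conv_to<mat>::from(z2 > 0.0);
      mat gW2 = a1.t() * d2;
      vec gb2 = arma::sum(d2, 0).t();
      mat d1 = (d2 * p.W2.t()) % arma::conv_to<mat>::from(z1 > 0.0);
      mat gW1 = Xb.t() * d1;
      vec gb1 = arma::sum(d1, 0).t();

      opt.t += 1;
      const double lr = lr0 / (1.0 + decay * (double)opt.t);
      opt.upd(p.W1, opt.mW1, opt.vW1, gW1, lr);
      opt.upd(p.b1, opt.mb1, opt.vb1, gb1, lr);
      opt.upd(p.W2, opt.mW2, opt.vW2, gW2, lr);
      opt.upd(p.b2, opt.mb2, opt.vb2, gb2, lr);
      opt.upd(p.W3, opt.mW3, opt.vW3, gW3, lr);
      opt.upd(p.b3, opt.mb3, opt.vb3, gb3, lr);

      if (!p.W1.is_finite() || !p.W2.is_finite() || !p.W3.is_finite()) {
        diverged = true; bad_lr = lr; bad_epoch = e + 1;
        break;
      }
    }
    if (diverged) break;

    vec pt = forward(p, X);
    vec pv = forward(p, Xval);
    const double tl = bce(pt, y);
    const double vl = bce(pv, yval);
    const double ta = arma::mean(arma::conv_to<vec>::from((pt >= 0.5)) == y);
    train_loss(e) = tl; val_loss(e) = vl; train_acc(e) = ta;
    if (!std::isfinite(tl) || !std::isfinite(vl)) {
      diverged = true; bad_lr = lr0 / (1.0 + decay * (double)opt.t);
      bad_epoch = e + 1;
      break;
    }

    // checkpoint rule: min val loss; ties -> higher train accuracy,
    // then the earlier epoch
    if (vl < best_val || (vl == best_val && ta > best_tracc)) {
      best_val = vl; best_tracc = ta; best_epoch = e + 1; best = p;
    }
  }

  if (diverged || best_epoch < 0) {
    return Rcpp::List::create(
      Rcpp::Named("diverged") = true,
      Rcpp::Named("lr_at_failure") = bad_lr,
      Rcpp::Named("epoch_at_failure") = bad_epoch);
  }

  return Rcpp::List::create(
    Rcpp::Named("diverged") = false,
    Rcpp::Named("W1") = best.W1, Rcpp::Named("b1") = best.b1,
    Rcpp::Named("W2") = best.W2, Rcpp::Named("b2") = best.b2,
    Rcpp::Named("W3") = best.W3, Rcpp::Named("b3") = best.b3,
    Rcpp::Named("train_loss") = train_loss,
    Rcpp::Named("val_loss") = val_loss,
    Rcpp::Named("train_acc") = train_acc,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val,
    Rcpp::Named("best_train_loss") = train_loss(best_epoch - 1),
    Rcpp::Named("best_train_acc") = best_tracc);
}

// [[Rcpp::export(name = ".ann_forward_cpp")]]
arma::vec ann_forward_cpp(const arma::mat& X,
                          const arma::mat& W1, const arma::vec& b1,
                          const arma::mat& W2, const arma::vec& b2,
                          const arma::mat& W3, const arma::vec& b3) {
  Params p{W1, W2, W3, b1, b2, b3};
  return forward(p, X);
}
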