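// Small multilayer perceptron (input -> h1 ReLU -> dropout -> h2 ReLU ->
// dropout -> 1 sigmoid) trained with Adam on weighted binary cross-entropy.
// Uses R's RNG (unif_rand/norm_rand) so every run is reproducible from a
// set.seed() in the calling R code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat he_init(int n_in, int n_out) {
  arma::mat W(n_in, n_out);
  double s = std::sqrt(2.0 / n_in);
  for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = norm_rand() * s;
  return W;
}

struct AdamState {
  arma::mat m, v;
  AdamState(int r, int c) : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat& W, const arma::mat& g, double lr, double t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * (g % g);
    arma::mat mh = m / (1 - std::pow(b1, t));
    arma::mat vh = v / (1 - std::pow(b2, t));
    W -= lr * mh / (arma::sqrt(vh) + eps);
  }
};

static arma::vec forward_probs(const arma::mat& X, const arma::mat& W1,
                               const arma::rowvec& b1, const arma::mat& W2,
                               const arma::rowvec& b2, const arma::mat& W3,
                               const arma::rowvec& b3) {
  arma::mat H1 = X * W1;
  H1.each_row() += b1;
  H1.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::mat H2 = H1 * W2;
  H2.each_row() += b2;
  H2.transform([](double v) { return v > 0 ? v : 0.0; });
  arma::vec z = H2 * W3 + b3(0);
  return 1.0 / (1.0 + arma::exp(-z));
}

// [[Rcpp::export]]
List mlp_fit(const arma::mat& X, const arma::ivec& y, double lr, int batch,
             double dropout, int epochs, int patience, double pos_weight,
             double noise_sd, int noise_col, double val_frac,
             int h1 = 32, int h2 = 16) {
  const int n = X.n_rows, p = X.n_cols;

  // held-out validation rows for early stopping (random, via R's RNG)
  arma::uvec perm(n);
  for (int i = 0; i < n; ++i) perm(i) = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    std::swap(perm(i), perm(j));
  }
  int n_val = std::max(1, (int)std::floor(val_frac * n));
  if (n_val >= n) n_val = n - 1;
  arma::uvec val_idx = perm.head(n_val);
  arma::uvec tr_idx = perm.tail(n - n_val);
  arma::mat Xtr = X.rows(tr_idx), Xval = X.rows(val_idx);
  arma::vec ytr(tr_idx.n_elem), yval(val_idx.n_elem);
  for (arma::uword i = 0; i < tr_idx.n_elem; ++i) ytr(i) = y(tr_idx(i));
  for (arma::uword i = 0; i < val_idx.n_elem; ++i) yval(i) = y(val_idx(i));
  const int n_tr = Xtr.n_rows;

  arma::mat W1 = he_init(p, h1), W2 = he_init(h1, h2), W3 = he_init(h2, 1);
  arma::rowvec b1(h1, arma::fill::zeros), b2(h2, arma::fill::zeros),
      b3(1, arma::fill::zeros);
  AdamState aW1(p, h1), aW2(h1, h2), aW3(h2, 1);
  AdamState ab1(1, h1), ab2(1, h2), ab3(1, 1);

  arma::mat bW1 = W1, bW2 = W2, bW3 = W3;
  arma::rowvec bb1 = b1, bb2 = b2, bb3 = b3;
  double best_val = arma::datum::inf;
  int since_best = 0, epochs_run = 0;
  double t_adam = 0;
  std::vector<double> train_loss, val_loss;

  auto wbce = [&](const arma::vec& prob, const arma::vec& yy) {
    double L = 0;
    for (arma::uword i = 0; i < yy.n_elem; ++i) {
      double pr = std::min(std::max(prob(i), 1e-12), 1.0 - 1e-12);
      double w = yy(i) > 0.5 ? pos_weight : 1.0;
      L += -w * (yy(i) * std::log(pr) + (1 - yy(i)) * std::log(1 - pr));
    }
    return L / yy.n_elem;
  };

  arma::uvec order(n_tr);
  for (int i = 0; i < n_tr; ++i) order(i) = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // shuffle
    for (int i = n_tr - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(order(i), order(j));
    }
    for (int start = 0; start < n_tr; start += batch) {
      int end = std::min(start + batch, n_tr);
      int m = end - start;
      arma::uvec idx = order.subvec(start, end - 1);
      arma::mat Xb = Xtr.rows(idx);
      arma::vec yb(m);
      for (int i = 0; i < m; ++i) yb(i) = ytr(idx(i));
      if (noise_sd > 0 && noise_col >= 0 && noise_col < p) {
        for (int i = 0; i < m; ++i) Xb(i, noise_col) += norm_rand() * noise_sd;
      }
      // forward with inverted dropout
      arma::mat Z1 = Xb * W1;
      Z1.each_row() += b1;
      arma::mat A1 = Z1;
      A1.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat M1(m, h1);
      for (arma::uword i = 0; i < M1.n_elem; ++i) {
        M1(i) = unif_rand() < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      }
      arma::mat D1 = A1 % M1;
      arma::mat Z2 = D1 * W2;
      Z2.each_row() += b2;
      arma::mat A2 = Z2;
      A2.transform([](double v) { return v > 0 ? v : 0.0; });
      arma::mat M2(m, h2);
      for (arma::uword i = 0; i < M2.n_elem; ++i) {
        M2(i) = unif_rand() < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      }
      arma::mat D2 = A2 % M2;
      arma::vec z3 = D2 * W3 + b3(0);
      arma::vec prob = 1.0 / (1.0 + arma::exp(-z3));

      // gradient of weighted BCE wrt z3: w * (prob - y) / m
      arma::vec w(m);
      for (int i = 0; i < m; ++i) w(i) = yb(i) > 0.5 ? pos_weight : 1.0;
      arma::vec dz3 = (w % (prob - yb)) / m;
      arma::mat gW3 = D2.t() * dz3;
      double gb3 = arma::accu(dz3);
      arma::mat dD2 = dz3 * W3.t();
      arma::mat dZ2 = dD2 % M2;
      for (arma::uword i = 0; i < dZ2.n_elem; ++i) if (Z2(i) <= 0) dZ2(i) = 0;
      arma::mat gW2 = D1.t() * dZ2;
      arma::rowvec gb2 = arma::sum(dZ2, 0);
      arma::mat dD1 = dZ2 * W2.t();
      arma::mat dZ1 = dD1 % M1;
      for (arma::uword i = 0; i < dZ1.n_elem; ++i) if (Z1(i) <= 0) dZ1(i) = 0;
      arma::mat gW1 = Xb.t() * dZ1;
      arma::rowvec gb1 = arma::sum(dZ1, 0);

      t_adam += 1;
      aW1.step(W1, gW1, lr, t_adam);
      aW2.step(W2, gW2, lr, t_adam);
      aW3.step(W3, gW3, lr, t_adam);
      arma::mat gb1m = gb1, gb2m = gb2, gb3m(1, 1);
      gb3m(0, 0) = gb3;
      arma::mat b1m = b1, b2m = b2, b3m(1, 1);
      b3m(0, 0) = b3(0);
      ab1.step(b1m, gb1m, lr, t_adam);
      ab2.step(b2m, gb2m, lr, t_adam);
      ab3.step(b3m, gb3m, lr, t_adam);
      b1 = b1m.row(0);
      b2 = b2m.row(0);
      b3(0) = b3m(0, 0);
    }
    epochs_run = ep + 1;
    train_loss.push_back(wbce(forward_probs(Xtr, W1, b1, W2, b2, W3, b3), ytr));
    double vl = wbce(forward_probs(Xval, W1, b1, W2, b2, W3, b3), yval);
    val_loss.push_back(vl);
    if (vl < best_val - 1e-6) {
      best_val = vl;
      bW1 = W1; bW2 = W2; bW3 = W3; bb1 = b1; bb2 = b2; bb3 = b3;
      since_best = 0;
    } else if (++since_best >= patience) {
      break;
    }
  }

  return List::create(
      _["W1"] = bW1, _["b1"] = bb1, _["W2"] = bW2, _["b2"] = bb2,
      _["W3"] = bW3, _["b3"] = bb3, _["train_loss"] = train_loss,
      _["val_loss"] = val_loss, _["epochs_run"] = epochs_run,
      _["best_val_loss"] = best_val);
}

// [[Rcpp::export]]
arma::vec mlp_forward(const List& weights, const arma::mat& X) {
  arma::mat W1 = weights["W1"], W2 = weights["W2"], W3 = weights["W3"];
  arma::rowvec b1 = weights["b1"], b2 = weights["b2"], b3 = weights["b3"];
  return forward_probs(X, W1, b1, W2, b2, W3, b3);
}
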