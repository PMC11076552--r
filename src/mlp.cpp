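// Small fully-connected feedforward classifier: minibatch Adam on
// softmax cross-entropy, seeded Glorot-uniform init, optional early
// stopping on validation loss with restore-best. All randomness comes
// from a private mt19937 so results are reproducible given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const int ACT_RELU = 0;
const int ACT_TANH = 1;

mat activate(const mat& z, int act) {
  if (act == ACT_RELU) return clamp(z, 0.0, datum::inf);
  return tanh(z);
}

mat activate_grad(const mat& z, int act) {
  if (act == ACT_RELU) return conv_to<mat>::from(z > 0.0);
  mat t = tanh(z);
  return 1.0 - t % t;
}

// row-wise softmax with max-shift for stability
mat softmax_rows(const mat& z) {
  mat shifted = z.each_col() - max(z, 1);
  mat e = exp(shifted);
  return e.each_col() / sum(e, 1);
}

mat forward(const mat& X, const std::vector<mat>& W,
            const std::vector<rowvec>& b, int act) {
  mat a = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    mat z = a * W[l];
    z.each_row() += b[l];
    a = (l + 1 < L) ? activate(z, act) : softmax_rows(z);
  }
  return a;
}

double ce_loss(const mat& P, const ivec& y) {
  double s = 0.0;
  for (uword i = 0; i < y.n_elem; ++i)
    s -= std::log(std::max(P(i, (uword)y(i)), 1e-12));
  return s / (double)y.n_elem;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::ivec& y, int n_classes,
                         const arma::mat& Xval, const arma::ivec& yval,
                         const arma::ivec& hidden, int activation,
                         double learning_rate, int batch_size, int max_epochs,
                         int patience, int seed) {
  const uword n = X.n_rows, d = X.n_cols;
  const size_t L = hidden.n_elem + 1;        // weight layers
  const bool use_val = Xval.n_rows > 0 && patience > 0;

  std::vector<uword> sizes;
  sizes.push_back(d);
  for (uword l = 0; l < hidden.n_elem; ++l) sizes.push_back((uword)hidden(l));
  sizes.push_back((uword)n_classes);

  std::mt19937 rng((uint32_t)seed);
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    double limit = std::sqrt(6.0 / (double)(sizes[l] + sizes[l + 1]));
    std::uniform_real_distribution<double> U(-limit, limit);
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (uword j = 0; j < W[l].n_cols; ++j)       // column-major fill, fixed order
      for (uword i = 0; i < W[l].n_rows; ++i)
        W[l](i, j) = U(rng);
    b[l] = rowvec(sizes[l + 1], fill::zeros);
  }

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (size_t l = 0; l < L; ++l) {
    mW[l] = zeros<mat>(size(W[l])); vW[l] = zeros<mat>(size(W[l]));
    mb[l] = zeros<rowvec>(sizes[l + 1]); vb[l] = zeros<rowvec>(sizes[l + 1]);
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  // one-hot targets
  mat Y(n, (uword)n_classes, fill::zeros);
  for (uword i = 0; i < n; ++i) Y(i, (uword)y(i)) = 1.0;

  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  std::vector<mat> bestW = W;
  std::vector<rowvec> bestb = b;
  double best_val = datum::inf;
  int wait = 0, epochs_run = 0;
  const uword bs = std::min<uword>((uword)std::max(batch_size, 1), n);

  std::vector<mat> A(L + 1), Z(L);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    // Fisher-Yates with our own rng (stdlib-independent determinism)
    for (uword i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<uword> Ui(0, i);
      std::swap(order[i], order[Ui(rng)]);
    }
    for (uword start = 0; start < n; start += bs) {
      uword end = std::min(start + bs, n) - 1;
      uvec idx(end - start + 1);
      for (uword k = 0; k < idx.n_elem; ++k) idx(k) = order[start + k];
      A[0] = X.rows(idx);
      for (size_t l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l + 1 < L) ? activate(Z[l], activation) : softmax_rows(Z[l]);
      }
      double m_inv = 1.0 / (double)idx.n_elem;
      mat dZ = (A[L] - Y.rows(idx)) * m_inv;
      ++t;
      double c1 = 1.0 - std::pow(beta1, (double)t);
      double c2 = 1.0 - std::pow(beta2, (double)t);
      for (size_t l = L; l-- > 0;) {
        mat dW = A[l].t() * dZ;
        rowvec db = sum(dZ, 0);
        if (l > 0) {
          mat dA = dZ * W[l].t();
          dZ = dA % activate_grad(Z[l - 1], activation);
        }
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * dW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * (dW % dW);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * db;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * (db % db);
        W[l] -= learning_rate * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
        b[l] -= learning_rate * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
      }
    }
    epochs_run = epoch + 1;
    if (use_val) {
      double vloss = ce_loss(forward(Xval, W, b, activation), yval);
      if (vloss < best_val - 1e-10) {
        best_val = vloss;
        bestW = W; bestb = b;
        wait = 0;
      } else if (++wait >= patience) {
        break;
      }
    }
  }

  if (use_val) { W = bestW; b = bestb; }
  else if (Xval.n_rows > 0) best_val = ce_loss(forward(Xval, W, b, activation), yval);
  double train_loss = ce_loss(forward(X, W, b, activation), y);

  Rcpp::List Wl(L), bl(L);
  for (size_t l = 0; l < L; ++l) { Wl[l] = W[l]; bl[l] = b[l]; }
  return Rcpp::List::create(
    Rcpp::Named("weights") = Wl,
    Rcpp::Named("biases") = bl,
    Rcpp::Named("epochs_run") = epochs_run,
    Rcpp::Named("best_val_loss") = (Xval.n_rows > 0) ? best_val : NA_REAL,
    Rcpp::Named("train_loss") = train_loss);
}

// [[Rcpp::export]]
arma::mat mlp_predict_cpp(const Rcpp::List& weights, const Rcpp::List& biases,
                          int activation, const arma::mat& X) {
  const size_t L = weights.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(weights[l]);
    b[l] = Rcpp::as<rowvec>(biases[l]);
  }
  return forward(X, W, b, activation);
}
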