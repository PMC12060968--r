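// Minibatch Adam trainer for a small fully connected regression network.
// All randomness (weight init, shuffle order, validation split) is drawn in
// R and passed in, so training is a deterministic function of its inputs.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat activate(const arma::mat& z, int act) {
  if (act == 0) return arma::clamp(z, 0.0, arma::datum::inf); // relu
  return arma::tanh(z);
}

static arma::mat activate_grad(const arma::mat& z, int act) {
  if (act == 0) return arma::conv_to<arma::mat>::from(z > 0.0);
  arma::mat t = arma::tanh(z);
  return 1.0 - t % t;
}

static arma::vec forward(const arma::mat& X,
                         const std::vector<arma::mat>& W,
                         const std::vector<arma::rowvec>& b, int act) {
  arma::mat A = X;
  for (size_t l = 0; l < W.size(); ++l) {
    A = A * W[l];
    A.each_row() += b[l];
    if (l + 1 < W.size()) A = activate(A, act);
  }
  return A.col(0);
}

// [[Rcpp::export]]
List mlp_fit_cpp(const arma::mat& X, const arma::vec& y,
                 List W0, List b0,
                 const arma::mat& Xval, const arma::vec& yval,
                 const arma::imat& order, int batch_size,
                 double lr, double weight_decay,
                 int patience, std::string activation) {
  const int n = X.n_rows;
  const int epochs = order.n_cols;
  const int L = W0.size();
  const int act = (activation == "relu") ? 0 : 1;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  std::vector<arma::mat> W(L), mW(L), vW(L), Wbest(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L), bbest(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = as<arma::rowvec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }

  const bool use_val = (patience > 0) && (Xval.n_rows > 0);
  double best_val = arma::datum::inf;
  int best_epoch = 0, wait = 0, epochs_run = 0;
  long t = 0;

  arma::vec train_mse(epochs, arma::fill::zeros);
  arma::vec val_mse(epochs, arma::fill::value(NA_REAL));

  std::vector<arma::mat> A(L + 1), Z(L);

  for (int e = 0; e < epochs; ++e) {
    double sse = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int stop = std::min(start + batch_size, n) - 1;
      arma::uvec idx(stop - start + 1);
      for (int k = start; k <= stop; ++k) idx[k - start] = order(k, e) - 1;
      const int nb = idx.n_elem;

      A[0] = X.rows(idx);
      for (int l = 0; l < L; ++l) {
        Z[l] = A[l] * W[l];
        Z[l].each_row() += b[l];
        A[l + 1] = (l + 1 < L) ? activate(Z[l], act) : Z[l];
      }
      arma::vec resid = A[L].col(0) - y.elem(idx);
      sse += arma::dot(resid, resid);

      arma::mat delta = resid / (double)nb;  // d(mean sq/2)/d out
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = A[l].t() * delta;
        arma::rowvec gb = arma::sum(delta, 0);
        if (weight_decay > 0) gW += weight_decay * W[l];
        if (l > 0) delta = (delta * W[l].t()) % activate_grad(Z[l - 1], act);
        ++t;
        mW[l] = b1 * mW[l] + (1 - b1) * gW;
        vW[l] = b2 * vW[l] + (1 - b2) * (gW % gW);
        mb[l] = b1 * mb[l] + (1 - b1) * gb;
        vb[l] = b2 * vb[l] + (1 - b2) * (gb % gb);
        double corr = lr * std::sqrt(1 - std::pow(b2, (double)t)) /
                      (1 - std::pow(b1, (double)t));
        W[l] -= corr * mW[l] / (arma::sqrt(vW[l]) + eps);
        b[l] -= corr * mb[l] / (arma::sqrt(vb[l]) + eps);
      }
    }
    train_mse[e] = sse / n;
    if (!std::isfinite(train_mse[e])) {
      stop("training diverged (non-finite loss) at epoch %d", e + 1);
    }
    epochs_run = e + 1;
    if (use_val) {
      arma::vec pv = forward(Xval, W, b, act) - yval;
      val_mse[e] = arma::dot(pv, pv) / Xval.n_rows;
      if (val_mse[e] < best_val - 1e-12) {
        best_val = val_mse[e];
        best_epoch = e + 1;
        Wbest = W; bbest = b;
        wait = 0;
      } else if (++wait > patience) {
        break;
      }
    }
  }

  if (use_val && best_epoch > 0) { W = Wbest; b = bbest; }
  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) { Wout[l] = W[l]; bout[l] = b[l]; }
  return List::create(
    _["W"] = Wout, _["b"] = bout,
    _["train_mse"] = train_mse.head(epochs_run),
    _["val_mse"] = val_mse.head(epochs_run),
    _["best_epoch"] = use_val ? best_epoch : epochs_run,
    _["epochs_run"] = epochs_run);
}

// [[Rcpp::export]]
arma::vec mlp_forward_cpp(const arma::mat& X, List Wl, List bl,
                          std::string activation) {
  const int L = Wl.size();
  const int act = (activation == "relu") ? 0 : 1;
  std::vector<arma::mat> W(L);
  std::vector<arma::rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(Wl[l]);
    b[l] = as<arma::rowvec>(bl[l]);
  }
  return forward(X, W, b, act);
}
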