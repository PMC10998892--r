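// Stochastic-gradient training loop for the one-hidden-layer
// post-surgery connectome predictor. The hot loop lives here because a
// fold touches ~edges x hidden weight matrices thousands of times.
// Two structural facts keep it fast: (1) the prior gate zeroes the
// loss gradient outside the prior support, so the output layer only
// ever updates its support rows (passed in restricted form, with the
// constant off-support loss term per sample supplied separately), and
// (2) input edge vectors are sparse, so first-layer products touch
// only the columns of the nonzero input edges. Everything random
// (initial weights, epoch shuffles) is drawn in R beforehand so
// results are bit-reproducible under a seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec hidden_act(const mat& W1, const vec& b1,
                      const rowvec& x, const uvec& nz) {
  vec z = b1;
  for (uword t = 0; t < nz.n_elem; ++t) {
    z += W1.col(nz[t]) * x[nz[t]];
  }
  return clamp(z, 0.0, datum::inf);
}

// mean squared error over the full edge dimension E, using the
// support-restricted output layer plus the per-sample constant term
static double gated_mse(const mat& X, const mat& Ys, const vec& cst,
                        const std::vector<uvec>& nz, const vec& gate,
                        const mat& W1, const vec& b1,
                        const mat& W2s, const vec& b2s, const double E) {
  double acc = 0.0;
  for (uword i = 0; i < X.n_rows; ++i) {
    vec h = hidden_act(W1, b1, X.row(i), nz[i]);
    vec err = gate % (W2s * h + b2s) - Ys.row(i).t();
    acc += dot(err, err) + cst[i];
  }
  return acc / (E * X.n_rows);
}

static std::vector<uvec> nonzero_cols(const mat& X) {
  std::vector<uvec> nz(X.n_rows);
  for (uword i = 0; i < X.n_rows; ++i) {
    nz[i] = find(abs(X.row(i)) > 0.0);
  }
  return nz;
}

// [[Rcpp::export]]
Rcpp::List fcnet_sgd_cpp(const arma::mat& X, const arma::mat& Ys,
                         const arma::vec& cst,
                         const arma::mat& Xval, const arma::mat& Yvals,
                         const arma::vec& cstval,
                         const arma::vec& gate,
                         arma::mat W1, arma::vec b1,
                         arma::mat W2s, arma::vec b2s,
                         const double lr, const int epochs,
                         const int val_every, const int batch_size,
                         const arma::imat& order, const double E) {
  const uword n = X.n_rows;
  const uword H = W1.n_rows;
  std::vector<uvec> nz = nonzero_cols(X);
  std::vector<uvec> nzval = nonzero_cols(Xval);
  std::vector<double> train_curve, val_curve;
  std::vector<int> val_epochs;
  train_curve.reserve(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    double sq_sum = 0.0;
    for (uword start = 0; start < n; start += batch_size) {
      const uword stop = std::min<uword>(start + batch_size, n);
      const uword k = stop - start;
      // accumulate batch gradients at the current weights
      mat dW2s(size(W2s), fill::zeros);
      vec db2s(b2s.n_elem, fill::zeros);
      vec db1(H, fill::zeros);
      mat dHs(H, k);            // per-sample hidden gradients
      uvec ids(k);
      for (uword i = 0; i < k; ++i) {
        const uword id = static_cast<uword>(order(ep, start + i)) - 1;
        ids[i] = id;
        vec z = b1;
        const uvec& cols = nz[id];
        for (uword t = 0; t < cols.n_elem; ++t) {
          z += W1.col(cols[t]) * X(id, cols[t]);
        }
        vec h = clamp(z, 0.0, datum::inf);
        vec err = gate % (W2s * h + b2s) - Ys.row(id).t();
        sq_sum += dot(err, err) + cst[id];
        vec G = (2.0 / (E * k)) * (gate % err);
        dW2s += G * h.t();
        db2s += G;
        vec dh = W2s.t() * G;
        dh.elem(find(z <= 0.0)).zeros();
        dHs.col(i) = dh;
        db1 += dh;
      }
      W2s -= lr * dW2s;
      b2s -= lr * db2s;
      b1 -= lr * db1;
      for (uword i = 0; i < k; ++i) {
        const uword id = ids[i];
        const uvec& cols = nz[id];
        const vec dh = dHs.col(i);
        for (uword t = 0; t < cols.n_elem; ++t) {
          W1.col(cols[t]) -= (lr * X(id, cols[t])) * dh;
        }
      }
    }
    train_curve.push_back(sq_sum / (E * n));
    if (Xval.n_rows > 0 && ((ep + 1) % val_every == 0 || ep + 1 == epochs)) {
      val_curve.push_back(gated_mse(Xval, Yvals, cstval, nzval, gate,
                                    W1, b1, W2s, b2s, E));
      val_epochs.push_back(ep + 1);
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W1") = W1, Rcpp::Named("b1") = b1,
    Rcpp::Named("W2s") = W2s, Rcpp::Named("b2s") = b2s,
    Rcpp::Named("training_curve") = train_curve,
    Rcpp::Named("validation_curve") = val_curve,
    Rcpp::Named("validation_epochs") = val_epochs);
}
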