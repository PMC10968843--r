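// Compiled training loop for the multilayer perceptron base learner:
// ReLU hidden layers, softmax output, full-batch Adam on the cross-entropy
// loss with L2 weight decay. Weight initialisation happens in R (seeded
// there); this routine is deterministic given its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat softmax_rows_cpp(mat z) {
  z.each_col() -= max(z, 1);
  z = exp(z);
  z.each_col() /= sum(z, 1);
  return z;
}

// [[Rcpp::export(name = ".mlp_train_cpp")]]
Rcpp::List mlp_train_cpp(const arma::mat& X, const arma::mat& Y,
                         Rcpp::List W0, Rcpp::List b0,
                         int max_iter, double lr, double tol, int patience,
                         double loss_floor, double l2) {
  const int nlay = W0.size();
  const int n = X.n_rows;
  std::vector<mat> W(nlay), mW(nlay), vW(nlay);
  std::vector<rowvec> b(nlay), mb(nlay), vb(nlay);
  for (int l = 0; l < nlay; ++l) {
    W[l] = Rcpp::as<mat>(W0[l]);
    b[l] = Rcpp::as<rowvec>(b0[l]);
    mW[l] = zeros<mat>(W[l].n_rows, W[l].n_cols);
    vW[l] = mW[l];
    mb[l] = zeros<rowvec>(b[l].n_elem);
    vb[l] = mb[l];
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  std::vector<mat> A(nlay + 1);
  double prev_loss = std::numeric_limits<double>::infinity();
  int stall = 0, it = 0;

  for (it = 1; it <= max_iter; ++it) {
    A[0] = X;
    for (int l = 0; l < nlay; ++l) {
      mat Z = A[l] * W[l];
      Z.each_row() += b[l];
      A[l + 1] = (l < nlay - 1) ? clamp(Z, 0.0, datum::inf)
                                : softmax_rows_cpp(Z);
    }
    mat P = clamp(A[nlay], 1e-15, 1.0 - 1e-15);
    double loss = -accu(Y % log(P)) / n;
    if (loss < loss_floor) break;
    double rel = (prev_loss - loss) / std::max(prev_loss, 1e-12);
    stall = (std::isfinite(rel) && rel < tol) ? stall + 1 : 0;
    if (stall >= patience) break;
    prev_loss = loss;

    mat delta = (A[nlay] - Y) / n;  // softmax + cross-entropy gradient
    const double c1 = 1.0 - std::pow(b1, it), c2 = 1.0 - std::pow(b2, it);
    for (int l = nlay - 1; l >= 0; --l) {
      mat gW = A[l].t() * delta + l2 * W[l];
      rowvec gb = sum(delta, 0);
      if (l > 0) {
        delta = delta * W[l].t();
        delta %= conv_to<mat>::from(A[l] > 0);  // ReLU gate
      }
      mW[l] = b1 * mW[l] + (1 - b1) * gW;
      vW[l] = b2 * vW[l] + (1 - b2) * square(gW);
      mb[l] = b1 * mb[l] + (1 - b1) * gb;
      vb[l] = b2 * vb[l] + (1 - b2) * square(gb);
      W[l] -= lr * (mW[l] / c1) / (sqrt(vW[l] / c2) + eps);
      b[l] -= lr * (mb[l] / c1) / (sqrt(vb[l] / c2) + eps);
    }
  }

  Rcpp::List Wout(nlay), bout(nlay);
  for (int l = 0; l < nlay; ++l) {
    Wout[l] = W[l];
    bout[l] = Rcpp::NumericVector(b[l].begin(), b[l].end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}

// Manhattan (L1) cross-distance matrix: rows of A against rows of B.
// Works on transposed copies so the inner loop walks contiguous memory.
// [[Rcpp::export(name = ".l1_cross_dist")]]
arma::mat l1_cross_dist(const arma::mat& A, const arma::mat& B) {
  const mat At = A.t(), Bt = B.t();
  mat out(A.n_rows, B.n_rows);
  for (uword j = 0; j < Bt.n_cols; ++j) {
    const vec b = Bt.col(j);
    for (uword i = 0; i < At.n_cols; ++i)
      out(i, j) = accu(abs(At.col(i) - b));
  }
  return out;
}
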