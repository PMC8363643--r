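#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Adam state for one parameter tensor.
struct AdamState {
  mat m, v;
  AdamState(uword r, uword c) : m(r, c, fill::zeros), v(r, c, fill::zeros) {}
};

static inline void adam_step(mat &theta, const mat &grad, AdamState &st,
                             double lr, double b1, double b2, double eps,
                             double b1t, double b2t) {
  st.m = b1 * st.m + (1.0 - b1) * grad;
  st.v = b2 * st.v + (1.0 - b2) * (grad % grad);
  theta -= lr * (st.m / (1.0 - b1t)) / (sqrt(st.v / (1.0 - b2t)) + eps);
}

static inline mat softmax_rows(const mat &Z) {
  mat S = Z.each_col() - max(Z, 1);
  S = exp(S);
  return S.each_col() / sum(S, 1);
}

// Full-batch training of the gating-layer classifier:
//   y = w (*) x  ->  [dense + ReLU + dropout] x (L-1)  ->  dense -> softmax,
// categorical cross-entropy loss, Adam updates, and projection of the gate
// weights onto [0, inf) after every update. The gate has no bias and a linear
// activation, so gate output is the exact elementwise product.
//
// Weights arrive initialized from R; dropout masks are drawn from R's RNG
// stream (unif_rand), so a set.seed() before the call makes the whole trial
// deterministic.
//
// [[Rcpp::export]]
Rcpp::List cpp_train_gate_mlp(const arma::mat &X,   // n x k, min-max normalized
                              const arma::mat &Y,   // n x C, one-hot
                              arma::vec w,          // k gate weights (init 1)
                              Rcpp::List W_init,    // dense weights, fan_in x fan_out
                              Rcpp::List b_init,    // dense biases
                              double dropout,
                              int epochs,
                              double lr, double beta1, double beta2,
                              double adam_eps, double prob_floor) {
  const uword n = X.n_rows;
  const int L = W_init.size();  // L-1 hidden layers + output layer

  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W_init[l]);
    b[l] = Rcpp::as<rowvec>(b_init[l]);
  }

  AdamState st_w(w.n_elem, 1);
  std::vector<AdamState> st_W, st_b;
  for (int l = 0; l < L; ++l) {
    st_W.emplace_back(W[l].n_rows, W[l].n_cols);
    st_b.emplace_back(1, b[l].n_elem);
  }

  const double keep = 1.0 - dropout;
  bool failed = false;
  double last_loss = NA_REAL;

  std::vector<mat> A(L), Zs(L), M(L);  // per-layer activations, pre-activations, masks

  for (int epoch = 1; epoch <= epochs && !failed; ++epoch) {
    // ---- forward (training mode) ----
    mat Xg = X.each_row() % w.t();
    mat cur = Xg;
    for (int l = 0; l < L - 1; ++l) {
      Zs[l] = cur * W[l];
      Zs[l].each_row() += b[l];
      cur = clamp(Zs[l], 0.0, datum::inf);  // ReLU
      if (dropout > 0.0) {
        mat mask(cur.n_rows, cur.n_cols);
        for (uword j = 0; j < mask.n_cols; ++j)
          for (uword i = 0; i < mask.n_rows; ++i)
            mask(i, j) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
        M[l] = mask;
        cur %= mask;
      }
      A[l] = cur;
    }
    mat ZL = cur * W[L - 1];
    ZL.each_row() += b[L - 1];
    mat P = softmax_rows(ZL);

    mat Pf = clamp(P, prob_floor, 1.0);
    last_loss = -accu(Y % log(Pf)) / (double)n;
    if (!std::isfinite(last_loss)) { failed = true; break; }

    // ---- backward ----
    mat dZ = (P - Y) / (double)n;
    std::vector<mat> gW(L);
    std::vector<rowvec> gb(L);
    for (int l = L - 1; l >= 0; --l) {
      const mat &Ain = (l == 0) ? Xg : A[l - 1];
      gW[l] = Ain.t() * dZ;
      gb[l] = sum(dZ, 0);
      mat dA = dZ * W[l].t();
      if (l > 0) {
        if (dropout > 0.0) dA %= M[l - 1];
        dZ = dA % conv_to<mat>::from(Zs[l - 1] > 0.0);
      } else {
        // dA is the gradient w.r.t. the gate output; gate is linear, no bias.
        vec gw = sum(dA % X, 0).t();
        double b1t = std::pow(beta1, epoch), b2t = std::pow(beta2, epoch);
        mat wmat(w);
        adam_step(wmat, mat(gw), st_w, lr, beta1, beta2, adam_eps, b1t, b2t);
        w = wmat.col(0);
        w = clamp(w, 0.0, datum::inf);  // non-negativity projection
      }
    }
    double b1t = std::pow(beta1, epoch), b2t = std::pow(beta2, epoch);
    for (int l = 0; l < L; ++l) {
      adam_step(W[l], gW[l], st_W[l], lr, beta1, beta2, adam_eps, b1t, b2t);
      mat bm(b[l]);
      adam_step(bm, mat(gb[l]), st_b[l], lr, beta1, beta2, adam_eps, b1t, b2t);
      b[l] = bm.row(0);
    }
  }

  // ---- final evaluation pass (no dropout) ----
  mat cur = X.each_row() % w.t();
  for (int l = 0; l < L - 1; ++l) {
    mat Z = cur * W[l];
    Z.each_row() += b[l];
    cur = clamp(Z, 0.0, datum::inf);
  }
  mat ZL = cur * W[L - 1];
  ZL.each_row() += b[L - 1];
  mat P = softmax_rows(ZL);
  double final_loss = -accu(Y % log(clamp(P, prob_floor, 1.0))) / (double)n;

  uword correct = 0;
  for (uword i = 0; i < n; ++i)
    if (P.row(i).index_max() == Y.row(i).index_max()) ++correct;
  double acc = (double)correct / (double)n;

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = vec(b[l].t());
  }

  return Rcpp::List::create(
      Rcpp::Named("gate") = w,
      Rcpp::Named("W") = Wout,
      Rcpp::Named("b") = bout,
      Rcpp::Named("final_loss") = final_loss,
      Rcpp::Named("final_accuracy") = acc,
      Rcpp::Named("last_train_loss") = last_loss,
      Rcpp::Named("failed") = failed);
}
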