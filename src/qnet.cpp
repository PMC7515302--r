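// Q-network numerics: two 1x1 convolution layers (per-pixel MLP), a
// fully-connected hidden layer, each followed by batch normalization and
// ReLU, and a fully-connected tanh output head with one Q-value per action.
// Training uses minibatch BN statistics, backpropagation, a pseudo-Huber
// loss (sqrt(1 + e^2) - 1) or plain squared error, and Adam. Parameters and
// optimizer state are mutated in place through views on the R matrices.
// Hidden-layer elementwise work (bias + BN + ReLU and its backward pass)
// runs in fused per-column loops; only the gemms go through BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double BN_EPS = 1e-5;

static arma::mat mview(List& l, const char* nm) {
  NumericMatrix m = l[nm];
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}
static arma::vec vview(List& l, const char* nm) {
  NumericVector v = l[nm];
  return arma::vec(v.begin(), v.size(), false, true);
}

// Build the (B*npix) x 2 per-pixel input (prey mask, predator mask) from
// integer window codes (B x npix, row-major windows).
static arma::mat pixel_input(const IntegerMatrix& obs) {
  int B = obs.nrow(), npix = obs.ncol();
  arma::mat P(B * npix, 2, arma::fill::zeros);
  for (int b = 0; b < B; b++)
    for (int p = 0; p < npix; p++) {
      int code = obs(b, p);
      if (code == 1) P(b * npix + p, 0) = 1.0;
      else if (code == 2) P(b * npix + p, 1) = 1.0;
    }
  return P;
}

struct BNCache {
  arma::vec mu, sd;  // batch mean and sqrt(var + eps)
  arma::mat xhat;
};

// In place on the pre-activation A = X*W: add bias, batch-normalize with
// minibatch statistics, apply ReLU. Fills the backprop cache and the ReLU
// mask, and updates the running statistics.
static void layer_train(arma::mat& A, const arma::vec& b, const arma::vec& g,
                        const arma::vec& be, arma::vec& mu_r, arma::vec& va_r,
                        double momentum, BNCache& C, arma::mat& M) {
  const arma::uword n = A.n_rows, K = A.n_cols;
  C.mu.set_size(K); C.sd.set_size(K);
  C.xhat.set_size(n, K); M.set_size(n, K);
  for (arma::uword j = 0; j < K; j++) {
    double* a = A.colptr(j);
    const double bj = b[j];
    double s = 0.0;
    for (arma::uword i = 0; i < n; i++) { a[i] += bj; s += a[i]; }
    const double mu = s / n;
    double ss = 0.0;
    for (arma::uword i = 0; i < n; i++) {
      const double d = a[i] - mu;
      ss += d * d;
    }
    const double va = ss / n;
    const double sd = std::sqrt(va + BN_EPS);
    C.mu[j] = mu; C.sd[j] = sd;
    mu_r[j] = momentum * mu_r[j] + (1.0 - momentum) * mu;
    va_r[j] = momentum * va_r[j] + (1.0 - momentum) * va;
    double* xh = C.xhat.colptr(j);
    double* mm = M.colptr(j);
    const double gj = g[j], bej = be[j];
    for (arma::uword i = 0; i < n; i++) {
      const double x = (a[i] - mu) / sd;
      xh[i] = x;
      const double y = gj * x + bej;
      if (y > 0) { a[i] = y; mm[i] = 1.0; }
      else { a[i] = 0.0; mm[i] = 0.0; }
    }
  }
}

// In place on A = X*W: bias + BN with running statistics + ReLU (inference).
static void layer_infer(arma::mat& A, const arma::vec& b, const arma::vec& g,
                        const arma::vec& be, const arma::vec& mu,
                        const arma::vec& va) {
  const arma::uword n = A.n_rows, K = A.n_cols;
  for (arma::uword j = 0; j < K; j++) {
    double* a = A.colptr(j);
    const double sc = g[j] / std::sqrt(va[j] + BN_EPS);
    const double sh = be[j] - (mu[j] - b[j]) * sc;  // bias folded in
    for (arma::uword i = 0; i < n; i++) {
      const double y = sc * a[i] + sh;
      a[i] = y > 0 ? y : 0.0;
    }
  }
}

// In place on dH (gradient w.r.t. the layer output): ReLU mask, BN
// backward; dH becomes the gradient w.r.t. the pre-bias activation.
// Also fills dgamma, dbeta and the bias gradient.
static void layer_back(arma::mat& dH, const arma::mat& M, const BNCache& C,
                       const arma::vec& g, arma::vec& dg, arma::vec& dbe,
                       arma::vec& db) {
  const arma::uword n = dH.n_rows, K = dH.n_cols;
  dg.set_size(K); dbe.set_size(K); db.set_size(K);
  for (arma::uword j = 0; j < K; j++) {
    double* d = dH.colptr(j);
    const double* mm = M.colptr(j);
    const double* xh = C.xhat.colptr(j);
    double s1 = 0.0, s2 = 0.0;
    for (arma::uword i = 0; i < n; i++) {
      const double v = d[i] * mm[i];
      d[i] = v;
      s1 += v; s2 += v * xh[i];
    }
    dg[j] = s2; dbe[j] = s1;
    const double m1 = s1 / n, m2 = s2 / n, sc = g[j] / C.sd[j];
    double sdb = 0.0;
    for (arma::uword i = 0; i < n; i++) {
      const double v = sc * (d[i] - m1 - xh[i] * m2);
      d[i] = v; sdb += v;
    }
    db[j] = sdb;
  }
}

// scatter H2 (B*npix x nch) into the flattened fc input F (B x npix*nch)
static void flatten_fwd(const arma::mat& H2, arma::mat& F, int B, int npix,
                        int nch) {
  for (int b = 0; b < B; b++)
    for (int p = 0; p < npix; p++) {
      const double* src = H2.memptr() ;
      for (int ch = 0; ch < nch; ch++)
        F.at(b, p * nch + ch) = src[(size_t)ch * H2.n_rows + (size_t)b * npix + p];
    }
}
static void flatten_bwd(const arma::mat& dF, arma::mat& dH2, int B, int npix,
                        int nch) {
  for (int b = 0; b < B; b++)
    for (int p = 0; p < npix; p++) {
      double* dst = dH2.memptr();
      for (int ch = 0; ch < nch; ch++)
        dst[(size_t)ch * dH2.n_rows + (size_t)b * npix + p] =
            dF.at(b, p * nch + ch);
    }
}

// Inference-mode forward pass (running BN statistics): B x na Q-values.
// [[Rcpp::export]]
NumericMatrix cpp_qnet_infer(List params, IntegerMatrix obs, int vr) {
  int B = obs.nrow(), npix = vr * vr;
  arma::mat W1 = mview(params, "W1"), W2 = mview(params, "W2"),
            W3 = mview(params, "W3"), W4 = mview(params, "W4");
  arma::vec b1 = vview(params, "b1"), b2 = vview(params, "b2"),
            b3 = vview(params, "b3"), b4 = vview(params, "b4");
  arma::vec g1 = vview(params, "g1"), be1 = vview(params, "be1"),
            mu1 = vview(params, "mu1"), va1 = vview(params, "va1");
  arma::vec g2 = vview(params, "g2"), be2 = vview(params, "be2"),
            mu2 = vview(params, "mu2"), va2 = vview(params, "va2");
  arma::vec g3 = vview(params, "g3"), be3 = vview(params, "be3"),
            mu3 = vview(params, "mu3"), va3 = vview(params, "va3");

  arma::mat P = pixel_input(obs);
  arma::mat H1 = P * W1;
  layer_infer(H1, b1, g1, be1, mu1, va1);
  arma::mat H2 = H1 * W2;
  layer_infer(H2, b2, g2, be2, mu2, va2);
  int nch = W2.n_cols;
  arma::mat F(B, npix * nch);
  flatten_fwd(H2, F, B, npix, nch);
  arma::mat H3 = F * W3;
  layer_infer(H3, b3, g3, be3, mu3, va3);
  arma::mat Q = arma::tanh(H3 * W4 + arma::repmat(b4.t(), B, 1));
  return wrap(Q);
}

struct Grads {
  double loss;
  arma::mat dW1, dW2, dW3, dW4;
  arma::vec db1, db2, db3, db4, dg1, dbe1, dg2, dbe2, dg3, dbe3;
};

// Shared training-mode forward + backward. When update_running is false the
// running BN statistics are left untouched (momentum forced to 1).
static Grads forward_backward(List& params, const IntegerMatrix& obs,
                              const IntegerVector& actions,
                              const NumericVector& y, int vr, int loss_type,
                              bool update_running, double momentum) {
  int B = obs.nrow(), npix = vr * vr;
  arma::mat W1 = mview(params, "W1"), W2 = mview(params, "W2"),
            W3 = mview(params, "W3"), W4 = mview(params, "W4");
  arma::vec b1 = vview(params, "b1"), b2 = vview(params, "b2"),
            b3 = vview(params, "b3"), b4 = vview(params, "b4");
  arma::vec g1 = vview(params, "g1"), be1 = vview(params, "be1"),
            mu1 = vview(params, "mu1"), va1 = vview(params, "va1");
  arma::vec g2 = vview(params, "g2"), be2 = vview(params, "be2"),
            mu2 = vview(params, "mu2"), va2 = vview(params, "va2");
  arma::vec g3 = vview(params, "g3"), be3 = vview(params, "be3"),
            mu3 = vview(params, "mu3"), va3 = vview(params, "va3");
  const double mom = update_running ? momentum : 1.0;

  // ---- forward ----
  arma::mat P = pixel_input(obs);
  arma::mat H1 = P * W1;
  BNCache C1; arma::mat M1;
  layer_train(H1, b1, g1, be1, mu1, va1, mom, C1, M1);
  arma::mat H2 = H1 * W2;
  BNCache C2; arma::mat M2;
  layer_train(H2, b2, g2, be2, mu2, va2, mom, C2, M2);
  int nch = W2.n_cols;
  arma::mat F(B, npix * nch);
  flatten_fwd(H2, F, B, npix, nch);
  arma::mat H3 = F * W3;
  BNCache C3; arma::mat M3;
  layer_train(H3, b3, g3, be3, mu3, va3, mom, C3, M3);
  arma::mat U4 = H3 * W4;
  U4.each_row() += b4.t();
  arma::mat Q = arma::tanh(U4);

  // ---- loss on the selected actions ----
  Grads G;
  arma::vec dq(B);
  double loss = 0.0;
  for (int i = 0; i < B; i++) {
    const double q = Q(i, actions[i] - 1);
    const double ei = y[i] - q;
    if (loss_type == 0) {
      const double s = std::sqrt(1.0 + ei * ei);
      loss += s - 1.0;
      dq[i] = -ei / s / B;
    } else {
      loss += ei * ei;
      dq[i] = -2.0 * ei / B;
    }
  }
  G.loss = loss / B;

  // ---- backward ----
  arma::mat dU4(B, W4.n_cols, arma::fill::zeros);
  for (int i = 0; i < B; i++) {
    const int a = actions[i] - 1;
    dU4(i, a) = dq[i] * (1.0 - Q(i, a) * Q(i, a));
  }
  G.dW4 = H3.t() * dU4;
  G.db4 = arma::sum(dU4, 0).t();
  arma::mat dH3 = dU4 * W4.t();
  layer_back(dH3, M3, C3, g3, G.dg3, G.dbe3, G.db3);
  G.dW3 = F.t() * dH3;
  arma::mat dF = dH3 * W3.t();
  arma::mat dH2(B * npix, nch);
  flatten_bwd(dF, dH2, B, npix, nch);
  layer_back(dH2, M2, C2, g2, G.dg2, G.dbe2, G.db2);
  G.dW2 = H1.t() * dH2;
  arma::mat dH1 = dH2 * W2.t();
  layer_back(dH1, M1, C1, g1, G.dg1, G.dbe1, G.db1);
  G.dW1 = P.t() * dH1;
  return G;
}

// Fused elementwise Adam step (bias-corrected), in place.
static void adam_fused(double* w, double* m, double* v, const double* gr,
                       size_t n, double lr, double t) {
  const double B1 = 0.9, B2 = 0.999, EPS = 1e-8;
  const double c1 = lr / (1.0 - std::pow(B1, t));
  const double c2 = 1.0 / std::sqrt(1.0 - std::pow(B2, t));
  for (size_t i = 0; i < n; i++) {
    m[i] = B1 * m[i] + (1.0 - B1) * gr[i];
    v[i] = B2 * v[i] + (1.0 - B2) * gr[i] * gr[i];
    w[i] -= c1 * m[i] / (std::sqrt(v[i]) * c2 + EPS);
  }
}

static void adam_apply(List& params, List& mL, List& vL, const char* nm,
                       const double* gr, size_t n, double lr, double t) {
  NumericVector w = params[nm], m = mL[nm], v = vL[nm];
  adam_fused(REAL(w), REAL(m), REAL(v), gr, n, lr, t);
}

// One minibatch gradient step. actions are 1-based; y are (scaled) Bellman
// targets. loss_type: 0 pseudo-Huber, 1 squared error. Returns the batch
// loss. Mutates params (weights + BN running stats) and Adam state in place.
// [[Rcpp::export]]
double cpp_qnet_train_step(List params, List adam_m, List adam_v, int adam_t,
                           IntegerMatrix obs, IntegerVector actions,
                           NumericVector y, int vr, double lr, int loss_type,
                           double bn_momentum) {
  Grads G = forward_backward(params, obs, actions, y, vr, loss_type, true,
                             bn_momentum);
  const double t = (double)adam_t;
  adam_apply(params, adam_m, adam_v, "W1", G.dW1.memptr(), G.dW1.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "b1", G.db1.memptr(), G.db1.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "g1", G.dg1.memptr(), G.dg1.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "be1", G.dbe1.memptr(), G.dbe1.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "W2", G.dW2.memptr(), G.dW2.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "b2", G.db2.memptr(), G.db2.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "g2", G.dg2.memptr(), G.dg2.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "be2", G.dbe2.memptr(), G.dbe2.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "W3", G.dW3.memptr(), G.dW3.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "b3", G.db3.memptr(), G.db3.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "g3", G.dg3.memptr(), G.dg3.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "be3", G.dbe3.memptr(), G.dbe3.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "W4", G.dW4.memptr(), G.dW4.n_elem, lr, t);
  adam_apply(params, adam_m, adam_v, "b4", G.db4.memptr(), G.db4.n_elem, lr, t);
  return G.loss;
}

// Batch loss + gradient of the loss w.r.t. every parameter, without
// updating anything (finite-difference gradient checking).
// [[Rcpp::export]]
List cpp_qnet_loss_grads(List params, IntegerMatrix obs, IntegerVector actions,
                         NumericVector y, int vr, int loss_type) {
  Grads G = forward_backward(params, obs, actions, y, vr, loss_type, false, 1.0);
  return List::create(
      _["loss"] = G.loss,
      _["grads"] = List::create(
          _["W1"] = wrap(G.dW1), _["b1"] = wrap(G.db1), _["g1"] = wrap(G.dg1),
          _["be1"] = wrap(G.dbe1), _["W2"] = wrap(G.dW2), _["b2"] = wrap(G.db2),
          _["g2"] = wrap(G.dg2), _["be2"] = wrap(G.dbe2), _["W3"] = wrap(G.dW3),
          _["b3"] = wrap(G.db3), _["g3"] = wrap(G.dg3), _["be3"] = wrap(G.dbe3),
          _["W4"] = wrap(G.dW4), _["b4"] = wrap(G.db4)));
}

// Batch loss only, with BN batch statistics (finite-difference companion
// to cpp_qnet_loss_grads).
// [[Rcpp::export]]
double cpp_qnet_batch_loss(List params, IntegerMatrix obs, IntegerVector actions,
                           NumericVector y, int vr, int loss_type) {
  Grads G = forward_backward(params, obs, actions, y, vr, loss_type, false, 1.0);
  return G.loss;
}
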