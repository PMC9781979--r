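// Training core for the chained three-block dense network (7 -> 20, 27 -> 20,
// 27 -> 20). Minibatch Adam on the summed MSE of the three blocks, with
// either teacher forcing (blocks 2/3 see ground-truth upstream segments) or
// chained feeding (blocks see predictions; gradients flow through the whole
// chain), selectable per epoch. Arithmetic is single precision, the standard
// for dense-network training; all randomness (init, shuffling) comes from R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#ifdef __SSE2__
#include <xmmintrin.h>
#endif
using namespace arma;

namespace {

void act_fwd(fmat &A, const fmat &Z, int act) {
  switch (act) {
  case 0: A = Z; A.transform([](float z) { return z > 0 ? z : 0.01f * z; }); break;
  case 1: A = Z; A.transform([](float z) { return z > 0 ? z : 0.0f; }); break;
  case 2: A = 1.0 / (1.0 + exp(-Z)); break;
  default: A = tanh(Z);
  }
}

fmat act_grad(const fmat &Z, const fmat &A, int act) {
  switch (act) {
  case 0: { fmat G(size(Z)); G.fill(0.01f); G.elem(find(Z > 0)).fill(1.0f); return G; }
  case 1: { fmat G(size(Z), fill::zeros); G.elem(find(Z > 0)).fill(1.0f); return G; }
  case 2: return A % (1.0 - A);
  default: return 1.0 - A % A;
  }
}

struct Block {
  std::vector<fmat> W; std::vector<frowvec> b;
  std::vector<fmat> mW, vW; std::vector<frowvec> mb, vb;
};

Block block_from_list(Rcpp::List bl) {
  Block B;
  Rcpp::List Ws = bl["W"], bs = bl["b"];
  for (int l = 0; l < Ws.size(); ++l) {
    B.W.push_back(conv_to<fmat>::from(Rcpp::as<mat>(Ws[l])));
    B.b.push_back(conv_to<frowvec>::from(Rcpp::as<rowvec>(bs[l])));
    B.mW.push_back(fmat(size(B.W.back()), fill::zeros));
    B.vW.push_back(fmat(size(B.W.back()), fill::zeros));
    B.mb.push_back(frowvec(B.b.back().n_elem, fill::zeros));
    B.vb.push_back(frowvec(B.b.back().n_elem, fill::zeros));
  }
  return B;
}

struct FwdCache { std::vector<fmat> A, Z; };

fmat block_forward(const Block &B, const fmat &X, int act, FwdCache &fc) {
  int L = B.W.size();
  fc.A.assign(L + 1, fmat()); fc.Z.assign(L, fmat());
  fc.A[0] = X;
  for (int l = 0; l < L; ++l) {
    fc.Z[l] = fc.A[l] * B.W[l];
    fc.Z[l].each_row() += B.b[l];
    if (l < L - 1) act_fwd(fc.A[l + 1], fc.Z[l], act); else fc.A[l + 1] = fc.Z[l];
  }
  return fc.A[L];
}

// One Adam step on a block; returns the gradient w.r.t. the block input
// (computed with the pre-update weights), for chained backpropagation.
fmat block_adam_step(Block &B, const FwdCache &fc, fmat d, int act,
                     float lr, float b1, float b2, float eps, int t) {
  int L = B.W.size();
  float c1 = 1.0f - std::pow(b1, t), c2 = 1.0f - std::pow(b2, t);
  fmat dX;
  for (int l = L - 1; l >= 0; --l) {
    fmat dW = fc.A[l].t() * d;
    frowvec db = sum(d, 0);
    if (l > 0) d = (d * B.W[l].t()) % act_grad(fc.Z[l - 1], fc.A[l], act);
    else dX = d * B.W[l].t();
    B.mW[l] = b1 * B.mW[l] + (1 - b1) * dW;
    B.vW[l] = b2 * B.vW[l] + (1 - b2) * square(dW);
    B.W[l] -= lr * (B.mW[l] / c1) / (sqrt(B.vW[l] / c2) + eps);
    B.mb[l] = b1 * B.mb[l] + (1 - b1) * db;
    B.vb[l] = b2 * B.vb[l] + (1 - b2) * square(db);
    B.b[l] -= lr * (B.mb[l] / c1) / (sqrt(B.vb[l] / c2) + eps);
  }
  return dX;
}

std::vector<Block> blocks_in(Rcpp::List blocks_init) {
  std::vector<Block> B;
  for (int k = 0; k < 3; ++k) B.push_back(block_from_list(blocks_init[k]));
  return B;
}

Rcpp::List blocks_out(const std::vector<Block> &B) {
  Rcpp::List out;
  for (int k = 0; k < 3; ++k) {
    Rcpp::List Ws, bs;
    for (size_t l = 0; l < B[k].W.size(); ++l) {
      Ws.push_back(conv_to<mat>::from(B[k].W[l]));
      bs.push_back(conv_to<rowvec>::from(B[k].b[l]));
    }
    out.push_back(Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs));
  }
  return out;
}

} // namespace

// perms: n x epochs matrix of 0-based shuffled row indices (one column per
// epoch); lr_epoch: learning rate per epoch; teacher_epoch: per-epoch flag,
// 1 = teacher forcing (blocks 2/3 see ground-truth upstream segments),
// 0 = chained (blocks see predictions; gradients flow through the chain).
// Y is n x 60.
// [[Rcpp::export]]
Rcpp::List train_chain_cpp(const arma::mat &X, const arma::mat &Y,
                           Rcpp::List blocks_init, int act, int batch,
                           const arma::vec &lr_epoch,
                           const arma::ivec &teacher_epoch,
                           const arma::imat &perms) {
  std::vector<Block> B = blocks_in(blocks_init);
  int n = X.n_rows, epochs = lr_epoch.n_elem;
#ifdef __SSE2__
  // flush denormals to zero for the duration of training: hard-zero
  // activations (ReLU) decay Adam moment estimates into subnormals, which
  // stall the FPU by an order of magnitude; at 1e-38 they carry no signal
  unsigned int csr = _mm_getcsr();
  _mm_setcsr(csr | 0x8040);   // FTZ | DAZ
#endif
  // single-precision arithmetic throughout training (the normalized data
  // and ~1e-4-scale losses sit comfortably inside float range)
  fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);
  vec lossh(epochs, fill::zeros);
  int t = 0;
  FwdCache f1, f2, f3;
  uvec c1 = regspace<uvec>(0, 19), c2 = regspace<uvec>(20, 39), c3 = regspace<uvec>(40, 59);
  for (int ep = 0; ep < epochs; ++ep) {
    float lr = (float)lr_epoch(ep); double epl = 0.0; int nb = 0;
    bool teach = teacher_epoch(ep) != 0;
    for (int s = 0; s < n; s += batch) {
      int e = std::min(s + batch, n) - 1;
      uvec idx = conv_to<uvec>::from(perms.col(ep).subvec(s, e));
      fmat Xb = Xf.rows(idx);
      fmat Y1 = Yf.submat(idx, c1), Y2 = Yf.submat(idx, c2), Y3 = Yf.submat(idx, c3);
      fmat P1 = block_forward(B[0], Xb, act, f1);
      fmat P2 = block_forward(B[1], join_rows(Xb, teach ? Y1 : P1), act, f2);
      fmat P3 = block_forward(B[2], join_rows(Xb, teach ? Y2 : P2), act, f3);
      float m = Xb.n_rows;
      if (!P1.is_finite() || !P2.is_finite() || !P3.is_finite())
        Rcpp::stop("non-finite activations during training (NaN loss)");
      epl += (accu(square(P1 - Y1)) + accu(square(P2 - Y2)) + accu(square(P3 - Y3))) / (m * 60.0);
      nb++; ++t;
      fmat g1 = 2.0f * (P1 - Y1) / (m * 60.0f);
      fmat g2 = 2.0f * (P2 - Y2) / (m * 60.0f);
      fmat g3 = 2.0f * (P3 - Y3) / (m * 60.0f);
      fmat dX3 = block_adam_step(B[2], f3, g3, act, lr, 0.9f, 0.999f, 1e-7f, t);
      if (!teach) g2 += dX3.cols(7, 26);
      fmat dX2 = block_adam_step(B[1], f2, g2, act, lr, 0.9f, 0.999f, 1e-7f, t);
      if (!teach) g1 += dX2.cols(7, 26);
      block_adam_step(B[0], f1, g1, act, lr, 0.9f, 0.999f, 1e-7f, t);
    }
    lossh(ep) = epl / nb;
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
#ifdef __SSE2__
  _mm_setcsr(csr);
#endif
  return Rcpp::List::create(Rcpp::Named("blocks") = blocks_out(B),
                            Rcpp::Named("loss") = lossh);
}

// Forward pass of the full chain. chained = true feeds each block the
// previous block's prediction (inference); false feeds ground-truth segments
// from Y (teacher forcing, requires Y).
// [[Rcpp::export]]
arma::mat forward_chain_cpp(const arma::mat &X, Rcpp::List blocks, int act,
                            bool chained, const arma::mat &Y) {
  std::vector<Block> B = blocks_in(blocks);
  FwdCache fc;
  fmat Xf = conv_to<fmat>::from(X), Yf = conv_to<fmat>::from(Y);
  fmat P1 = block_forward(B[0], Xf, act, fc);
  fmat U1 = chained ? P1 : fmat(Yf.cols(0, 19));
  fmat P2 = block_forward(B[1], join_rows(Xf, U1), act, fc);
  fmat U2 = chained ? P2 : fmat(Yf.cols(20, 39));
  fmat P3 = block_forward(B[2], join_rows(Xf, U2), act, fc);
  return conv_to<mat>::from(join_rows(P1, P2, P3));
}
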