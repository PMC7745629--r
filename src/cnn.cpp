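// Small CNN regressor: stride-2 3x3 conv blocks (zero pad 1, ReLU) ->
// global average pooling -> dense(ReLU) -> linear scalar head.
//
// Activations are (channels x Npix*B) matrices, pixel index column-major
// within a sample (p = h + H*w), samples in consecutive blocks.
// Convolutions run as im2col gathers (tap-major row layout, so each
// output column is filled by contiguous per-tap memcpys) followed by BLAS
// GEMM. Training runs in single precision for speed on one CPU; inference
// entry points run in double so perturbation deltas are reproducible to
// tight tolerances. All randomness (epoch shuffles) comes from R's RNG, so
// set.seed() on the R side makes a session bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Arch {
  int H, W;
  arma::ivec channels;
  int dense_width;
  bool flatten;  // false: global average pool; true: flatten feature map
};

Arch parse_arch(const List& arch) {
  Arch a;
  a.H = as<int>(arch["height_px"]);
  a.W = as<int>(arch["width_px"]);
  a.channels = as<arma::ivec>(arch["conv_channels"]);
  a.dense_width = as<int>(arch["dense_width"]);
  a.flatten = arch.containsElementNamed("pooling") &&
              as<std::string>(arch["pooling"]) == "flatten";
  return a;
}

inline int out_dim(int n) { return (n - 1) / 2 + 1; }  // k=3, s=2, p=1

// zero-copy alias of a contiguous column block [s, e) of X
template <typename eT>
arma::Mat<eT> col_block(const arma::Mat<eT>& X, int s, int e) {
  return arma::Mat<eT>(const_cast<eT*>(X.colptr(s)), X.n_rows, e - s,
                       false, true);
}

template <typename eT>
struct Net {
  std::vector<arma::Mat<eT>> convW;  // Cout x 9*Cin, column = tap*Cin + cin
  std::vector<arma::Col<eT>> convB;
  arma::Mat<eT> denseW;
  arma::Col<eT> denseB;
  arma::Mat<eT> outW;  // 1 x dense_width
  eT outB;
};

template <typename eT>
Net<eT> unpack_weights(const List& wl, const Arch& a) {
  Net<eT> w;
  const int L = a.channels.n_elem;
  for (int l = 0; l < L; ++l) {
    w.convW.push_back(arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(wl[2 * l])));
    w.convB.push_back(arma::conv_to<arma::Col<eT>>::from(
        arma::vec(as<arma::mat>(wl[2 * l + 1]).col(0))));
  }
  w.denseW = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(wl[2 * L]));
  w.denseB = arma::conv_to<arma::Col<eT>>::from(
      arma::vec(as<arma::mat>(wl[2 * L + 1]).col(0)));
  w.outW = arma::conv_to<arma::Mat<eT>>::from(as<arma::mat>(wl[2 * L + 2]));
  w.outB = (eT)as<arma::mat>(wl[2 * L + 3])(0, 0);
  return w;
}

template <typename eT>
List pack_weights(const Net<eT>& w) {
  List out;
  for (size_t l = 0; l < w.convW.size(); ++l) {
    out.push_back(wrap(arma::conv_to<arma::mat>::from(w.convW[l])));
    out.push_back(wrap(arma::conv_to<arma::mat>::from(
        arma::Mat<eT>(w.convB[l]))));
  }
  out.push_back(wrap(arma::conv_to<arma::mat>::from(w.denseW)));
  out.push_back(wrap(arma::conv_to<arma::mat>::from(arma::Mat<eT>(w.denseB))));
  out.push_back(wrap(arma::conv_to<arma::mat>::from(w.outW)));
  arma::mat ob(1, 1); ob(0, 0) = (double)w.outB;
  out.push_back(wrap(ob));
  return out;
}

// K(9*Cin x Ho*Wo*B) from A(Cin x Hi*Wi*B); K must be pre-sized.
// Inner loops run over contiguous ho runs with precomputed validity
// bounds, so there is no per-tap branching on the hot path.
template <typename eT>
void im2col(const arma::Mat<eT>& A, int Cin, int Hi, int Wi, int B,
            arma::Mat<eT>& K) {
  const int Ho = out_dim(Hi), Wo = out_dim(Wi);
  const size_t krows = 9 * (size_t)Cin;
  for (int b = 0; b < B; ++b) {
    const size_t in_off = (size_t)b * Hi * Wi;
    const size_t out_off = (size_t)b * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      eT* kcol0 = K.colptr(out_off + (size_t)wo * Ho);
      for (int kw = 0; kw < 3; ++kw) {
        const int w = wo * 2 - 1 + kw;
        if (w < 0 || w >= Wi) {
          for (int ho = 0; ho < Ho; ++ho) {
            eT* d = kcol0 + (size_t)ho * krows + (size_t)(kw * 3) * Cin;
            std::fill(d, d + 3 * Cin, (eT)0);
          }
          continue;
        }
        const eT* acol = A.colptr(in_off + (size_t)w * Hi);
        for (int kh = 0; kh < 3; ++kh) {
          const int ho_lo = (kh == 0) ? 1 : 0;     // h = 2*ho - 1 + kh >= 0
          const int ho_hi = std::min(Ho - 1, (Hi - kh) / 2);  // h <= Hi - 1
          const size_t roff = (size_t)(kw * 3 + kh) * Cin;
          for (int ho = 0; ho < ho_lo; ++ho) {
            eT* d = kcol0 + (size_t)ho * krows + roff;
            std::fill(d, d + Cin, (eT)0);
          }
          for (int ho = ho_hi + 1; ho < Ho; ++ho) {
            eT* d = kcol0 + (size_t)ho * krows + roff;
            std::fill(d, d + Cin, (eT)0);
          }
          const eT* s = acol + (size_t)(2 * ho_lo - 1 + kh) * Cin;
          eT* d = kcol0 + (size_t)ho_lo * krows + roff;
          if (Cin == 1) {
            for (int ho = ho_lo; ho <= ho_hi; ++ho) {
              *d = *s; d += krows; s += 2;
            }
          } else {
            const size_t cb = (size_t)Cin * sizeof(eT);
            const size_t sstep = 2 * (size_t)Cin;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) {
              std::memcpy(d, s, cb); d += krows; s += sstep;
            }
          }
        }
      }
    }
  }
}

// Transpose scatter-add of im2col: dK into dA (pre-sized, zeroed here).
template <typename eT>
void col2im(const arma::Mat<eT>& dK, int Cin, int Hi, int Wi, int B,
            arma::Mat<eT>& dA) {
  const int Ho = out_dim(Hi), Wo = out_dim(Wi);
  const size_t krows = 9 * (size_t)Cin;
  dA.zeros();
  for (int b = 0; b < B; ++b) {
    const size_t in_off = (size_t)b * Hi * Wi;
    const size_t out_off = (size_t)b * Ho * Wo;
    for (int wo = 0; wo < Wo; ++wo) {
      const eT* kcol0 = dK.colptr(out_off + (size_t)wo * Ho);
      for (int kw = 0; kw < 3; ++kw) {
        const int w = wo * 2 - 1 + kw;
        if (w < 0 || w >= Wi) continue;
        eT* acol = dA.colptr(in_off + (size_t)w * Hi);
        for (int kh = 0; kh < 3; ++kh) {
          const int ho_lo = (kh == 0) ? 1 : 0;
          const int ho_hi = std::min(Ho - 1, (Hi - kh) / 2);
          const eT* s = kcol0 + (size_t)ho_lo * krows +
                        (size_t)(kw * 3 + kh) * Cin;
          eT* d = acol + (size_t)(2 * ho_lo - 1 + kh) * Cin;
          if (Cin == 1) {
            for (int ho = ho_lo; ho <= ho_hi; ++ho) {
              *d += *s; s += krows; d += 2;
            }
          } else {
            const size_t sstep = krows;
            const size_t dstep = 2 * (size_t)Cin;
            for (int ho = ho_lo; ho <= ho_hi; ++ho) {
              for (int c = 0; c < Cin; ++c) d[c] += s[c];
              s += sstep; d += dstep;
            }
          }
        }
      }
    }
  }
}

template <typename eT>
inline void relu_inplace(arma::Mat<eT>& Z) {
  eT* p = Z.memptr();
  const size_t n = Z.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < (eT)0) p[i] = (eT)0;
}

// zero gradient entries where the cached post-ReLU activation is zero
template <typename eT>
inline void relu_backward(const arma::Mat<eT>& A, arma::Mat<eT>& dZ) {
  const eT* a = A.memptr();
  eT* d = dZ.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] <= (eT)0) d[i] = (eT)0;
}

// Reusable buffers; resized per batch (no-op when sizes repeat).
template <typename eT>
struct Workspace {
  std::vector<arma::Mat<eT>> K, A, dZ;
  arma::Mat<eT> A0, G, D1, dA;
  arma::Row<eT> out;
};

// K0, when given, is the precomputed layer-1 im2col of this batch (the
// input data never changes during training, so sessions build it once).
template <typename eT>
void forward(const Net<eT>& w, const Arch& a, const arma::Mat<eT>& X,
             Workspace<eT>& ws, bool cache,
             const arma::Mat<eT>* K0 = nullptr) {
  const int L = a.channels.n_elem;
  const int B = X.n_cols;
  ws.K.resize(L); ws.A.resize(L);
  int Hi = a.H, Wi = a.W, Cin = 1;
  // layer 0 input: reshape X to (1 x H*W*B) without copy semantics issues
  const arma::Mat<eT> A0(const_cast<eT*>(X.memptr()), 1,
                         (size_t)a.H * a.W * B, false, true);
  const arma::Mat<eT>* Ain = &A0;
  for (int l = 0; l < L; ++l) {
    const int Ho = out_dim(Hi), Wo = out_dim(Wi);
    const arma::Mat<eT>* Kl;
    if (l == 0 && K0 != nullptr) {
      Kl = K0;
    } else {
      ws.K[l].set_size(9 * Cin, (size_t)Ho * Wo * B);
      im2col(*Ain, Cin, Hi, Wi, B, ws.K[l]);
      Kl = &ws.K[l];
    }
    ws.A[l] = w.convW[l] * (*Kl);
    ws.A[l].each_col() += w.convB[l];
    relu_inplace(ws.A[l]);
    Ain = &ws.A[l];
    Hi = Ho; Wi = Wo; Cin = a.channels[l];
  }
  const size_t Np = (size_t)Hi * Wi;
  if (a.flatten) {
    // sample blocks are contiguous, so flatten is a pure reshape
    ws.G = arma::Mat<eT>(ws.A[L - 1].memptr(), Cin * Np, B);
  } else {
    ws.G.set_size(Cin, B);
    for (int b = 0; b < B; ++b) {
      ws.G.col(b) = arma::sum(ws.A[L - 1].cols(b * Np, (b + 1) * Np - 1), 1) /
                    (eT)Np;
    }
  }
  ws.D1 = w.denseW * ws.G;
  ws.D1.each_col() += w.denseB;
  relu_inplace(ws.D1);
  ws.out = w.outW * ws.D1;
  ws.out += w.outB;
  if (!cache) { /* buffers retained for reuse either way */ }
}

// MSE backward on one batch; fills gradients in g; returns batch loss.
template <typename eT>
double backward(const Net<eT>& w, const Arch& a, const arma::Mat<eT>& X,
                const arma::Row<eT>& y, Workspace<eT>& ws, Net<eT>& g,
                const arma::Mat<eT>* K0 = nullptr) {
  forward(w, a, X, ws, true, K0);
  const int L = a.channels.n_elem;
  const int B = X.n_cols;
  arma::Row<eT> resid = ws.out - y;
  const double loss = arma::mean(arma::square(
      arma::conv_to<arma::rowvec>::from(resid)));
  arma::Row<eT> dout = resid * ((eT)2 / (eT)B);

  g.outW = dout * ws.D1.t();
  g.outB = arma::accu(dout);
  arma::Mat<eT> dD1 = w.outW.t() * dout;
  relu_backward(ws.D1, dD1);
  g.denseW = dD1 * ws.G.t();
  g.denseB = arma::sum(dD1, 1);
  arma::Mat<eT> dG = w.denseW.t() * dD1;

  std::vector<int> Hs(L + 1), Ws_(L + 1);
  Hs[0] = a.H; Ws_[0] = a.W;
  for (int l = 0; l < L; ++l) {
    Hs[l + 1] = out_dim(Hs[l]); Ws_[l + 1] = out_dim(Ws_[l]);
  }

  ws.dZ.resize(L);
  const size_t Np = (size_t)Hs[L] * Ws_[L];
  arma::Mat<eT>& dtop = ws.dZ[L - 1];
  dtop.set_size(a.channels[L - 1], Np * B);
  if (a.flatten) {
    std::memcpy(dtop.memptr(), dG.memptr(),
                dtop.n_elem * sizeof(eT));  // inverse reshape
  } else {
    for (int b = 0; b < B; ++b) {
      arma::Col<eT> gb = dG.col(b) / (eT)Np;
      for (size_t p = 0; p < Np; ++p) dtop.col(b * Np + p) = gb;
    }
  }
  for (int l = L - 1; l >= 0; --l) {
    arma::Mat<eT>& dZ = ws.dZ[l];
    relu_backward(ws.A[l], dZ);
    const arma::Mat<eT>& Kl = (l == 0 && K0 != nullptr) ? *K0 : ws.K[l];
    g.convW[l] = dZ * Kl.t();
    g.convB[l] = arma::sum(dZ, 1);
    if (l > 0) {
      arma::Mat<eT> dK = w.convW[l].t() * dZ;
      ws.dZ[l - 1].set_size(a.channels[l - 1],
                            (size_t)Hs[l] * Ws_[l] * B);
      col2im(dK, (int)a.channels[l - 1], Hs[l], Ws_[l], B, ws.dZ[l - 1]);
    }
  }
  return loss;
}

// Keras-style Nadam (Dozat momentum schedule with 0.96 decay).
template <typename eT>
struct Nadam {
  double lr, beta1, beta2, eps;
  double m_schedule = 1.0;
  long t = 0;
  std::vector<arma::Mat<eT>> m, v;

  void init(const std::vector<arma::Mat<eT>*>& params) {
    for (auto* p : params) {
      m.push_back(arma::zeros<arma::Mat<eT>>(p->n_rows, p->n_cols));
      v.push_back(arma::zeros<arma::Mat<eT>>(p->n_rows, p->n_cols));
    }
  }
  void step(std::vector<arma::Mat<eT>*>& params,
            const std::vector<arma::Mat<eT>*>& grads) {
    ++t;
    const double mu_t = beta1 * (1.0 - 0.5 * std::pow(0.96, 0.004 * t));
    const double mu_t1 = beta1 * (1.0 - 0.5 * std::pow(0.96, 0.004 * (t + 1)));
    const double msch_new = m_schedule * mu_t;
    const double msch_next = msch_new * mu_t1;
    m_schedule = msch_new;
    const double v_corr = 1.0 - std::pow(beta2, (double)t);
    for (size_t i = 0; i < params.size(); ++i) {
      const arma::Mat<eT>& gm = *grads[i];
      m[i] = (eT)beta1 * m[i] + (eT)(1.0 - beta1) * gm;
      v[i] = (eT)beta2 * v[i] + (eT)(1.0 - beta2) * arma::square(gm);
      *params[i] -= (eT)lr *
        ((eT)(1.0 - mu_t) * (gm / (eT)(1.0 - msch_new)) +
         (eT)mu_t1 * (m[i] / (eT)(1.0 - msch_next))) /
        (arma::sqrt(v[i] / (eT)v_corr) + (eT)eps);
    }
  }
};

// biases as 1-column mats so one pointer list covers every parameter
template <typename eT>
struct ParamView {
  std::vector<arma::Mat<eT>> bias_holders;  // convB..., denseB, out bias
  std::vector<arma::Mat<eT>*> ptrs;
};

template <typename eT>
void sync_biases_to_net(ParamView<eT>& pv, Net<eT>& net) {
  const int L = net.convW.size();
  for (int l = 0; l < L; ++l) net.convB[l] = pv.bias_holders[l].col(0);
  net.denseB = pv.bias_holders[L].col(0);
  net.outB = pv.bias_holders[L + 1](0, 0);
}

template <typename eT>
ParamView<eT> make_param_view(Net<eT>& net) {
  ParamView<eT> pv;
  const int L = net.convW.size();
  pv.bias_holders.reserve(L + 2);
  for (int l = 0; l < L; ++l) pv.bias_holders.emplace_back(net.convB[l]);
  pv.bias_holders.emplace_back(net.denseB);
  pv.bias_holders.emplace_back(arma::Mat<eT>(1, 1, arma::fill::value(net.outB)));
  for (int l = 0; l < L; ++l) pv.ptrs.push_back(&net.convW[l]);
  pv.ptrs.push_back(&net.denseW);
  pv.ptrs.push_back(&net.outW);
  for (auto& b : pv.bias_holders) pv.ptrs.push_back(&b);
  return pv;
}

template <typename eT>
double mean_sq_err(const Net<eT>& w, const Arch& a, const arma::Mat<eT>& X,
                   const arma::Col<eT>& y, Workspace<eT>& ws, int chunk,
                   const arma::Mat<eT>* K0all = nullptr, size_t Np1 = 0) {
  const int n = X.n_cols;
  double acc = 0.0;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n);
    arma::Mat<eT> K0blk;
    if (K0all != nullptr) {
      K0blk = arma::Mat<eT>(const_cast<eT*>(K0all->colptr(s * Np1)),
                            K0all->n_rows, (size_t)(e - s) * Np1,
                            false, true);
    }
    forward(w, a, col_block(X, s, e), ws, false,
            K0all != nullptr ? &K0blk : nullptr);
    for (int i = s; i < e; ++i) {
      const double r = (double)ws.out[i - s] - (double)y[i];
      acc += r * r;
    }
  }
  return acc / n;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_forward(Rcpp::List weights, Rcpp::List arch,
                                const arma::mat& X, int chunk = 16) {
  const Arch a = parse_arch(arch);
  if ((int)X.n_rows != a.H * a.W)
    stop("input has %d rows; architecture expects %d x %d = %d",
         (int)X.n_rows, a.H, a.W, a.H * a.W);
  const Net<double> w = unpack_weights<double>(weights, a);
  const int n = X.n_cols;
  NumericVector out(n);
  Workspace<double> ws;
  for (int s = 0; s < n; s += chunk) {
    const int e = std::min(s + chunk, n);
    forward(w, a, col_block(X, s, e), ws, false);
    for (int i = s; i < e; ++i) out[i] = ws.out[i - s];
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List init_weights, Rcpp::List arch,
                     const arma::mat& Xtr, const arma::vec& ytr,
                     const arma::mat& Xval, const arma::vec& yval,
                     double lr, int batch_size, int epochs,
                     double beta1 = 0.9, double beta2 = 0.999,
                     double eps = 1e-7) {
  const Arch a = parse_arch(arch);
  if ((int)Xtr.n_rows != a.H * a.W || (int)Xval.n_rows != a.H * a.W)
    stop("training data rows do not match architecture input size");
  const int n = Xtr.n_cols;
  if (n == 0 || Xval.n_cols == 0) stop("empty training or validation set");

  typedef float eT;
  Net<eT> w = unpack_weights<eT>(init_weights, a);
  Net<eT> g = w;  // shape holder for gradients
  const arma::Mat<eT> Xtr_f = arma::conv_to<arma::Mat<eT>>::from(Xtr);
  const arma::Col<eT> ytr_f = arma::conv_to<arma::Col<eT>>::from(ytr);
  const arma::Mat<eT> Xval_f = arma::conv_to<arma::Mat<eT>>::from(Xval);
  const arma::Col<eT> yval_f = arma::conv_to<arma::Col<eT>>::from(yval);

  ParamView<eT> pw = make_param_view(w);
  ParamView<eT> pg = make_param_view(g);
  Nadam<eT> opt;
  opt.lr = lr; opt.beta1 = beta1; opt.beta2 = beta2; opt.eps = eps;
  opt.init(pw.ptrs);

  NumericVector train_trace(epochs), val_trace(epochs);
  double best_val = R_PosInf;
  int best_epoch = -1;
  List best_weights = clone(init_weights);
  Workspace<eT> ws;
  arma::Mat<eT> Xb(Xtr_f.n_rows, std::min(batch_size, n));
  arma::Row<eT> yb;

  // layer-1 im2col depends only on the (fixed) data: build once, reuse
  const size_t Np1 = (size_t)out_dim(a.H) * out_dim(a.W);
  arma::Mat<eT> K1tr(9, Np1 * n), K1val(9, Np1 * Xval_f.n_cols);
  {
    const arma::Mat<eT> A0tr(const_cast<eT*>(Xtr_f.memptr()), 1,
                             (size_t)a.H * a.W * n, false, true);
    im2col(A0tr, 1, a.H, a.W, n, K1tr);
    const arma::Mat<eT> A0v(const_cast<eT*>(Xval_f.memptr()), 1,
                            (size_t)a.H * a.W * Xval_f.n_cols, false, true);
    im2col(A0v, 1, a.H, a.W, (int)Xval_f.n_cols, K1val);
  }
  arma::Mat<eT> K0b(9, Np1 * std::min(batch_size, n));

  for (int ep = 0; ep < epochs; ++ep) {
    IntegerVector ord = Rcpp::sample(n, n, false);  // R RNG, 1-based
    double loss_sum = 0.0;
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n);
      const int B = e - s;
      Xb.set_size(Xtr_f.n_rows, B);
      yb.set_size(B);
      K0b.set_size(9, Np1 * B);
      for (int i = 0; i < B; ++i) {
        const int j = ord[s + i] - 1;
        Xb.col(i) = Xtr_f.col(j);
        yb[i] = ytr_f[j];
        K0b.cols(i * Np1, (i + 1) * Np1 - 1) =
          K1tr.cols(j * Np1, (j + 1) * Np1 - 1);
      }
      const double loss = backward(w, a, Xb, yb, ws, g, &K0b);
      if (!std::isfinite(loss))
        stop("non-finite training loss at epoch %d", ep + 1);
      loss_sum += loss * B;
      // mirror gradient biases into holders before the update
      {
        const int L = (int)g.convW.size();
        for (int l = 0; l < L; ++l) pg.bias_holders[l].col(0) = g.convB[l];
        pg.bias_holders[L].col(0) = g.denseB;
        pg.bias_holders[L + 1](0, 0) = g.outB;
      }
      opt.step(pw.ptrs, pg.ptrs);
      sync_biases_to_net(pw, w);
    }
    train_trace[ep] = loss_sum / n;
    const double vloss = mean_sq_err(w, a, Xval_f, yval_f, ws, 128,
                                     &K1val, Np1);
    if (!std::isfinite(vloss))
      stop("non-finite validation loss at epoch %d", ep + 1);
    val_trace[ep] = vloss;
    if (vloss < best_val) {
      best_val = vloss;
      best_epoch = ep;
      best_weights = pack_weights(w);
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = best_weights,
                      _["train_mse"] = train_trace,
                      _["val_mse"] = val_trace,
                      _["best_epoch"] = best_epoch + 1,
                      _["best_val_mse"] = best_val);
}
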