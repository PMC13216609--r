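// Stride-1, same-padded 3x3 convolutional networks in single precision.
//
// Every activation canvas is stored channels x (B * P * Q) where P = h + 2,
// Q = w + 2 is the zero-padded spatial canvas of one sample and samples
// occupy contiguous column blocks. A 3x3 convolution is then nine GEMMs,
// one per kernel tap, each operating on a contiguous column range shifted
// by the tap's linear offset. Values that wrap across image-column
// boundaries land only in padding positions, which are masked to zero after
// every layer, so the interior is exact. This keeps all work inside large
// sgemm calls, which is what makes CPU training of the patch networks fast
// enough for routine use.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::stop;

namespace {

struct Net {
  std::vector<fmat> W;   // layer l: (c_out x 9*c_in)
  std::vector<fvec> b;   // (c_out)
  std::vector<int> cin, cout;
  int L = 0;
};

Net net_from_r(const List& Wl, const List& bl) {
  Net net;
  net.L = Wl.size();
  for (int l = 0; l < net.L; ++l) {
    Rcpp::NumericMatrix Wm = Wl[l];
    Rcpp::NumericVector bv = bl[l];
    fmat W = conv_to<fmat>::from(mat(Wm.begin(), Wm.nrow(), Wm.ncol(), false));
    fvec b = conv_to<fvec>::from(vec(bv.begin(), bv.size(), false));
    if (W.n_cols % 9 != 0) stop("weight matrix columns must be 9 * c_in");
    net.W.push_back(std::move(W));
    net.b.push_back(std::move(b));
    net.cout.push_back(Wm.nrow());
    net.cin.push_back(Wm.ncol() / 9);
  }
  return net;
}

List net_to_r(const Net& net) {
  List Wl(net.L), bl(net.L);
  for (int l = 0; l < net.L; ++l) {
    Rcpp::NumericMatrix Wm(net.W[l].n_rows, net.W[l].n_cols);
    for (uword j = 0; j < net.W[l].n_elem; ++j) Wm[j] = net.W[l](j);
    Rcpp::NumericVector bv(net.b[l].n_elem);
    for (uword j = 0; j < net.b[l].n_elem; ++j) bv[j] = net.b[l](j);
    Wl[l] = Wm; bl[l] = bv;
  }
  return List::create(Rcpp::Named("W") = Wl, Rcpp::Named("b") = bl);
}

// interior mask for B sample blocks, as a row vector over columns
frowvec make_mask(int P, int Q, int B) {
  frowvec m(static_cast<uword>(P) * Q * B, fill::zeros);
  for (int n = 0; n < B; ++n)
    for (int c = 1; c < Q - 1; ++c)
      for (int r = 1; r < P - 1; ++r)
        m(static_cast<uword>(n) * P * Q + static_cast<uword>(c) * P + r) = 1.0f;
  return m;
}

// Work proceeds in column chunks so that the chunk of the input and output
// canvases stays cache-resident across all nine kernel taps; otherwise the
// stride-1 convolutions are memory-bandwidth bound.
constexpr uword kChunk = 2048;

// Y += W_k * X shifted by tap offsets; X, Y are (c x N) canvases
void conv_accum(const fmat& Wfull, int cin, int cout, const fmat& X, fmat& Y,
                int P) {
  const uword N = X.n_cols;
  for (uword a = 0; a < N; a += kChunk) {
    const uword b = std::min(N, a + kChunk);  // chunk [a, b)
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      const long s = dy + static_cast<long>(P) * dx;
      const uword lo0 = s < 0 ? static_cast<uword>(-s) : 0;
      const uword hi0 = s > 0 ? N - 1 - static_cast<uword>(s) : N - 1;
      const uword lo = std::max(lo0, a);
      const uword hi = std::min(hi0, b - 1);
      if (lo > hi) continue;
      const uword len = hi - lo + 1;
      const fmat Wk = Wfull.cols(static_cast<uword>(k) * cin,
                                 static_cast<uword>(k) * cin + cin - 1);
      const fmat Xs(const_cast<float*>(X.memptr()) + (lo + s) * cin,
                    cin, len, false, true);
      fmat Ys(Y.memptr() + lo * cout, cout, len, false, true);
      Ys += Wk * Xs;
    }
  }
}

// gradient accumulation: dW_k += G(out range) * X(in range)^T and
// dX(in range) += W_k^T * G(out range)
void conv_backward(const fmat& Wfull, int cin, int cout, const fmat& X,
                   const fmat& G, fmat& dW, fmat* dX, int P) {
  const uword N = X.n_cols;
  if (cout == 1) {
    // single-channel gradient: tap-wise GEMMs degenerate to rank-1 updates,
    // so gather the nine shifted copies of the gradient row instead and use
    // two dense GEMMs
    fmat G9(N, 9, fill::zeros);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      const long s = dy + static_cast<long>(P) * dx;
      // column k holds G(j - s) at row j
      const uword dst0 = s > 0 ? static_cast<uword>(s) : 0;
      const uword src0 = s < 0 ? static_cast<uword>(-s) : 0;
      const uword len = N - (s > 0 ? s : -s);
      std::memcpy(G9.colptr(k) + dst0, G.memptr() + src0, sizeof(float) * len);
    }
    const fmat dWmat = X * G9;                    // (cin x 9)
    for (int k = 0; k < 9; ++k)
      for (int c = 0; c < cin; ++c)
        dW(0, static_cast<uword>(k) * cin + c) += dWmat(c, k);
    if (dX) {
      fmat Wr(cin, 9);
      for (int k = 0; k < 9; ++k)
        for (int c = 0; c < cin; ++c)
          Wr(c, k) = Wfull(0, static_cast<uword>(k) * cin + c);
      *dX += Wr * G9.t();
    }
    return;
  }
  for (uword a = 0; a < N; a += kChunk) {
    const uword b = std::min(N, a + kChunk);
    for (int k = 0; k < 9; ++k) {
      const int dy = k % 3 - 1, dx = k / 3 - 1;
      const long s = dy + static_cast<long>(P) * dx;
      const uword lo0 = s < 0 ? static_cast<uword>(-s) : 0;
      const uword hi0 = s > 0 ? N - 1 - static_cast<uword>(s) : N - 1;
      const uword lo = std::max(lo0, a);
      const uword hi = std::min(hi0, b - 1);
      if (lo > hi) continue;
      const uword len = hi - lo + 1;
      const fmat Gs(const_cast<float*>(G.memptr()) + lo * cout, cout, len,
                    false, true);
      const fmat Xs(const_cast<float*>(X.memptr()) + (lo + s) * cin,
                    cin, len, false, true);
      fmat dWk(dW.memptr() + static_cast<uword>(k) * cin * cout, cout, cin,
               false, true);
      dWk += Gs * Xs.t();
      if (dX) {
        const fmat Wk = Wfull.cols(static_cast<uword>(k) * cin,
                                   static_cast<uword>(k) * cin + cin - 1);
        fmat dXs(dX->memptr() + (lo + s) * cin, cin, len, false, true);
        dXs += Wk.t() * Gs;
      }
    }
  }
}

// copy sample data (c x h*w pixel-major) into the padded canvas column block
void fill_canvas(fmat& canvas, const fmat& data, const std::vector<int>& idx,
                 int h, int w, int P, int Q) {
  canvas.zeros();
  const int c = data.n_rows;
  for (size_t j = 0; j < idx.size(); ++j) {
    const long n = idx[j];
    for (int col = 0; col < w; ++col) {
      std::memcpy(canvas.colptr(j * static_cast<long>(P) * Q +
                                (col + 1) * static_cast<long>(P) + 1),
                  data.colptr(n * static_cast<long>(h) * w +
                              col * static_cast<long>(h)),
                  sizeof(float) * c * h);
    }
  }
}

// fused bias + activation + padding mask, single pass over the canvas
void bias_act_mask(fmat& Y, const fvec& b, const frowvec& mask, bool relu) {
  const uword c = Y.n_rows, N = Y.n_cols;
  const float* bp = b.memptr();
  const float* mp = mask.memptr();
  for (uword j = 0; j < N; ++j) {
    float* y = Y.colptr(j);
    if (mp[j] == 0.0f) {
      std::memset(y, 0, sizeof(float) * c);
    } else if (relu) {
      for (uword r = 0; r < c; ++r) {
        const float v = y[r] + bp[r];
        y[r] = v > 0.0f ? v : 0.0f;
      }
    } else {
      for (uword r = 0; r < c; ++r) y[r] += bp[r];
    }
  }
}

// forward pass over a prepared input canvas; activations stored per layer
void forward(const Net& net, const fmat& X0, const frowvec& mask, int P,
             std::vector<fmat>& acts) {
  const uword N = X0.n_cols;
  acts.resize(net.L + 1);
  acts[0] = X0;
  for (int l = 0; l < net.L; ++l) {
    acts[l + 1].zeros(net.cout[l], N);
    conv_accum(net.W[l], net.cin[l], net.cout[l], acts[l], acts[l + 1], P);
    bias_act_mask(acts[l + 1], net.b[l], mask, l < net.L - 1);
  }
}

fmat data_from_r(const NumericVector& x, int c, long npix_total) {
  fmat out(c, npix_total);
  const double* p = x.begin();
  for (long j = 0; j < npix_total; ++j)
    for (int ch = 0; ch < c; ++ch)
      out(ch, j) = static_cast<float>(p[ch * npix_total + j]);
  return out;
}

}  // namespace

// [[Rcpp::export]]
List cpp_cnn_train(List W0, List b0, NumericVector inputs, NumericVector targets,
                   IntegerVector dims, int epochs, int batch_size, double lr,
                   int seed) {
  // dims = (h, w, c_in, n_samples); inputs laid out (h, w, c_in, n), i.e.
  // pixel index fastest, channel next, sample last
  const int h = dims[0], w = dims[1], cin = dims[2];
  const long n = dims[3];
  const int P = h + 2, Q = w + 2;
  const long hw = static_cast<long>(h) * w;
  Net net = net_from_r(W0, b0);
  if (net.cin[0] != cin) stop("input channel count does not match the network");

  // reorder from (h*w, c, n) planes to channel-rows x pixel-columns
  fmat Xdata(cin, n * hw);
  {
    const double* p = inputs.begin();
    for (long s = 0; s < n; ++s)
      for (int ch = 0; ch < cin; ++ch)
        for (long j = 0; j < hw; ++j)
          Xdata(ch, s * hw + j) =
            static_cast<float>(p[s * hw * cin + ch * hw + j]);
  }
  fmat Tdata(1, n * hw);
  {
    const double* p = targets.begin();
    for (long j = 0; j < n * hw; ++j) Tdata(0, j) = static_cast<float>(p[j]);
  }

  // Adam state
  std::vector<fmat> mW(net.L), vW(net.L);
  std::vector<fvec> mb(net.L), vb(net.L);
  for (int l = 0; l < net.L; ++l) {
    mW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
    mb[l].zeros(net.b[l].n_elem);
    vb[l].zeros(net.b[l].n_elem);
  }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;

  std::vector<long> order(n);
  for (long i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(static_cast<unsigned>(seed));

  std::vector<double> loss_hist;
  std::vector<fmat> acts;
  std::vector<fmat> dW(net.L);
  std::vector<fvec> db(net.L);
  fmat X0, T;
  // ping-pong gradient canvases, sized for the widest layer
  int cmax = 1;
  for (int l = 0; l < net.L; ++l)
    cmax = std::max(cmax, std::max(net.cin[l], net.cout[l]));
  std::vector<float> bufA, bufB;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (long start = 0; start < n; start += batch_size) {
      const int B = static_cast<int>(std::min<long>(batch_size, n - start));
      const uword N = static_cast<uword>(B) * P * Q;
      std::vector<int> idx(order.begin() + start, order.begin() + start + B);
      frowvec mask = make_mask(P, Q, B);

      X0.set_size(cin, N);
      T.set_size(1, N);
      fill_canvas(X0, Xdata, idx, h, w, P, Q);
      fill_canvas(T, Tdata, idx, h, w, P, Q);

      forward(net, X0, mask, P, acts);

      // loss and its gradient in one pass (padding entries are zero on both
      // sides, so they contribute nothing)
      bufA.resize(static_cast<size_t>(cmax) * N);
      bufB.resize(static_cast<size_t>(cmax) * N);
      float* gp = bufA.data();
      float* xp = bufB.data();
      const float scale = 2.0f / (static_cast<float>(B) * hw);
      {
        const float* a = acts[net.L].memptr();
        const float* t = T.memptr();
        const uword ne = static_cast<uword>(net.cout[net.L - 1]) * N;
        double acc = 0.0;
        for (uword i = 0; i < ne; ++i) {
          const float d = a[i] - t[i];
          acc += static_cast<double>(d) * d;
          gp[i] = d * scale;
        }
        ep_loss += acc / hw;
      }

      for (int l = net.L - 1; l >= 0; --l) {
        const fmat G(gp, net.cout[l], N, false, true);
        dW[l].zeros(net.cout[l], 9 * net.cin[l]);
        db[l] = sum(G, 1);
        if (l > 0) {
          const uword ne = static_cast<uword>(net.cin[l]) * N;
          std::memset(xp, 0, sizeof(float) * ne);
          fmat dX(xp, net.cin[l], N, false, true);
          conv_backward(net.W[l], net.cin[l], net.cout[l], acts[l], G,
                        dW[l], &dX, P);
          // ReLU derivative of the producing layer; stored activations are
          // zero on padding, so this also re-zeros the padding positions
          const float* a = acts[l].memptr();
          for (uword i = 0; i < ne; ++i) xp[i] *= (a[i] > 0.0f);
          std::swap(gp, xp);
        } else {
          conv_backward(net.W[l], net.cin[l], net.cout[l], acts[l], G,
                        dW[l], nullptr, P);
        }
      }

      // Adam
      ++step;
      const float bc1 = 1.0f - std::pow(b1, static_cast<float>(step));
      const float bc2 = 1.0f - std::pow(b2, static_cast<float>(step));
      const float alpha = static_cast<float>(lr) * std::sqrt(bc2) / bc1;
      for (int l = 0; l < net.L; ++l) {
        mW[l] = b1 * mW[l] + (1.0f - b1) * dW[l];
        vW[l] = b2 * vW[l] + (1.0f - b2) * square(dW[l]);
        net.W[l] -= alpha * mW[l] / (sqrt(vW[l]) + eps);
        mb[l] = b1 * mb[l] + (1.0f - b1) * db[l];
        vb[l] = b2 * vb[l] + (1.0f - b2) * square(db[l]);
        net.b[l] -= alpha * mb[l] / (sqrt(vb[l]) + eps);
      }
    }
    loss_hist.push_back(ep_loss / static_cast<double>(n));
    Rcpp::checkUserInterrupt();
  }

  List out = net_to_r(net);
  out["loss"] = Rcpp::wrap(loss_hist);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cnn_predict(List Wl, List bl, NumericVector inputs,
                              IntegerVector dims, int batch_size) {
  const int h = dims[0], w = dims[1], cin = dims[2];
  const long n = dims[3];
  const int P = h + 2, Q = w + 2;
  const long hw = static_cast<long>(h) * w;
  Net net = net_from_r(Wl, bl);
  if (net.cin[0] != cin) stop("input channel count does not match the network");

  fmat Xdata(cin, n * hw);
  {
    const double* p = inputs.begin();
    for (long s = 0; s < n; ++s)
      for (int ch = 0; ch < cin; ++ch)
        for (long j = 0; j < hw; ++j)
          Xdata(ch, s * hw + j) =
            static_cast<float>(p[s * hw * cin + ch * hw + j]);
  }

  NumericVector out(n * hw);
  std::vector<fmat> acts;
  for (long start = 0; start < n; start += batch_size) {
    const int B = static_cast<int>(std::min<long>(batch_size, n - start));
    std::vector<int> idx(B);
    for (int j = 0; j < B; ++j) idx[j] = static_cast<int>(start + j);
    frowvec mask = make_mask(P, Q, B);
    fmat X0(cin, static_cast<uword>(B) * P * Q);
    fill_canvas(X0, Xdata, idx, h, w, P, Q);
    forward(net, X0, mask, P, acts);
    const fmat& Y = acts[net.L];
    for (int j = 0; j < B; ++j)
      for (int col = 0; col < w; ++col)
        for (int r = 0; r < h; ++r)
          out[(start + j) * hw + static_cast<long>(col) * h + r] =
            Y(0, static_cast<uword>(j) * P * Q + (col + 1) * P + r + 1);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cnn_activations(List Wl, List bl, NumericVector input,
                                  IntegerVector dims, int layer) {
  // single sample; returns the (h, w, c_layer) activation stack of `layer`
  const int h = dims[0], w = dims[1], cin = dims[2];
  const int P = h + 2, Q = w + 2;
  const long hw = static_cast<long>(h) * w;
  Net net = net_from_r(Wl, bl);
  if (layer < 1 || layer > net.L) stop("layer index out of range");

  fmat Xdata(cin, hw);
  for (int ch = 0; ch < cin; ++ch)
    for (long j = 0; j < hw; ++j)
      Xdata(ch, j) = static_cast<float>(input[ch * hw + j]);

  std::vector<int> idx{0};
  frowvec mask = make_mask(P, Q, 1);
  fmat X0(cin, static_cast<uword>(P) * Q);
  fill_canvas(X0, Xdata, idx, h, w, P, Q);
  std::vector<fmat> acts;
  forward(net, X0, mask, P, acts);
  const fmat& A = acts[layer];
  const int c = A.n_rows;
  NumericVector out(hw * c);
  out.attr("dim") = IntegerVector::create(h, w, c);
  for (int ch = 0; ch < c; ++ch)
    for (int col = 0; col < w; ++col)
      for (int r = 0; r < h; ++r)
        out[static_cast<long>(ch) * hw + static_cast<long>(col) * h + r] =
          A(ch, static_cast<uword>(col + 1) * P + r + 1);
  return out;
}
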