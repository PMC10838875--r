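// Multi-task 3D convolutional network: forward, backward, Adam.
//
// Single-precision throughout; activations are stored channel-major as
// (channels x n_voxels*n_volumes) matrices with column index
// vol*n_voxels + (x + ext*y + ext^2*z). Convolutions are 3x3x3, zero-padded,
// stride 1, realised as im2col + GEMM; im2col is materialised per z-slab so
// peak memory stays bounded even for full-scale (112^3) inputs.

#ifndef ARMA_NO_DEBUG
#define ARMA_NO_DEBUG
#endif
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::frowvec;
using arma::uword;

static const int K3 = 27; // 3x3x3 taps

// coarse wall-clock accounting of the training hot spots (for development
// and the occasional "where did the minute go" question)
#include <chrono>
#include <cstring>
static std::map<std::string, double> g_perf;
struct Tic {
  const char* name;
  std::chrono::high_resolution_clock::time_point t0;
  explicit Tic(const char* n) : name(n),
    t0(std::chrono::high_resolution_clock::now()) {}
  ~Tic() {
    g_perf[name] += std::chrono::duration<double>(
      std::chrono::high_resolution_clock::now() - t0).count();
  }
};

struct Adam {
  fmat m, v;
  void init(uword r, uword c) { m.zeros(r, c); v.zeros(r, c); }
};

struct ConvLayer {
  int in_ch, out_ch;
  fmat W;                       // out_ch x (in_ch*27)
  fvec gamma, beta, rmean, rvar;
  Adam aW, ag, ab;
  // per-batch caches (training)
  fmat xhat, out;               // out_ch x cols
  fvec invstd;
  std::vector<fmat> col_cache;  // im2col blocks in forward order
};

struct FCLayer {
  fmat W;       // in x out
  frowvec b;
  Adam aW, ab;
  fmat in, out; // caches
};

// backward-pass tape
struct Rec {
  int type;     // 0 conv, 1 pool, 2 add
  int layer;    // conv index
  int ext;      // input spatial extent
  int in, in2, out; // activation indices
  arma::umat argmax;
};

struct CNN3D {
  int extent, n_tasks;
  std::vector<int> channels, nlayers, fc_widths;
  std::vector<ConvLayer> convs;
  std::vector<int> conv_ext; // input extent per conv layer
  FCLayer fc1, fc2;
  fmat Wo; frowvec bo;
  Adam aWo, abo;
  float eta;
  float eta_m, eta_v;
  long t;                  // Adam step counter
  float bn_mom, bn_eps, b1, b2, a_eps;
  // max floats in one im2col slab buffer (~64 MB)
  size_t slab_cap;

  CNN3D(int ext, std::vector<int> ch, std::vector<int> nl,
        std::vector<int> fc, int tasks)
    : extent(ext), n_tasks(tasks), channels(ch), nlayers(nl), fc_widths(fc),
      eta(1.0f), eta_m(0.0f), eta_v(0.0f), t(0),
      bn_mom(0.9f), bn_eps(1e-5f), b1(0.9f), b2(0.999f), a_eps(1e-8f),
      slab_cap(16u * 1024u * 1024u) {
    int e = ext, in = 1;
    for (size_t g = 0; g < channels.size(); ++g) {
      for (int l = 0; l < nlayers[g]; ++l) {
        ConvLayer L;
        L.in_ch = in; L.out_ch = channels[g];
        L.W.zeros(L.out_ch, (uword)L.in_ch * K3);
        L.gamma.ones(L.out_ch); L.beta.zeros(L.out_ch);
        L.rmean.zeros(L.out_ch); L.rvar.ones(L.out_ch);
        L.aW.init(L.W.n_rows, L.W.n_cols);
        L.ag.init(L.out_ch, 1); L.ab.init(L.out_ch, 1);
        convs.push_back(L);
        conv_ext.push_back(e);
        in = channels[g];
      }
      e /= 2;
    }
    int flat = e * e * e * channels.back();
    fc1.W.zeros(flat, fc_widths[0]); fc1.b.zeros(fc_widths[0]);
    fc1.aW.init(flat, fc_widths[0]); fc1.ab.init(1, fc_widths[0]);
    fc2.W.zeros(fc_widths[0], fc_widths[1]); fc2.b.zeros(fc_widths[1]);
    fc2.aW.init(fc_widths[0], fc_widths[1]); fc2.ab.init(1, fc_widths[1]);
    Wo.zeros(fc_widths[1], n_tasks); bo.zeros(n_tasks);
    aWo.init(fc_widths[1], n_tasks); abo.init(1, n_tasks);
  }

  int slab_thickness(int ext, int in_ch) const {
    size_t per_slice = (size_t)in_ch * K3 * ext * ext;
    int zt = (int)(slab_cap / std::max<size_t>(per_slice, 1));
    if (zt < 1) zt = 1;
    if (zt > ext) zt = ext;
    return zt;
  }
};

// ---- im2col / col2im over one z-slab of one volume --------------------------

// Precomputed 3x3x3 tap offsets; k = (dx+1) + 3*(dy+1) + 9*(dz+1).
struct Taps {
  int dx[K3], dy[K3], dz[K3];
  Taps() {
    for (int k = 0; k < K3; ++k) {
      dx[k] = k % 3 - 1; dy[k] = (k / 3) % 3 - 1; dz[k] = k / 9 - 1;
    }
  }
};
static const Taps TAPS;

// A: in_ch x (nvox*nvol); fills cols (in_ch*27 x ext*ext*zt) for volume `vol`,
// output voxels z in [z0, z0+zt). Row index is k*in_ch + ic, so each tap of a
// column is a contiguous in_ch-float block and interior voxels reduce to 27
// small memcpys. Only boundary-touching columns are pre-zeroed.
static void im2col_slab(const fmat& A, int ext, int in_ch, int vol,
                        int z0, int zt, fmat& cols) {
  const size_t nvox = (size_t)ext * ext * ext;
  const size_t voff = (size_t)vol * nvox;
  const int e2 = ext * ext;
  cols.set_size((uword)in_ch * K3, (uword)e2 * zt);
  const float* a = A.memptr();
  float* c = cols.memptr();
  const size_t c_rows = cols.n_rows;
  long off[K3];
  for (int k = 0; k < K3; ++k)
    off[k] = (long)TAPS.dz[k] * e2 + (long)TAPS.dy[k] * ext + TAPS.dx[k];
  const size_t blk = sizeof(float) * in_ch;
  for (int z = z0; z < z0 + zt; ++z) {
    const bool zb = (z == 0 || z == ext - 1);
    for (int y = 0; y < ext; ++y) {
      const bool yb = zb || y == 0 || y == ext - 1;
      const size_t vb = voff + (size_t)z * e2 + (size_t)y * ext;
      float* crow = c + ((size_t)(z - z0) * e2 + (size_t)y * ext) * c_rows;
      if (!yb) {
        for (int x = 1; x < ext - 1; ++x) {
          float* cc = crow + (size_t)x * c_rows;
          const float* av = a + (vb + x) * in_ch;
          for (int k = 0; k < K3; ++k)
            std::memcpy(cc + (size_t)k * in_ch, av + off[k] * (long)in_ch, blk);
        }
        for (int x = 0; x < ext; x += ext - 1) {
          float* cc = crow + (size_t)x * c_rows;
          std::memset(cc, 0, sizeof(float) * c_rows);
          const float* av = a + (vb + x) * in_ch;
          for (int k = 0; k < K3; ++k) {
            const int nx = x + TAPS.dx[k];
            if (nx < 0 || nx >= ext) continue;
            std::memcpy(cc + (size_t)k * in_ch, av + off[k] * (long)in_ch, blk);
          }
        }
      } else {
        std::memset(crow, 0, sizeof(float) * c_rows * ext);
        for (int x = 0; x < ext; ++x) {
          float* cc = crow + (size_t)x * c_rows;
          for (int k = 0; k < K3; ++k) {
            const int nx = x + TAPS.dx[k], ny = y + TAPS.dy[k],
                      nz = z + TAPS.dz[k];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= ext || ny >= ext ||
                nz >= ext) continue;
            std::memcpy(cc + (size_t)k * in_ch,
                        a + (voff + (size_t)nz * e2 + (size_t)ny * ext + nx) *
                            in_ch, blk);
          }
        }
      }
    }
  }
}

// scatter-add of dcols (in_ch*27 x ext*ext*zt) into dX (in_ch x nvox*nvol)
static void col2im_slab(const fmat& dcols, int ext, int in_ch, int vol,
                        int z0, int zt, fmat& dX) {
  const size_t nvox = (size_t)ext * ext * ext;
  const size_t voff = (size_t)vol * nvox;
  const int e2 = ext * ext;
  const float* c = dcols.memptr();
  const size_t c_rows = dcols.n_rows;
  float* d = dX.memptr();
  long off[K3];
  for (int k = 0; k < K3; ++k)
    off[k] = (long)TAPS.dz[k] * e2 + (long)TAPS.dy[k] * ext + TAPS.dx[k];
  for (int z = z0; z < z0 + zt; ++z) {
    const bool zb = (z == 0 || z == ext - 1);
    for (int y = 0; y < ext; ++y) {
      const bool yb = zb || y == 0 || y == ext - 1;
      const size_t vb = voff + (size_t)z * e2 + (size_t)y * ext;
      const float* crow = c + ((size_t)(z - z0) * e2 + (size_t)y * ext) * c_rows;
      for (int x = 0; x < ext; ++x) {
        const float* cc = crow + (size_t)x * c_rows;
        const bool xb = yb || x == 0 || x == ext - 1;
        if (!xb) {
          float* dv = d + (vb + x) * in_ch;
          for (int k = 0; k < K3; ++k) {
            float* dk = dv + off[k] * (long)in_ch;
            const float* ck = cc + (size_t)k * in_ch;
            for (int ic = 0; ic < in_ch; ++ic) dk[ic] += ck[ic];
          }
        } else {
          for (int k = 0; k < K3; ++k) {
            const int nx = x + TAPS.dx[k], ny = y + TAPS.dy[k],
                      nz = z + TAPS.dz[k];
            if (nx < 0 || ny < 0 || nz < 0 || nx >= ext || ny >= ext ||
                nz >= ext) continue;
            float* dk = d + (voff + (size_t)nz * e2 + (size_t)ny * ext + nx) *
                        in_ch;
            const float* ck = cc + (size_t)k * in_ch;
            for (int ic = 0; ic < in_ch; ++ic) dk[ic] += ck[ic];
          }
        }
      }
    }
  }
}

// ---- layer forward/backward -------------------------------------------------

// conv -> BN -> ReLU. X: (in_ch x nvox*n). Returns (out_ch x nvox*n).
static fmat conv_forward(CNN3D& net, int li, const fmat& X, int ext, int n,
                         bool train) {
  ConvLayer& L = net.convs[li];
  const size_t nvox = (size_t)ext * ext * ext;
  fmat Z((uword)L.out_ch, nvox * n);
  fmat cols;
  const int zt = net.slab_thickness(ext, L.in_ch);
  if (train) L.col_cache.clear();
  for (int v = 0; v < n; ++v) {
    for (int z0 = 0; z0 < ext; z0 += zt) {
      const int th = std::min(zt, ext - z0);
      { Tic t("im2col"); im2col_slab(X, ext, L.in_ch, v, z0, th, cols); }
      const size_t c0 = (size_t)v * nvox + (size_t)z0 * ext * ext;
      { Tic t("conv_gemm");
        Z.cols(c0, c0 + (size_t)th * ext * ext - 1) = L.W * cols; }
      if (train) { L.col_cache.push_back(std::move(cols)); cols.reset(); }
    }
  }
  Tic tbn("bn_fwd");
  const int ch = L.out_ch;
  const size_t m = Z.n_cols;
  if (train) {
    // one pass for per-channel sums, one fused pass for xhat + relu output
    std::vector<double> s(ch, 0.0), ss(ch, 0.0);
    const float* z = Z.memptr();
    for (size_t j = 0; j < m; ++j) {
      const float* col = z + j * ch;
      for (int c = 0; c < ch; ++c) {
        s[c] += col[c];
        ss[c] += (double)col[c] * col[c];
      }
    }
    fvec mu(ch), var(ch);
    for (int c = 0; c < ch; ++c) {
      mu[c] = (float)(s[c] / (double)m);
      var[c] = (float)(ss[c] / (double)m - (double)mu[c] * mu[c]);
      if (var[c] < 0.0f) var[c] = 0.0f;
    }
    L.rmean = net.bn_mom * L.rmean + (1.0f - net.bn_mom) * mu;
    L.rvar  = net.bn_mom * L.rvar  + (1.0f - net.bn_mom) * var;
    L.invstd = 1.0f / arma::sqrt(var + net.bn_eps);
    fmat out((uword)ch, m);
    {
      float* zp = Z.memptr();
      float* op = out.memptr();
      const float* muv = mu.memptr();
      const float* iv = L.invstd.memptr();
      const float* ga = L.gamma.memptr();
      const float* be = L.beta.memptr();
      for (size_t j = 0; j < m; ++j) {
        float* zc = zp + j * ch;
        float* oc = op + j * ch;
        for (int c = 0; c < ch; ++c) {
          const float xh = (zc[c] - muv[c]) * iv[c];
          zc[c] = xh; // Z becomes xhat in place
          const float y = ga[c] * xh + be[c];
          oc[c] = y > 0.0f ? y : 0.0f;
        }
      }
    }
    L.xhat = std::move(Z);
    L.out = out;
    return out;
  } else {
    fvec scale = L.gamma / arma::sqrt(L.rvar + net.bn_eps);
    fvec shift = L.beta - L.rmean % scale;
    float* zp = Z.memptr();
    const float* sc = scale.memptr();
    const float* sh = shift.memptr();
    for (size_t j = 0; j < m; ++j) {
      float* zc = zp + j * ch;
      for (int c = 0; c < ch; ++c) {
        const float y = sc[c] * zc[c] + sh[c];
        zc[c] = y > 0.0f ? y : 0.0f;
      }
    }
    return Z;
  }
}

static void adam_update(Adam& st, fmat& W, const fmat& g, float lr, long t,
                        float b1, float b2, float eps) {
  st.m = b1 * st.m + (1.0f - b1) * g;
  st.v = b2 * st.v + (1.0f - b2) * (g % g);
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  W -= lr * (st.m / c1) / (arma::sqrt(st.v / c2) + eps);
}

static void adam_update_vec(Adam& st, fvec& w, const fvec& g, float lr, long t,
                            float b1, float b2, float eps) {
  fmat W(w.memptr(), w.n_elem, 1, false, true);
  fmat G(const_cast<float*>(g.memptr()), g.n_elem, 1, false, true);
  adam_update(st, W, G, lr, t, b1, b2, eps);
}

static void adam_update_row(Adam& st, frowvec& w, const frowvec& g, float lr,
                            long t, float b1, float b2, float eps) {
  fmat W(w.memptr(), 1, w.n_elem, false, true);
  fmat G(const_cast<float*>(g.memptr()), 1, g.n_elem, false, true);
  adam_update(st, W, G, lr, t, b1, b2, eps);
}

// backward through ReLU+BN+conv; dOut (out_ch x cols) consumed, returns dX
// (empty when need_dx is false, e.g. for the input layer).
static fmat conv_backward(CNN3D& net, int li, int ext, int n,
                          fmat& dOut, float lr, bool need_dx,
                          List* grad_out = nullptr) {
  ConvLayer& L = net.convs[li];
  const size_t nvox = (size_t)ext * ext * ext;
  // fused ReLU + BN backward: dOut is turned into the pre-BN gradient dZ
  Tic tbn("bn_bwd");
  const int ch = L.out_ch;
  const size_t m = dOut.n_cols;
  fvec dgamma(ch), dbeta(ch);
  {
    float* g = dOut.memptr();
    const float* o = L.out.memptr();
    const float* xh = L.xhat.memptr();
    std::vector<double> sg(ch, 0.0), sb(ch, 0.0);
    for (size_t j = 0; j < m; ++j) {
      float* gc = g + j * ch;
      const float* oc = o + j * ch;
      const float* xc = xh + j * ch;
      for (int c = 0; c < ch; ++c) {
        if (oc[c] <= 0.0f) gc[c] = 0.0f;
        sg[c] += (double)gc[c] * xc[c];
        sb[c] += gc[c];
      }
    }
    // sum(dxhat) = gamma * sum(dOut); sum(dxhat * xhat) = gamma * dgamma
    fvec mu1(ch), mu2(ch);
    for (int c = 0; c < ch; ++c) {
      dgamma[c] = (float)sg[c];
      dbeta[c] = (float)sb[c];
      mu1[c] = L.gamma[c] * dbeta[c] / (float)m;
      mu2[c] = L.gamma[c] * dgamma[c] / (float)m;
    }
    const float* ga = L.gamma.memptr();
    const float* iv = L.invstd.memptr();
    const float* m1 = mu1.memptr();
    const float* m2 = mu2.memptr();
    for (size_t j = 0; j < m; ++j) {
      float* gc = g + j * ch;
      const float* xc = xh + j * ch;
      for (int c = 0; c < ch; ++c)
        gc[c] = iv[c] * (ga[c] * gc[c] - m1[c] - xc[c] * m2[c]);
    }
  }
  fmat& dZ = dOut;
  // conv
  fmat dW(arma::size(L.W), arma::fill::zeros);
  fmat dX;
  if (need_dx) dX.zeros((uword)L.in_ch, nvox * n);
  const int zt = net.slab_thickness(ext, L.in_ch);
  size_t blk = 0;
  for (int v = 0; v < n; ++v) {
    for (int z0 = 0; z0 < ext; z0 += zt) {
      const int th = std::min(zt, ext - z0);
      const fmat& cols = L.col_cache[blk++];
      const size_t c0 = (size_t)v * nvox + (size_t)z0 * ext * ext;
      // alias into dZ (contiguous column block): no copy
      const fmat dZs(const_cast<float*>(dZ.colptr(c0)), dZ.n_rows,
                     (size_t)th * ext * ext, false, true);
      { Tic t("dw_gemm"); dW += dZs * cols.t(); }
      if (need_dx) {
        fmat dcols;
        { Tic t("dcols_gemm"); dcols = L.W.t() * dZs; }
        { Tic t("col2im"); col2im_slab(dcols, ext, L.in_ch, v, z0, th, dX); }
      }
    }
  }
  if (!grad_out) {
    adam_update(L.aW, L.W, dW, lr, net.t, net.b1, net.b2, net.a_eps);
    adam_update_vec(L.ag, L.gamma, dgamma, lr, net.t, net.b1, net.b2,
                    net.a_eps);
    adam_update_vec(L.ab, L.beta, dbeta, lr, net.t, net.b1, net.b2,
                    net.a_eps);
  } else {
    List g = List::create(
      _["W"] = wrap(arma::conv_to<arma::mat>::from(dW)),
      _["gamma"] = wrap(arma::conv_to<arma::vec>::from(dgamma)),
      _["beta"] = wrap(arma::conv_to<arma::vec>::from(dbeta)));
    List convs = (*grad_out)["convs"];
    convs[li] = g;
    (*grad_out)["convs"] = convs;
  }
  L.xhat.reset(); L.out.reset(); L.col_cache.clear();
  return dX;
}

// max pooling, kernel 2 stride 2. X: (ch x nvox*n) at extent ext.
static fmat pool_forward(const fmat& X, int ext, int n, arma::umat& argmax) {
  const int oe = ext / 2;
  const size_t nvox = (size_t)ext * ext * ext;
  const size_t onvox = (size_t)oe * oe * oe;
  const int ch = X.n_rows;
  fmat Y((uword)ch, onvox * n);
  argmax.set_size((uword)ch, onvox * n);
  const int e2 = ext * ext;
  for (int v = 0; v < n; ++v) {
    for (int oz = 0; oz < oe; ++oz)
      for (int oy = 0; oy < oe; ++oy)
        for (int ox = 0; ox < oe; ++ox) {
          const size_t oc = (size_t)v * onvox + (size_t)oz * oe * oe +
                            (size_t)oy * oe + ox;
          for (int c = 0; c < ch; ++c) {
            float best = -std::numeric_limits<float>::infinity();
            size_t bi = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const size_t ic = (size_t)v * nvox +
                    (size_t)(2 * oz + dz) * e2 + (size_t)(2 * oy + dy) * ext +
                    (2 * ox + dx);
                  const float val = X((uword)c, ic);
                  if (val > best) { best = val; bi = ic; }
                }
            Y((uword)c, oc) = best;
            argmax((uword)c, oc) = bi;
          }
        }
  }
  return Y;
}

static fmat pool_backward(const fmat& dY, const arma::umat& argmax,
                          size_t in_cols) {
  fmat dX(dY.n_rows, in_cols, arma::fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (uword c = 0; c < dY.n_rows; ++c)
      dX(c, argmax(c, j)) += dY(c, j);
  return dX;
}

static inline float sigmoid_stable(float z) {
  if (z >= 0.0f) return 1.0f / (1.0f + std::exp(-z));
  const float e = std::exp(z);
  return e / (1.0f + e);
}

// ---- whole-network passes ---------------------------------------------------

// forward in eval mode; fills Y (n x tasks); optionally embeddings (n x fc2)
// and a shape trace of the conv groups.
static void eval_forward(CNN3D& net, const fmat& X0, int n, fmat& Y,
                         fmat* emb, IntegerVector* trace_ext,
                         IntegerVector* trace_ch, int* flat_len) {
  fmat A = X0;
  int ext = net.extent, li = 0;
  for (size_t g = 0; g < net.channels.size(); ++g) {
    fmat a1, a2;
    for (int l = 0; l < net.nlayers[g]; ++l) {
      if (net.nlayers[g] == 3 && l == 2) A = a1 + a2; // residual aggregation
      A = conv_forward(net, li, A, ext, n, false);
      if (l == 0) a1 = A;
      if (l == 1) a2 = A;
      ++li;
    }
    arma::umat am;
    { Tic t("pool_f"); A = pool_forward(A, ext, n, am); }
    ext /= 2;
    if (trace_ext) (*trace_ext)[g] = ext;
    if (trace_ch) (*trace_ch)[g] = net.channels[g];
  }
  const size_t onvox = (size_t)ext * ext * ext;
  const int flat = (int)(onvox * net.channels.back());
  if (flat_len) *flat_len = flat;
  fmat H0((uword)n, (uword)flat);
  for (int v = 0; v < n; ++v)
    H0.row(v) = arma::vectorise(A.cols((uword)v * onvox,
                                       (uword)(v + 1) * onvox - 1)).t();
  fmat H1 = arma::tanh(H0 * net.fc1.W + arma::repmat(net.fc1.b, n, 1));
  fmat H2 = arma::tanh(H1 * net.fc2.W + arma::repmat(net.fc2.b, n, 1));
  if (emb) *emb = H2;
  fmat Zo = H2 * net.Wo + arma::repmat(net.bo, n, 1);
  Y = Zo;
  Y.transform([&](float z) { return sigmoid_stable(net.eta * z); });
}

// one training step on a mini-batch; returns batch loss. When grad_out is
// non-null, no parameter is updated and all gradients are collected instead
// (used by the finite-difference checks).
static float train_step(CNN3D& net, const fmat& X0, const fmat& T, int n,
                        float lr, List* grad_out = nullptr) {
  std::vector<fmat> acts;
  std::vector<Rec> tape;
  acts.push_back(X0);
  int ext = net.extent, li = 0, cur = 0;
  for (size_t g = 0; g < net.channels.size(); ++g) {
    int a1 = -1, a2 = -1;
    for (int l = 0; l < net.nlayers[g]; ++l) {
      if (net.nlayers[g] == 3 && l == 2) {
        acts.push_back(acts[a1] + acts[a2]);
        Rec r; r.type = 2; r.layer = -1; r.ext = ext;
        r.in = a1; r.in2 = a2; r.out = (int)acts.size() - 1;
        tape.push_back(r);
        cur = r.out;
      }
      acts.push_back(conv_forward(net, li, acts[cur], ext, n, true));
      Rec r; r.type = 0; r.layer = li; r.ext = ext;
      r.in = cur; r.in2 = -1; r.out = (int)acts.size() - 1;
      tape.push_back(r);
      cur = r.out;
      if (l == 0) a1 = cur;
      if (l == 1) a2 = cur;
      ++li;
    }
    arma::umat am;
    { Tic t("pool_f"); acts.push_back(pool_forward(acts[cur], ext, n, am)); }
    Rec r; r.type = 1; r.layer = -1; r.ext = ext;
    r.in = cur; r.in2 = -1; r.out = (int)acts.size() - 1;
    r.argmax = std::move(am);
    tape.push_back(r);
    cur = r.out;
    ext /= 2;
  }
  const size_t onvox = (size_t)ext * ext * ext;
  const int flat = (int)(onvox * net.channels.back());
  fmat H0((uword)n, (uword)flat);
  for (int v = 0; v < n; ++v)
    H0.row(v) = arma::vectorise(acts[cur].cols((uword)v * onvox,
                                               (uword)(v + 1) * onvox - 1)).t();
  fmat Z1 = H0 * net.fc1.W + arma::repmat(net.fc1.b, n, 1);
  fmat H1 = arma::tanh(Z1);
  fmat Z2 = H1 * net.fc2.W + arma::repmat(net.fc2.b, n, 1);
  fmat H2 = arma::tanh(Z2);
  fmat Zo = H2 * net.Wo + arma::repmat(net.bo, n, 1);
  fmat Y = Zo;
  Y.transform([&](float z) { return sigmoid_stable(net.eta * z); });

  fmat diff = Y - T;
  const float loss = arma::accu(diff % diff) / (float)(n * net.n_tasks);
  if (!std::isfinite(loss)) Rcpp::stop("training diverged: non-finite loss");

  if (!grad_out) net.t += 1;
  const float lrf = lr;
  fmat dY = (2.0f / (float)(n * net.n_tasks)) * diff;
  fmat sig = Y % (1.0f - Y);
  fmat dZo = dY % sig * net.eta;
  // trainable sharpness
  float deta = arma::accu(dY % sig % Zo);
  if (!grad_out) {
    fvec w(1), g(1); w[0] = net.eta; g[0] = deta;
    fmat W(w.memptr(), 1, 1, false, true), G(g.memptr(), 1, 1, false, true);
    Adam st; st.m.set_size(1, 1); st.v.set_size(1, 1);
    st.m(0, 0) = net.eta_m; st.v(0, 0) = net.eta_v;
    adam_update(st, W, G, lrf, net.t, net.b1, net.b2, net.a_eps);
    net.eta = w[0]; net.eta_m = st.m(0, 0); net.eta_v = st.v(0, 0);
  } else (*grad_out)["eta"] = (double)deta;
  fmat dWo = H2.t() * dZo;
  frowvec dbo = arma::sum(dZo, 0);
  fmat dH2 = dZo * net.Wo.t();
  if (!grad_out) {
    adam_update(net.aWo, net.Wo, dWo, lrf, net.t, net.b1, net.b2, net.a_eps);
    adam_update_row(net.abo, net.bo, dbo, lrf, net.t, net.b1, net.b2,
                    net.a_eps);
  } else {
    (*grad_out)["Wo"] = wrap(arma::conv_to<arma::mat>::from(dWo));
    (*grad_out)["bo"] = wrap(arma::conv_to<arma::rowvec>::from(dbo));
  }

  fmat dZ2 = dH2 % (1.0f - H2 % H2);
  fmat dW2 = H1.t() * dZ2;
  frowvec db2 = arma::sum(dZ2, 0);
  fmat dH1 = dZ2 * net.fc2.W.t();
  if (!grad_out) {
    adam_update(net.fc2.aW, net.fc2.W, dW2, lrf, net.t, net.b1, net.b2,
                net.a_eps);
    adam_update_row(net.fc2.ab, net.fc2.b, db2, lrf, net.t, net.b1, net.b2,
                    net.a_eps);
  } else {
    (*grad_out)["W2"] = wrap(arma::conv_to<arma::mat>::from(dW2));
    (*grad_out)["b2"] = wrap(arma::conv_to<arma::rowvec>::from(db2));
  }

  fmat dZ1 = dH1 % (1.0f - H1 % H1);
  fmat dW1 = H0.t() * dZ1;
  frowvec db1 = arma::sum(dZ1, 0);
  fmat dH0 = dZ1 * net.fc1.W.t();
  if (!grad_out) {
    adam_update(net.fc1.aW, net.fc1.W, dW1, lrf, net.t, net.b1, net.b2,
                net.a_eps);
    adam_update_row(net.fc1.ab, net.fc1.b, db1, lrf, net.t, net.b1, net.b2,
                    net.a_eps);
  } else {
    (*grad_out)["W1"] = wrap(arma::conv_to<arma::mat>::from(dW1));
    (*grad_out)["b1"] = wrap(arma::conv_to<arma::rowvec>::from(db1));
  }

  // unflatten
  std::vector<fmat> grads(acts.size());
  fmat dA((uword)net.channels.back(), onvox * n);
  for (int v = 0; v < n; ++v) {
    fvec row = dH0.row(v).t();
    dA.cols((uword)v * onvox, (uword)(v + 1) * onvox - 1) =
      arma::reshape(fmat(row), (uword)net.channels.back(), onvox);
  }
  grads[cur] = std::move(dA);

  for (int i = (int)tape.size() - 1; i >= 0; --i) {
    Rec& r = tape[i];
    fmat& g = grads[r.out];
    if (g.n_elem == 0) continue;
    if (r.type == 1) { // pool
      const size_t in_cols = acts[r.in].n_cols;
      Tic t("pool_b");
      fmat dX = pool_backward(g, r.argmax, in_cols);
      if (grads[r.in].n_elem == 0) grads[r.in] = std::move(dX);
      else grads[r.in] += dX;
    } else if (r.type == 2) { // add
      if (grads[r.in].n_elem == 0) grads[r.in] = g; else grads[r.in] += g;
      if (grads[r.in2].n_elem == 0) grads[r.in2] = g; else grads[r.in2] += g;
    } else { // conv
      const bool need_dx = r.in != 0; // input volume gradient is unused
      fmat dX = conv_backward(net, r.layer, r.ext, n, g, lrf, need_dx,
                              grad_out);
      if (need_dx) {
        if (grads[r.in].n_elem == 0) grads[r.in] = std::move(dX);
        else grads[r.in] += dX;
      }
    }
    grads[r.out].reset();
    acts[r.out].reset();
  }
  return loss;
}

// ---- R interface ------------------------------------------------------------

static fmat batch_to_fmat(const NumericMatrix& X, const std::vector<int>& idx) {
  // X: nvox x n (doubles); returns (1 x nvox*nb) input activation
  const size_t nvox = X.nrow();
  fmat A(1, nvox * idx.size());
  for (size_t v = 0; v < idx.size(); ++v) {
    const double* src = X.begin() + (size_t)idx[v] * nvox;
    float* dst = A.memptr() + v * nvox;
    for (size_t i = 0; i < nvox; ++i) dst[i] = (float)src[i];
  }
  return A;
}

// Loss and all parameter gradients on one batch, without updating anything.
// [[Rcpp::export]]
List cnn_loss_grad(SEXP ptr, NumericMatrix X, NumericMatrix Y) {
  XPtr<CNN3D> net(ptr);
  const size_t nvox = (size_t)net->extent * net->extent * net->extent;
  if ((size_t)X.nrow() != nvox)
    stop("volume voxel count does not match model input extent");
  const int n = X.ncol();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  fmat A = batch_to_fmat(X, idx);
  fmat T((uword)n, (uword)net->n_tasks);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < net->n_tasks; ++k) T(i, k) = (float)Y(i, k);
  List grads = List::create(_["convs"] = List((int)net->convs.size()));
  const float loss = train_step(*net, A, T, n, 0.0f, &grads);
  grads["loss"] = (double)loss;
  return grads;
}

// Raw zero-padded 3x3x3 convolution of one multi-channel volume (no BN, no
// activation): X is (in_ch x nvox) channel-major, W is (out_ch x in_ch*27)
// with column k*in_ch+ic for tap k; used by tests as an oracle entry point.
// [[Rcpp::export]]
NumericMatrix cnn_conv_once(NumericMatrix X, int ext, NumericMatrix W) {
  const int in_ch = X.nrow();
  const size_t nvox = (size_t)ext * ext * ext;
  if ((size_t)X.ncol() != nvox) stop("X must be in_ch x ext^3");
  if (W.ncol() != in_ch * K3) stop("W must be out_ch x in_ch*27");
  fmat A((uword)in_ch, nvox);
  for (size_t j = 0; j < nvox; ++j)
    for (int i = 0; i < in_ch; ++i) A(i, j) = (float)X(i, j);
  fmat Wf((uword)W.nrow(), (uword)W.ncol());
  for (int j = 0; j < W.ncol(); ++j)
    for (int i = 0; i < W.nrow(); ++i) Wf(i, j) = (float)W(i, j);
  fmat cols;
  fmat Z((uword)W.nrow(), nvox);
  const int zt = ext; // single volume, no slabbing needed at test sizes
  im2col_slab(A, ext, in_ch, 0, 0, zt, cols);
  Z = Wf * cols;
  NumericMatrix out(W.nrow(), (int)nvox);
  for (size_t j = 0; j < nvox; ++j)
    for (int i = 0; i < W.nrow(); ++i) out(i, j) = (double)Z(i, j);
  return out;
}

// [[Rcpp::export]]
List cnn_perf() {
  List out;
  for (auto& kv : g_perf) out[kv.first] = kv.second;
  g_perf.clear();
  return out;
}

// [[Rcpp::export]]
SEXP cnn_create(int extent, IntegerVector channels, IntegerVector layers,
                IntegerVector fc_widths, int n_tasks) {
  if (channels.size() != layers.size())
    stop("channels and layers must have equal length");
  int pools = channels.size();
  int div = 1 << pools;
  if (extent % div != 0)
    stop("input extent must be divisible by 2^%d", pools);
  std::vector<int> ch(channels.begin(), channels.end());
  std::vector<int> nl(layers.begin(), layers.end());
  std::vector<int> fc(fc_widths.begin(), fc_widths.end());
  XPtr<CNN3D> p(new CNN3D(extent, ch, nl, fc, n_tasks), true);
  return p;
}

// [[Rcpp::export]]
List cnn_get_params(SEXP ptr) {
  XPtr<CNN3D> net(ptr);
  List convs(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    ConvLayer& L = net->convs[i];
    convs[i] = List::create(
      _["W"] = wrap(arma::conv_to<arma::mat>::from(L.W)),
      _["gamma"] = wrap(arma::conv_to<arma::vec>::from(L.gamma)),
      _["beta"] = wrap(arma::conv_to<arma::vec>::from(L.beta)),
      _["rmean"] = wrap(arma::conv_to<arma::vec>::from(L.rmean)),
      _["rvar"] = wrap(arma::conv_to<arma::vec>::from(L.rvar)));
  }
  return List::create(
    _["convs"] = convs,
    _["W1"] = wrap(arma::conv_to<arma::mat>::from(net->fc1.W)),
    _["b1"] = wrap(arma::conv_to<arma::rowvec>::from(net->fc1.b)),
    _["W2"] = wrap(arma::conv_to<arma::mat>::from(net->fc2.W)),
    _["b2"] = wrap(arma::conv_to<arma::rowvec>::from(net->fc2.b)),
    _["Wo"] = wrap(arma::conv_to<arma::mat>::from(net->Wo)),
    _["bo"] = wrap(arma::conv_to<arma::rowvec>::from(net->bo)),
    _["eta"] = (double)net->eta);
}

// [[Rcpp::export]]
void cnn_set_params(SEXP ptr, List params) {
  XPtr<CNN3D> net(ptr);
  List convs = params["convs"];
  if ((size_t)convs.size() != net->convs.size())
    stop("parameter list does not match architecture");
  for (size_t i = 0; i < net->convs.size(); ++i) {
    List li = convs[i];
    ConvLayer& L = net->convs[i];
    arma::mat W = li["W"];
    if (W.n_rows != L.W.n_rows || W.n_cols != L.W.n_cols)
      stop("conv weight shape mismatch at layer %d", (int)i + 1);
    L.W = arma::conv_to<fmat>::from(W);
    L.gamma = arma::conv_to<fvec>::from(as<arma::vec>(li["gamma"]));
    L.beta  = arma::conv_to<fvec>::from(as<arma::vec>(li["beta"]));
    L.rmean = arma::conv_to<fvec>::from(as<arma::vec>(li["rmean"]));
    L.rvar  = arma::conv_to<fvec>::from(as<arma::vec>(li["rvar"]));
    L.aW.init(L.W.n_rows, L.W.n_cols);
    L.ag.init(L.out_ch, 1); L.ab.init(L.out_ch, 1);
  }
  net->fc1.W = arma::conv_to<fmat>::from(as<arma::mat>(params["W1"]));
  net->fc1.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(params["b1"]));
  net->fc2.W = arma::conv_to<fmat>::from(as<arma::mat>(params["W2"]));
  net->fc2.b = arma::conv_to<frowvec>::from(as<arma::rowvec>(params["b2"]));
  net->Wo = arma::conv_to<fmat>::from(as<arma::mat>(params["Wo"]));
  net->bo = arma::conv_to<frowvec>::from(as<arma::rowvec>(params["bo"]));
  net->eta = (float)as<double>(params["eta"]);
  net->fc1.aW.init(net->fc1.W.n_rows, net->fc1.W.n_cols);
  net->fc1.ab.init(1, net->fc1.b.n_elem);
  net->fc2.aW.init(net->fc2.W.n_rows, net->fc2.W.n_cols);
  net->fc2.ab.init(1, net->fc2.b.n_elem);
  net->aWo.init(net->Wo.n_rows, net->Wo.n_cols);
  net->abo.init(1, net->bo.n_elem);
  net->eta_m = 0.0f; net->eta_v = 0.0f;
  net->t = 0;
}

// [[Rcpp::export]]
int cnn_n_conv_layers(SEXP ptr) {
  XPtr<CNN3D> net(ptr);
  return (int)net->convs.size();
}

// [[Rcpp::export]]
List cnn_config(SEXP ptr) {
  XPtr<CNN3D> net(ptr);
  return List::create(_["extent"] = net->extent,
                      _["channels"] = wrap(net->channels),
                      _["layers"] = wrap(net->nlayers),
                      _["fc_widths"] = wrap(net->fc_widths),
                      _["n_tasks"] = net->n_tasks);
}

// [[Rcpp::export]]
NumericMatrix cnn_forward(SEXP ptr, NumericMatrix X, int batch_size = 8) {
  XPtr<CNN3D> net(ptr);
  const size_t nvox = (size_t)net->extent * net->extent * net->extent;
  if ((size_t)X.nrow() != nvox)
    stop("volume voxel count does not match model input extent");
  const int n = X.ncol();
  NumericMatrix out(n, net->n_tasks);
  for (int s = 0; s < n; s += batch_size) {
    const int nb = std::min(batch_size, n - s);
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = s + i;
    fmat A = batch_to_fmat(X, idx);
    fmat Y;
    eval_forward(*net, A, nb, Y, nullptr, nullptr, nullptr, nullptr);
    for (int i = 0; i < nb; ++i)
      for (int k = 0; k < net->n_tasks; ++k)
        out(s + i, k) = (double)Y((uword)i, (uword)k);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cnn_embed(SEXP ptr, NumericMatrix X, int batch_size = 8) {
  XPtr<CNN3D> net(ptr);
  const size_t nvox = (size_t)net->extent * net->extent * net->extent;
  if ((size_t)X.nrow() != nvox)
    stop("volume voxel count does not match model input extent");
  const int n = X.ncol();
  const int width = net->fc_widths[1];
  NumericMatrix out(n, width);
  for (int s = 0; s < n; s += batch_size) {
    const int nb = std::min(batch_size, n - s);
    std::vector<int> idx(nb);
    for (int i = 0; i < nb; ++i) idx[i] = s + i;
    fmat A = batch_to_fmat(X, idx);
    fmat Y, E;
    eval_forward(*net, A, nb, Y, &E, nullptr, nullptr, nullptr);
    for (int i = 0; i < nb; ++i)
      for (int k = 0; k < width; ++k)
        out(s + i, k) = (double)E((uword)i, (uword)k);
  }
  return out;
}

// [[Rcpp::export]]
List cnn_trace(SEXP ptr, NumericMatrix X) {
  XPtr<CNN3D> net(ptr);
  const size_t nvox = (size_t)net->extent * net->extent * net->extent;
  if ((size_t)X.nrow() != nvox)
    stop("volume voxel count does not match model input extent");
  std::vector<int> idx(1, 0);
  fmat A = batch_to_fmat(X, idx);
  fmat Y;
  IntegerVector ext((int)net->channels.size()), ch((int)net->channels.size());
  int flat = 0;
  eval_forward(*net, A, 1, Y, nullptr, &ext, &ch, &flat);
  NumericVector pred(net->n_tasks);
  for (int k = 0; k < net->n_tasks; ++k) pred[k] = (double)Y(0, (uword)k);
  return List::create(_["group_extent"] = ext, _["group_channels"] = ch,
                      _["flatten_length"] = flat, _["prediction"] = pred);
}

// [[Rcpp::export]]
double cnn_train_epoch(SEXP ptr, NumericMatrix X, NumericMatrix Y,
                       IntegerVector order, int batch_size, double lr) {
  XPtr<CNN3D> net(ptr);
  const size_t nvox = (size_t)net->extent * net->extent * net->extent;
  if ((size_t)X.nrow() != nvox)
    stop("volume voxel count does not match model input extent");
  if (Y.nrow() != X.ncol() || Y.ncol() != net->n_tasks)
    stop("target matrix must be n_volumes x n_tasks");
  const int n = order.size();
  double tot = 0.0; int nb_tot = 0;
  for (int s = 0; s < n; s += batch_size) {
    const int nb = std::min(batch_size, n - s);
    std::vector<int> idx(nb);
    fmat T((uword)nb, (uword)net->n_tasks);
    for (int i = 0; i < nb; ++i) {
      idx[i] = order[s + i] - 1;
      for (int k = 0; k < net->n_tasks; ++k)
        T((uword)i, (uword)k) = (float)Y(idx[i], k);
    }
    fmat A = batch_to_fmat(X, idx);
    tot += (double)train_step(*net, A, T, nb, (float)lr) * nb;
    nb_tot += nb;
    Rcpp::checkUserInterrupt();
  }
  return tot / nb_tot;
}

// [[Rcpp::export]]
NumericVector cnn_eval_mse(SEXP ptr, NumericMatrix X, NumericMatrix Y,
                           int batch_size = 8) {
  XPtr<CNN3D> net(ptr);
  NumericMatrix P = cnn_forward(ptr, X, batch_size);
  const int n = X.ncol(), k = net->n_tasks;
  NumericVector mse(k);
  for (int j = 0; j < k; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      const double d = P(i, j) - Y(i, j);
      s += d * d;
    }
    mse[j] = s / n;
  }
  return mse;
}
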