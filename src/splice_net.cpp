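// Grouped dilated residual network engine.
//
// Activations are held positions-first: a feature map is an (N x C) float
// matrix where N = L * B (all positions of all windows in the batch,
// window-major) and C is the channel count.  This makes batch-norm and the
// 1x1 convolutions contiguous column operations and lets the grouped dilated
// convolutions run as im2col + sgemm with contiguous copies.  Convolutions
// never read across window boundaries: the im2col fill zero-pads each window
// independently (symmetric padding D*(W-1)/2 per side, so length is
// preserved).
//
// Parameters live in one flat vector whose layout must match the R-side
// param_layout():
//   stem (Cin x F) w + b, skip0 (F x F) w + b,
//   for each residual group g:
//     for each unit u:
//       bn1 gamma, bn1 beta, conv1 (cpg*Wg x F) w + b,
//       bn2 gamma, bn2 beta, conv2 w + b
//     group-out 1x1 (F x F) w + b
//   penultimate 1x1 (F x F) w + b, output (F x Cout) w + b.
// Conv weight column oc holds the taps of output channel oc, row index
// ic_within_group * W + t.  Batch-norm running stats are a separate vector:
// per unit [mean1, var1, mean2, var2], each of length F.

#include <RcppArmadillo.h>
#include <cstring>
#include <array>
#include <malloc.h>
using namespace Rcpp;
using namespace arma;

namespace {

// the engine repeatedly allocates/frees multi-MB activation buffers; keep
// them on the heap (rather than per-allocation mmap) so pages stay warm
// across batches
const bool heap_tuned = []() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
  return true;
}();

struct Cfg {
  int F, G, upg, ng, Cin, Cout;
  std::vector<int> W, D;
  float slope, eps, mom;
};

Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.F    = as<int>(cfg["filters"]);
  c.G    = as<int>(cfg["groups"]);
  c.upg  = as<int>(cfg["units_per_group"]);
  c.ng   = as<int>(cfg["n_groups"]);
  c.Cin  = as<int>(cfg["in_channels"]);
  c.Cout = as<int>(cfg["out_channels"]);
  c.W    = as<std::vector<int>>(cfg["window_sizes"]);
  c.D    = as<std::vector<int>>(cfg["dilations"]);
  c.slope = (float)as<double>(cfg["lrelu_slope"]);
  c.eps   = (float)as<double>(cfg["bn_eps"]);
  c.mom   = (float)as<double>(cfg["bn_momentum"]);
  if ((int)c.W.size() != c.ng || (int)c.D.size() != c.ng)
    stop("window_sizes/dilations must have one entry per residual group");
  if (c.F % c.G != 0) stop("filters not divisible by groups");
  if (c.Cout != 3) stop("engine supports exactly 3 output channels");
  return c;
}

// offsets of every parameter block in the flat vector
struct Layout {
  size_t stem_w, stem_b, skip0_w, skip0_b;
  std::vector<std::array<size_t, 8>> unit;  // g1,b1,w1,cb1,g2,b2,w2,cb2
  std::vector<size_t> gout_w, gout_b;
  size_t penult_w, penult_b, out_w, out_b, total;
};

Layout layout_of(const Cfg& c) {
  Layout L;
  size_t o = 0;
  const int F = c.F, cpg = c.F / c.G;
  L.stem_w = o; o += (size_t)c.Cin * F;
  L.stem_b = o; o += F;
  L.skip0_w = o; o += (size_t)F * F;
  L.skip0_b = o; o += F;
  for (int g = 0; g < c.ng; ++g) {
    const size_t wsz = (size_t)cpg * c.W[g] * F;
    for (int u = 0; u < c.upg; ++u) {
      std::array<size_t, 8> a;
      a[0] = o; o += F;      // bn1 gamma
      a[1] = o; o += F;      // bn1 beta
      a[2] = o; o += wsz;    // conv1 w
      a[3] = o; o += F;      // conv1 b
      a[4] = o; o += F;      // bn2 gamma
      a[5] = o; o += F;      // bn2 beta
      a[6] = o; o += wsz;    // conv2 w
      a[7] = o; o += F;      // conv2 b
      L.unit.push_back(a);
    }
    L.gout_w.push_back(o); o += (size_t)F * F;
    L.gout_b.push_back(o); o += F;
  }
  L.penult_w = o; o += (size_t)F * F;
  L.penult_b = o; o += F;
  L.out_w = o; o += (size_t)F * c.Cout;
  L.out_b = o; o += c.Cout;
  L.total = o;
  return L;
}

// non-owning views into a float buffer (C++17 guaranteed elision keeps the
// returned object aliasing `b`)
inline fmat MV(float* b, size_t o, int r, int c) {
  return fmat(b + o, r, c, false, true);
}
inline fvec VV(float* b, size_t o, int n) {
  return fvec(b + o, n, false, true);
}

// ---- low-level ops ---------------------------------------------------------

// loop order (channel, window, tap) keeps the 4*L-byte source window in L1
// while its W shifted copies are written out
void im2col_pf(const fmat& A, int c0, int cpg, int W, int D, int L, int B,
               fmat& Col) {
  const int pad = D * (W - 1) / 2;
  for (int ic = 0; ic < cpg; ++ic) {
    const float* src = A.colptr(c0 + ic);
    for (int s = 0; s < B; ++s) {
      const float* sp = src + (size_t)s * L;
      for (int t = 0; t < W; ++t) {
        const int o = t * D - pad;
        float* dp = Col.colptr((size_t)ic * W + t) + (size_t)s * L;
        if (o >= 0) {
          const int n = L - o;
          std::memcpy(dp, sp + o, (size_t)n * sizeof(float));
          if (o) std::memset(dp + n, 0, (size_t)o * sizeof(float));
        } else {
          const int n = L + o;
          std::memset(dp, 0, (size_t)(-o) * sizeof(float));
          std::memcpy(dp - o, sp, (size_t)n * sizeof(float));
        }
      }
    }
  }
}

void col2im_pf(const fmat& dCol, int c0, int cpg, int W, int D, int L, int B,
               fmat& dA) {
  const int pad = D * (W - 1) / 2;
  for (int ic = 0; ic < cpg; ++ic) {
    float* dst = dA.colptr(c0 + ic);
    for (int s = 0; s < B; ++s) {
      float* dp = dst + (size_t)s * L;
      for (int t = 0; t < W; ++t) {
        const int o = t * D - pad;
        const float* sp = dCol.colptr((size_t)ic * W + t) + (size_t)s * L;
        if (o >= 0) {
          const int n = L - o;
          for (int i = 0; i < n; ++i) dp[o + i] += sp[i];
        } else {
          const int n = L + o;
          for (int i = 0; i < n; ++i) dp[i] += sp[-o + i];
        }
      }
    }
  }
}

void gconv_fwd(const fmat& A, const fmat& Wt, const fvec& b, int G, int W,
               int D, int L, int B, fmat& Y, float* colmem) {
  const int cin = A.n_cols, cout = Y.n_cols;
  const int cpg_in = cin / G, cpg_out = cout / G;
  fmat Col(colmem, A.n_rows, (size_t)cpg_in * W, false, true);
  for (int g = 0; g < G; ++g) {
    im2col_pf(A, g * cpg_in, cpg_in, W, D, L, B, Col);
    Y.cols(g * cpg_out, (g + 1) * cpg_out - 1) =
        Col * Wt.cols(g * cpg_out, (g + 1) * cpg_out - 1);
  }
  for (int c = 0; c < cout; ++c) Y.col(c) += b[c];
}

void colsum_into(const fmat& X, fvec& out) {
  for (uword c = 0; c < X.n_cols; ++c) {
    const float* p = X.colptr(c);
    double acc = 0;
    for (uword i = 0; i < X.n_rows; ++i) acc += p[i];
    out[c] = (float)acc;
  }
}

void gconv_bwd(const fmat& A, const fmat& Wt, const fmat& dY, int G, int W,
               int D, int L, int B, fmat& dA, fmat dWt, fvec db, float* colmem,
               float* dcolmem) {
  const int cin = A.n_cols, cout = dY.n_cols;
  const int cpg_in = cin / G, cpg_out = cout / G;
  fmat Col(colmem, A.n_rows, (size_t)cpg_in * W, false, true);
  fmat dCol(dcolmem, A.n_rows, (size_t)cpg_in * W, false, true);
  dA.zeros();
  for (int g = 0; g < G; ++g) {
    im2col_pf(A, g * cpg_in, cpg_in, W, D, L, B, Col);
    const uword a = g * cpg_out, z = (g + 1) * cpg_out - 1;
    dWt.cols(a, z) = Col.t() * dY.cols(a, z);
    dCol = dY.cols(a, z) * Wt.cols(a, z).t();
    col2im_pf(dCol, g * cpg_in, cpg_in, W, D, L, B, dA);
  }
  colsum_into(dY, db);
}

void bn_batch_stats(const fmat& X, frowvec& mu, frowvec& var) {
  const uword N = X.n_rows, C = X.n_cols;
  mu.set_size(C); var.set_size(C);
  for (uword c = 0; c < C; ++c) {
    const float* p = X.colptr(c);
    double s = 0, s2 = 0;
    for (uword i = 0; i < N; ++i) {
      const double x = p[i];
      s += x; s2 += x * x;
    }
    const double m = s / N;
    mu[c] = (float)m;
    var[c] = (float)(std::max(s2 / N - m * m, 0.0));
  }
}

// fused batch-norm affine + leaky ReLU
void bn_lrelu(const fmat& X, const frowvec& mu, const frowvec& var,
              const fvec& gamma, const fvec& beta, float eps, float slope,
              fmat& A) {
  const uword N = X.n_rows, C = X.n_cols;
  for (uword c = 0; c < C; ++c) {
    const float sc = gamma[c] / std::sqrt(var[c] + eps);
    const float sh = beta[c] - mu[c] * sc;
    const float* x = X.colptr(c);
    float* a = A.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const float t = sc * x[i] + sh;
      a[i] = t > 0.f ? t : slope * t;
    }
  }
}

// backward through leaky ReLU (sign taken from its output) then batch norm
void bn_lrelu_bwd(const fmat& X, const fmat& act, const fmat& dPost,
                  const frowvec& mu, const frowvec& var, const fvec& gamma,
                  float eps, float slope, fmat& dX, fvec dgamma, fvec dbeta) {
  const uword N = X.n_rows, C = X.n_cols;
  for (uword c = 0; c < C; ++c) {
    const float inv = 1.0f / std::sqrt(var[c] + eps);
    const float m = mu[c];
    const float* x = X.colptr(c);
    const float* a = act.colptr(c);
    const float* dp = dPost.colptr(c);
    float* dx = dX.colptr(c);
    double sdy = 0, sdyx = 0;
    for (uword i = 0; i < N; ++i) {
      const float dy = a[i] > 0.f ? dp[i] : slope * dp[i];
      dx[i] = dy;  // stash dT
      const float xh = (x[i] - m) * inv;
      sdy += dy;
      sdyx += (double)dy * xh;
    }
    dgamma[c] = (float)sdyx;
    dbeta[c] = (float)sdy;
    const float mdy = (float)(sdy / N);
    const float mdyx = (float)(sdyx / N);
    const float g = gamma[c] * inv;
    for (uword i = 0; i < N; ++i) {
      const float xh = (x[i] - m) * inv;
      dx[i] = g * (dx[i] - mdy - xh * mdyx);
    }
  }
}

void add_bias(fmat& Y, const fvec& b) {
  for (uword c = 0; c < Y.n_cols; ++c) Y.col(c) += b[c];
}

fmat onehot(const IntegerMatrix& codes, int Cin) {
  const int L = codes.nrow(), B = codes.ncol();
  fmat X((size_t)L * B, Cin, fill::zeros);
  for (int s = 0; s < B; ++s)
    for (int i = 0; i < L; ++i) {
      const int code = codes(i, s);  // 0 = N, 1..4 = A,C,G,T
      if (code > 0 && code <= Cin) X((size_t)s * L + i, code - 1) = 1.0f;
    }
  return X;
}

struct ForwardState {
  std::vector<fmat> x_in;  // input of each unit, plus final x at the end
  std::vector<fmat> c1;    // first-conv output of each unit
  std::vector<fmat> a1, a2;  // leaky-ReLU outputs feeding each conv
  std::vector<frowvec> mu1, var1, mu2, var2;
  fmat x_stem, skip, h, P;
  double loss = 0;
};

// one forward pass; train_mode selects batch statistics (recorded into
// `running` when non-null) versus running statistics; when `positive` is
// given, the focal loss (and dZ when requested) is computed.  Label channel
// order: 0 = neither, 1 = acceptor, 2 = donor; donor label at in-window
// offset 200, acceptor at 600, for positive windows only.
void net_forward(float* parf, const Cfg& c, const Layout& lay, const fmat& X0,
                 int L, int B, bool train_mode, std::vector<float>* running,
                 const LogicalVector* positive, double gamma, double posw,
                 bool keep, ForwardState& st, fmat* dZ_out) {
  const size_t N = (size_t)L * B;
  const int F = c.F, cpg = c.F / c.G;
  const int maxW = *std::max_element(c.W.begin(), c.W.end());
  std::vector<float> colmem((size_t)N * cpg * maxW);
  const int n_units = c.ng * c.upg;
  if (keep) {
    st.x_in.reserve(n_units + 1);
    st.c1.reserve(n_units);
    st.a1.reserve(n_units); st.a2.reserve(n_units);
    st.mu1.reserve(n_units); st.var1.reserve(n_units);
    st.mu2.reserve(n_units); st.var2.reserve(n_units);
  }

  fmat x = X0 * MV(parf, lay.stem_w, c.Cin, F);
  add_bias(x, VV(parf, lay.stem_b, F));
  st.x_stem = x;
  st.skip = x * MV(parf, lay.skip0_w, F, F);
  add_bias(st.skip, VV(parf, lay.skip0_b, F));

  fmat a(N, F), cmat(N, F);
  int k = 0;
  for (int g = 0; g < c.ng; ++g) {
    const int W = c.W[g], D = c.D[g];
    for (int u = 0; u < c.upg; ++u, ++k) {
      const std::array<size_t, 8>& U = lay.unit[k];
      if (keep) st.x_in.push_back(x);
      frowvec mu1, var1, mu2, var2;
      float* rs = running ? running->data() + (size_t)k * 4 * F : nullptr;
      if (train_mode) {
        bn_batch_stats(x, mu1, var1);
        if (rs)
          for (int j = 0; j < F; ++j) {
            rs[j] = (1 - c.mom) * rs[j] + c.mom * mu1[j];
            rs[F + j] = (1 - c.mom) * rs[F + j] + c.mom * var1[j];
          }
      } else {
        mu1 = frowvec(rs, F);
        var1 = frowvec(rs + F, F);
      }
      bn_lrelu(x, mu1, var1, VV(parf, U[0], F), VV(parf, U[1], F), c.eps,
               c.slope, a);
      if (keep) st.a1.push_back(a);
      gconv_fwd(a, MV(parf, U[2], cpg * W, F), VV(parf, U[3], F), c.G, W, D, L,
                B, cmat, colmem.data());
      if (keep) st.c1.push_back(cmat);
      if (train_mode) {
        bn_batch_stats(cmat, mu2, var2);
        if (rs)
          for (int j = 0; j < F; ++j) {
            rs[2 * F + j] = (1 - c.mom) * rs[2 * F + j] + c.mom * mu2[j];
            rs[3 * F + j] = (1 - c.mom) * rs[3 * F + j] + c.mom * var2[j];
          }
      } else {
        mu2 = frowvec(rs + 2 * F, F);
        var2 = frowvec(rs + 3 * F, F);
      }
      bn_lrelu(cmat, mu2, var2, VV(parf, U[4], F), VV(parf, U[5], F), c.eps,
               c.slope, a);
      if (keep) st.a2.push_back(a);
      {
        fmat c2(N, F);
        gconv_fwd(a, MV(parf, U[6], cpg * W, F), VV(parf, U[7], F), c.G, W, D,
                  L, B, c2, colmem.data());
        x += c2;
      }
      if (keep) {
        st.mu1.push_back(mu1); st.var1.push_back(var1);
        st.mu2.push_back(mu2); st.var2.push_back(var2);
      }
    }
    {
      fmat contrib = x * MV(parf, lay.gout_w[g], F, F);
      add_bias(contrib, VV(parf, lay.gout_b[g], F));
      st.skip += contrib;
    }
  }
  if (keep) st.x_in.push_back(x);

  st.h = st.skip * MV(parf, lay.penult_w, F, F);
  add_bias(st.h, VV(parf, lay.penult_b, F));
  fmat z = st.h * MV(parf, lay.out_w, F, c.Cout);
  add_bias(z, VV(parf, lay.out_b, c.Cout));

  st.P.set_size(N, c.Cout);
  if (dZ_out) dZ_out->set_size(N, c.Cout);
  const float* z0 = z.colptr(0);
  const float* z1 = z.colptr(1);
  const float* z2 = z.colptr(2);
  float* p0 = st.P.colptr(0);
  float* p1 = st.P.colptr(1);
  float* p2 = st.P.colptr(2);
  for (size_t i = 0; i < N; ++i) {
    const float m = std::max(z0[i], std::max(z1[i], z2[i]));
    const float e0 = std::exp(z0[i] - m), e1 = std::exp(z1[i] - m),
                e2 = std::exp(z2[i] - m);
    const float s = e0 + e1 + e2;
    p0[i] = e0 / s; p1[i] = e1 / s; p2[i] = e2 / s;
  }
  if (positive) {
    float* d0 = dZ_out ? dZ_out->colptr(0) : nullptr;
    float* d1 = dZ_out ? dZ_out->colptr(1) : nullptr;
    float* d2 = dZ_out ? dZ_out->colptr(2) : nullptr;
    const double invN = 1.0 / (double)N;
    double loss = 0;
    for (int s = 0; s < B; ++s) {
      const bool pos = (*positive)[s];
      const double w = pos ? posw : 1.0;
      for (int l = 0; l < L; ++l) {
        const size_t i = (size_t)s * L + l;
        int t = 0;
        if (pos && l == 200) t = 2;
        else if (pos && l == 600) t = 1;
        const double pt =
            std::max((double)(t == 0 ? p0[i] : (t == 1 ? p1[i] : p2[i])), 1e-12);
        const double om = 1.0 - pt;
        loss += w * (-std::pow(om, gamma) * std::log(pt));
        if (dZ_out) {
          double dldp;
          if (gamma == 0.0) dldp = -1.0 / pt;
          else dldp = gamma * std::pow(om, gamma - 1.0) * std::log(pt) -
                      std::pow(om, gamma) / pt;
          const double cmn = w * invN * dldp * pt;
          d0[i] = (float)(cmn * ((t == 0 ? 1.0 : 0.0) - p0[i]));
          d1[i] = (float)(cmn * ((t == 1 ? 1.0 : 0.0) - p1[i]));
          d2[i] = (float)(cmn * ((t == 2 ? 1.0 : 0.0) - p2[i]));
        }
      }
    }
    st.loss = loss * invN;
  }
}

} // namespace

// [[Rcpp::export]]
double cpp_param_count(List cfg) {
  return (double)layout_of(read_cfg(cfg)).total;
}

// [[Rcpp::export]]
List cpp_net_train_batch(NumericVector par, NumericVector bnstats,
                         IntegerMatrix codes, LogicalVector positive,
                         double gamma, double pos_weight, List cfg) {
  const Cfg c = read_cfg(cfg);
  const Layout lay = layout_of(c);
  if ((size_t)par.size() != lay.total) stop("parameter vector has wrong length");
  if ((size_t)bnstats.size() != (size_t)c.ng * c.upg * 4 * c.F)
    stop("bnstats vector has wrong length");
  const int L = codes.nrow(), B = codes.ncol();
  if (B != positive.size()) stop("positive flag per window required");
  const size_t N = (size_t)L * B;
  const int F = c.F, cpg = c.F / c.G;

  std::vector<float> parf(lay.total);
  for (size_t i = 0; i < lay.total; ++i) parf[i] = (float)par[i];
  std::vector<float> running(bnstats.size());
  for (int i = 0; i < bnstats.size(); ++i) running[i] = (float)bnstats[i];

  fmat X0 = onehot(codes, c.Cin);
  ForwardState st;
  fmat dZ;
  net_forward(parf.data(), c, lay, X0, L, B, true, &running, &positive, gamma,
              pos_weight, true, st, &dZ);

  // ---- backward ----
  std::vector<float> gradf(lay.total, 0.0f);
  float* gp = gradf.data();
  float* pp = parf.data();

  MV(gp, lay.out_w, F, c.Cout) = st.h.t() * dZ;
  { fvec gb = VV(gp, lay.out_b, c.Cout); colsum_into(dZ, gb); }
  fmat dH = dZ * MV(pp, lay.out_w, F, c.Cout).t();
  MV(gp, lay.penult_w, F, F) = st.skip.t() * dH;
  { fvec gb = VV(gp, lay.penult_b, F); colsum_into(dH, gb); }
  fmat dSkip = dH * MV(pp, lay.penult_w, F, F).t();

  const int maxW = *std::max_element(c.W.begin(), c.W.end());
  std::vector<float> colmem((size_t)N * cpg * maxW),
      dcolmem((size_t)N * cpg * maxW);
  fmat dx(N, F, fill::zeros), da(N, F), dtmp(N, F);

  int k = c.ng * c.upg;
  for (int g = c.ng - 1; g >= 0; --g) {
    const int W = c.W[g], D = c.D[g];
    const fmat& x_gend = st.x_in[(size_t)(g + 1) * c.upg];
    MV(gp, lay.gout_w[g], F, F) = x_gend.t() * dSkip;
    { fvec gb = VV(gp, lay.gout_b[g], F); colsum_into(dSkip, gb); }
    dx += dSkip * MV(pp, lay.gout_w[g], F, F).t();
    for (int u = c.upg - 1; u >= 0; --u) {
      --k;
      const std::array<size_t, 8>& U = lay.unit[k];
      const fmat& x_in = st.x_in[k];
      const fmat& c1 = st.c1[k];
      // conv2 backward
      gconv_bwd(st.a2[k], MV(pp, U[6], cpg * W, F), dx, c.G, W, D, L, B, da,
                MV(gp, U[6], cpg * W, F), VV(gp, U[7], F), colmem.data(),
                dcolmem.data());
      bn_lrelu_bwd(c1, st.a2[k], da, st.mu2[k], st.var2[k], VV(pp, U[4], F),
                   c.eps, c.slope, dtmp, VV(gp, U[4], F), VV(gp, U[5], F));
      // conv1 backward
      gconv_bwd(st.a1[k], MV(pp, U[2], cpg * W, F), dtmp, c.G, W, D, L, B, da,
                MV(gp, U[2], cpg * W, F), VV(gp, U[3], F), colmem.data(),
                dcolmem.data());
      bn_lrelu_bwd(x_in, st.a1[k], da, st.mu1[k], st.var1[k], VV(pp, U[0], F),
                   c.eps, c.slope, dtmp, VV(gp, U[0], F), VV(gp, U[1], F));
      dx += dtmp;  // identity path stays in dx
    }
  }
  MV(gp, lay.skip0_w, F, F) = st.x_stem.t() * dSkip;
  { fvec gb = VV(gp, lay.skip0_b, F); colsum_into(dSkip, gb); }
  dx += dSkip * MV(pp, lay.skip0_w, F, F).t();
  MV(gp, lay.stem_w, c.Cin, F) = X0.t() * dx;
  { fvec gb = VV(gp, lay.stem_b, F); colsum_into(dx, gb); }

  NumericVector grad(lay.total);
  for (size_t i = 0; i < lay.total; ++i) grad[i] = (double)gradf[i];
  NumericVector bn_new(bnstats.size());
  for (int i = 0; i < bnstats.size(); ++i) bn_new[i] = (double)running[i];
  return List::create(_["loss"] = st.loss, _["grad"] = grad,
                      _["bnstats"] = bn_new);
}

// [[Rcpp::export]]
NumericMatrix cpp_net_forward(NumericVector par, NumericVector bnstats,
                              IntegerMatrix codes, List cfg,
                              bool train_mode = false) {
  const Cfg c = read_cfg(cfg);
  const Layout lay = layout_of(c);
  if ((size_t)par.size() != lay.total) stop("parameter vector has wrong length");
  const int L = codes.nrow(), B = codes.ncol();

  std::vector<float> parf(lay.total);
  for (size_t i = 0; i < lay.total; ++i) parf[i] = (float)par[i];
  std::vector<float> running(bnstats.size());
  for (int i = 0; i < bnstats.size(); ++i) running[i] = (float)bnstats[i];

  fmat X0 = onehot(codes, c.Cin);
  ForwardState st;
  net_forward(parf.data(), c, lay, X0, L, B, train_mode,
              train_mode ? nullptr : &running, nullptr, 0, 0, false, st,
              nullptr);
  NumericMatrix out((size_t)L * B, c.Cout);
  for (int j = 0; j < c.Cout; ++j)
    for (size_t i = 0; i < (size_t)L * B; ++i) out(i, j) = st.P(i, j);
  return out;
}

// [[Rcpp::export]]
double cpp_net_loss(NumericVector par, IntegerMatrix codes,
                    LogicalVector positive, double gamma, double pos_weight,
                    List cfg) {
  const Cfg c = read_cfg(cfg);
  const Layout lay = layout_of(c);
  if ((size_t)par.size() != lay.total) stop("parameter vector has wrong length");
  const int L = codes.nrow(), B = codes.ncol();
  std::vector<float> parf(lay.total);
  for (size_t i = 0; i < lay.total; ++i) parf[i] = (float)par[i];
  fmat X0 = onehot(codes, c.Cin);
  ForwardState st;
  net_forward(parf.data(), c, lay, X0, L, B, true, nullptr, &positive, gamma,
              pos_weight, false, st, nullptr);
  return st.loss;
}

// Generic grouped dilated 1-D convolution on a single example, exposed for
// equation-level testing.  x: L x C_in; w: (C_in/G * W) x C_out, column oc
// holding taps for output channel oc (row index = ic_within_group * W + t).
// [[Rcpp::export]]
NumericMatrix cpp_grouped_conv(NumericMatrix x, NumericMatrix w,
                               NumericVector bias, int G, int W, int D) {
  const int L = x.nrow(), Cin = x.ncol(), Cout = w.ncol();
  if (Cin % G || Cout % G) stop("channels not divisible by groups");
  if ((int)w.nrow() != (Cin / G) * W) stop("weight matrix has wrong row count");
  if (bias.size() != Cout) stop("bias has wrong length");
  fmat A(L, Cin);
  for (int c = 0; c < Cin; ++c)
    for (int i = 0; i < L; ++i) A(i, c) = (float)x(i, c);
  fmat Wt(w.nrow(), Cout);
  for (int c = 0; c < Cout; ++c)
    for (int i = 0; i < (int)w.nrow(); ++i) Wt(i, c) = (float)w(i, c);
  fvec b(Cout);
  for (int c = 0; c < Cout; ++c) b[c] = (float)bias[c];
  fmat Y(L, Cout);
  std::vector<float> colmem((size_t)L * (Cin / G) * W);
  gconv_fwd(A, Wt, b, G, W, D, L, 1, Y, colmem.data());
  NumericMatrix out(L, Cout);
  for (int c = 0; c < Cout; ++c)
    for (int i = 0; i < L; ++i) out(i, c) = Y(i, c);
  return out;
}
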