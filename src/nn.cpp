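// 3D Unet++(L3) regression/classification core.
//
// Layout conventions:
//  - A batch tensor (BTen) stores float32 values channel-major over the
//    batch: v[(((ch*n + i)*s + z)*s + y)*s + x]. Each channel block
//    (all samples, one channel) is contiguous, which makes batch-norm and
//    1x1 convolutions single contiguous sweeps / GEMMs.
//  - Every tensor lives on a cubic region [r, r+s) of its resolution level's
//    grid (g = 40, 20, 10 or 5 voxels). Backbone nodes cover their full grid
//    and use zero-padded "same" convolutions; in the cropped (regression)
//    variants the nested skip nodes are computed by *valid* convolutions on
//    exactly the receptive field of the central 10^3 subbox, which is
//    mathematically the restriction of the full-box network to the voxels
//    the loss can see. The occupancy variant computes everything full-box.
//  - Convolutions run as im2col + sgemm (one GEMM per sample); the column
//    matrix is rebuilt during backward instead of being cached.
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
#include <cmath>
#include <random>
using namespace Rcpp;
using arma::fmat;

static const float BN_EPS = 1e-5f;

struct BTen {
  int n = 0, c = 0, r = 0, s = 0;
  std::vector<float> v;
  void alloc(int n_, int c_, int r_, int s_) {
    n = n_; c = c_; r = r_; s = s_;
    v.assign((size_t)n * c * s * s * s, 0.0f);
  }
  size_t spn() const { return (size_t)s * s * s; }
  float* ch(int ci, int i) { return v.data() + (((size_t)ci * n + i) * spn()); }
  const float* ch(int ci, int i) const { return v.data() + (((size_t)ci * n + i) * spn()); }
};

struct Conv {            // k^3 convolution, weights (cin*k^3) x cout
  int cin = 0, cout = 0, k = 3;
  bool same = true;      // zero-padded (full grid) vs valid (interior crop)
  size_t woff = 0, boff = 0;
  int K() const { return cin * k * k * k; }
  size_t nparams() const { return (size_t)K() * cout + cout; }
};

struct BNorm {
  int c = 0;
  size_t goff = 0, boff = 0;   // gamma, beta in the parameter vector
  std::vector<float> rmean, rvar;
  size_t nparams() const { return 2 * (size_t)c; }
};

// source of one channel group of a node's concatenated input
struct Src { int kind; int idx; };  // kind: 0 net input, 1 block output,
                                    //       2 upsample of block, 3 maxpool of block

struct Node {
  int level = 0;            // 0..3
  int g = 40;               // grid edge at this level
  int r = 0, s = 40;        // output region
  int rin = 0, sin = 40;    // input region
  bool same = true;
  std::vector<Src> srcs;
  Conv conv1, conv2;
  BNorm bn1, bn2;
};

struct NodeActs {
  BTen in, h1, out;
  std::vector<float> xhat1, xhat2;
  std::vector<float> inv1, inv2;
  std::vector<int> poolarg;   // argmax indices if input is a maxpool
};

struct Net {
  int in_ch, base, out_ch;
  bool crop, softmax;
  std::vector<Node> nodes;          // X00 X10 X20 X30 X21 X11 X12 X01 X02 X03
  Conv head1, head2;                // 1x1 convs
  std::vector<float> P, G;          // parameters, gradients
  std::vector<float> Am, Av;        // Adam moments
  long adam_t = 0;
  // activations of the last forward pass
  std::vector<NodeActs> acts;
  BTen hin, hmid, out;
  bool last_train = false;
};

// ---------------------------------------------------------------- scratch
static std::vector<float>& scratch(int which, size_t nfloats) {
  static std::vector<float> bufs[4];
  if (bufs[which].size() < nfloats) bufs[which].resize(nfloats);
  return bufs[which];
}

// ---------------------------------------------------------------- im2col
static void im2col(const BTen& in, int i, int k, bool same, float* col, int s_out) {
  const int s = in.s;
  const size_t S = (size_t)s_out * s_out * s_out;
  const int pad = same ? (k / 2) : 0;
  for (int ci = 0; ci < in.c; ++ci) {
    const float* src = in.ch(ci, i);
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          float* dst = col + ((((size_t)ci * k + dz) * k + dy) * k + dx) * S;
          const int x0 = dx - pad;
          int lo = x0 < 0 ? -x0 : 0;
          int hi = s - x0; if (hi > s_out) hi = s_out;
          for (int z = 0; z < s_out; ++z) {
            const int sz = z + dz - pad;
            for (int y = 0; y < s_out; ++y) {
              const int sy = y + dy - pad;
              float* drow = dst + (size_t)s_out * (y + (size_t)s_out * z);
              if (sz < 0 || sz >= s || sy < 0 || sy >= s) {
                std::memset(drow, 0, (size_t)s_out * sizeof(float));
                continue;
              }
              const float* srow = src + (size_t)s * (sy + (size_t)s * sz);
              if (lo > 0) std::memset(drow, 0, (size_t)lo * sizeof(float));
              if (hi > lo) std::memcpy(drow + lo, srow + x0 + lo, (size_t)(hi - lo) * sizeof(float));
              if (hi < s_out) std::memset(drow + hi, 0, (size_t)(s_out - hi) * sizeof(float));
            }
          }
        }
  }
}

static void col2im_add(const float* col, BTen& din, int i, int k, bool same, int s_out) {
  const int s = din.s;
  const size_t S = (size_t)s_out * s_out * s_out;
  const int pad = same ? (k / 2) : 0;
  for (int ci = 0; ci < din.c; ++ci) {
    float* dst = din.ch(ci, i);
    for (int dz = 0; dz < k; ++dz)
      for (int dy = 0; dy < k; ++dy)
        for (int dx = 0; dx < k; ++dx) {
          const float* srcc = col + ((((size_t)ci * k + dz) * k + dy) * k + dx) * S;
          const int x0 = dx - pad;
          int lo = x0 < 0 ? -x0 : 0;
          int hi = s - x0; if (hi > s_out) hi = s_out;
          for (int z = 0; z < s_out; ++z) {
            const int sz = z + dz - pad;
            if (sz < 0 || sz >= s) continue;
            for (int y = 0; y < s_out; ++y) {
              const int sy = y + dy - pad;
              if (sy < 0 || sy >= s) continue;
              const float* srow = srcc + (size_t)s_out * (y + (size_t)s_out * z);
              float* drow = dst + (size_t)s * (sy + (size_t)s * sz) + x0;
              for (int x = lo; x < hi; ++x) drow[x] += srow[x];
            }
          }
        }
  }
}

// ---------------------------------------------------------------- conv
static void conv_fwd(Net& net, const Conv& cv, const BTen& in, BTen& out) {
  const int s_out = cv.same ? in.s : in.s - (cv.k - 1);
  const int r_out = cv.same ? in.r : in.r + (cv.k - 1) / 2;
  out.alloc(in.n, cv.cout, r_out, s_out);
  const size_t S = out.spn();
  const int K = cv.K();
  fmat W(net.P.data() + cv.woff, K, cv.cout, false, true);
  float* colbuf = scratch(0, S * K).data();
  float* obuf = scratch(1, S * cv.cout).data();
  for (int i = 0; i < in.n; ++i) {
    im2col(in, i, cv.k, cv.same, colbuf, s_out);
    fmat C(colbuf, S, K, false, true);
    fmat O(obuf, S, cv.cout, false, true);
    O = C * W;
    for (int co = 0; co < cv.cout; ++co) {
      float* dst = out.ch(co, i);
      const float* srcp = obuf + (size_t)co * S;
      const float b = net.P[cv.boff + co];
      for (size_t j = 0; j < S; ++j) dst[j] = srcp[j] + b;
    }
  }
}

static void conv_bwd(Net& net, const Conv& cv, const BTen& in, const BTen& dout,
                     BTen& din) {
  const int s_out = dout.s;
  const size_t S = dout.spn();
  const int K = cv.K();
  din.alloc(in.n, in.c, in.r, in.s);
  fmat W(net.P.data() + cv.woff, K, cv.cout, false, true);
  fmat GW(net.G.data() + cv.woff, K, cv.cout, false, true);
  float* colbuf = scratch(0, S * K).data();
  float* dobuf = scratch(1, S * cv.cout).data();
  float* dcbuf = scratch(2, S * K).data();
  for (int i = 0; i < in.n; ++i) {
    for (int co = 0; co < cv.cout; ++co)
      std::memcpy(dobuf + (size_t)co * S, dout.ch(co, i), S * sizeof(float));
    fmat dO(dobuf, S, cv.cout, false, true);
    im2col(in, i, cv.k, cv.same, colbuf, s_out);
    fmat C(colbuf, S, K, false, true);
    GW += C.t() * dO;
    for (int co = 0; co < cv.cout; ++co) {
      double sb = 0; const float* p = dobuf + (size_t)co * S;
      for (size_t j = 0; j < S; ++j) sb += p[j];
      net.G[cv.boff + co] += (float)sb;
    }
    fmat dC(dcbuf, S, K, false, true);
    dC = dO * W.t();
    col2im_add(dcbuf, din, i, cv.k, cv.same, s_out);
  }
}

// 1x1 convolution over the whole batch as a single GEMM (channel blocks are
// matrix columns).
static void conv1x1_fwd(Net& net, const Conv& cv, const BTen& in, BTen& out) {
  out.alloc(in.n, cv.cout, in.r, in.s);
  const size_t NS = (size_t)in.n * in.spn();
  fmat A(const_cast<float*>(in.v.data()), NS, cv.cin, false, true);
  fmat W(net.P.data() + cv.woff, cv.cin, cv.cout, false, true);
  fmat O(out.v.data(), NS, cv.cout, false, true);
  O = A * W;
  for (int co = 0; co < cv.cout; ++co) {
    float* p = out.v.data() + (size_t)co * NS;
    const float b = net.P[cv.boff + co];
    for (size_t j = 0; j < NS; ++j) p[j] += b;
  }
}

static void conv1x1_bwd(Net& net, const Conv& cv, const BTen& in, const BTen& dout,
                        BTen& din) {
  din.alloc(in.n, in.c, in.r, in.s);
  const size_t NS = (size_t)in.n * in.spn();
  fmat A(const_cast<float*>(in.v.data()), NS, cv.cin, false, true);
  fmat dO(const_cast<float*>(dout.v.data()), NS, cv.cout, false, true);
  fmat W(net.P.data() + cv.woff, cv.cin, cv.cout, false, true);
  fmat GW(net.G.data() + cv.woff, cv.cin, cv.cout, false, true);
  GW += A.t() * dO;
  for (int co = 0; co < cv.cout; ++co) {
    double sb = 0; const float* p = dout.v.data() + (size_t)co * NS;
    for (size_t j = 0; j < NS; ++j) sb += p[j];
    net.G[cv.boff + co] += (float)sb;
  }
  fmat dA(din.v.data(), NS, cv.cin, false, true);
  dA = dO * W.t();
}

// ---------------------------------------------------------------- batchnorm
static void bn_fwd(Net& net, BNorm& bn, BTen& t, bool train,
                   std::vector<float>& xhat, std::vector<float>& inv) {
  const size_t N = (size_t)t.n * t.spn();
  if (train) { xhat.resize((size_t)bn.c * N); inv.resize(bn.c); }
  for (int ci = 0; ci < bn.c; ++ci) {
    float* p = t.v.data() + (size_t)ci * N;
    const float g = net.P[bn.goff + ci], b = net.P[bn.boff + ci];
    if (train) {
      double s = 0, s2 = 0;
      for (size_t j = 0; j < N; ++j) { s += p[j]; s2 += (double)p[j] * p[j]; }
      const double mu = s / N;
      double var = s2 / N - mu * mu; if (var < 0) var = 0;
      const float iv = (float)(1.0 / std::sqrt(var + BN_EPS));
      inv[ci] = iv;
      float* xh = xhat.data() + (size_t)ci * N;
      for (size_t j = 0; j < N; ++j) {
        const float h = (p[j] - (float)mu) * iv;
        xh[j] = h;
        p[j] = g * h + b;
      }
      const double unb = N > 1 ? var * (double)N / (N - 1) : var;
      bn.rmean[ci] = 0.9f * bn.rmean[ci] + 0.1f * (float)mu;
      bn.rvar[ci] = 0.9f * bn.rvar[ci] + 0.1f * (float)unb;
    } else {
      const float iv = 1.0f / std::sqrt(bn.rvar[ci] + BN_EPS);
      const float mu = bn.rmean[ci];
      for (size_t j = 0; j < N; ++j) p[j] = g * (p[j] - mu) * iv + b;
    }
  }
}

static void bn_bwd(Net& net, const BNorm& bn, BTen& dy,
                   const std::vector<float>& xhat, const std::vector<float>& inv) {
  const size_t N = (size_t)dy.n * dy.spn();
  for (int ci = 0; ci < bn.c; ++ci) {
    float* d = dy.v.data() + (size_t)ci * N;
    const float* xh = xhat.data() + (size_t)ci * N;
    double s1 = 0, s2 = 0;
    for (size_t j = 0; j < N; ++j) { s1 += d[j]; s2 += (double)d[j] * xh[j]; }
    net.G[bn.boff + ci] += (float)s1;
    net.G[bn.goff + ci] += (float)s2;
    const float g = net.P[bn.goff + ci];
    const float a = g * inv[ci];
    const float m1 = (float)(s1 / N), m2 = (float)(s2 / N);
    for (size_t j = 0; j < N; ++j) d[j] = a * (d[j] - m1 - xh[j] * m2);
  }
}

// ---------------------------------------------------------------- relu
static void relu_fwd(BTen& t) {
  for (auto& x : t.v) if (x < 0) x = 0;
}
static void relu_bwd(const BTen& act, BTen& d) {
  for (size_t j = 0; j < d.v.size(); ++j) if (act.v[j] <= 0) d.v[j] = 0;
}

// ---------------------------------------------------------------- maxpool 2
static void pool_fwd(const BTen& in, BTen& out, std::vector<int>& arg) {
  const int so = in.s / 2;
  out.alloc(in.n, in.c, 0, so);
  arg.assign((size_t)in.n * in.c * so * so * so, 0);
  const size_t So = out.spn();
  for (int ci = 0; ci < in.c; ++ci)
    for (int i = 0; i < in.n; ++i) {
      const float* src = in.ch(ci, i);
      float* dst = out.ch(ci, i);
      int* ag = arg.data() + (((size_t)ci * in.n + i) * So);
      for (int z = 0; z < so; ++z)
        for (int y = 0; y < so; ++y)
          for (int x = 0; x < so; ++x) {
            float best = -1e30f; int bidx = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const int idx = (2 * x + dx) + in.s * ((2 * y + dy) + (size_t)in.s * (2 * z + dz));
                  if (src[idx] > best) { best = src[idx]; bidx = idx; }
                }
            dst[x + so * (y + (size_t)so * z)] = best;
            ag[x + so * (y + (size_t)so * z)] = bidx;
          }
    }
}

static void pool_bwd(const BTen& dout, const std::vector<int>& arg, BTen& din) {
  const size_t So = dout.spn();
  for (int ci = 0; ci < dout.c; ++ci)
    for (int i = 0; i < dout.n; ++i) {
      const float* d = dout.ch(ci, i);
      const int* ag = arg.data() + (((size_t)ci * dout.n + i) * So);
      float* dst = din.ch(ci, i);
      for (size_t j = 0; j < So; ++j) dst[ag[j]] += d[j];
    }
}

// ------------------------------------------------------------- upsample x2
// Trilinear, output voxel o samples input coordinate (o + 0.5)/2 - 0.5,
// edge-clamped. Writes region (r_out, s_out) of the doubled grid into the
// destination tensor's channel group starting at ch_off.
struct UpTab { std::vector<int> i0, i1; std::vector<float> w; };
static UpTab up_table(int r_out, int s_out, int g_in, int r_in) {
  UpTab t; t.i0.resize(s_out); t.i1.resize(s_out); t.w.resize(s_out);
  for (int j = 0; j < s_out; ++j) {
    const double c = (r_out + j + 0.5) * 0.5 - 0.5;
    int i0 = (int)std::floor(c);
    double w = c - i0;
    int i1 = i0 + 1;
    if (i0 < 0) { i0 = 0; i1 = 0; w = 0; }
    if (i1 > g_in - 1) { i1 = g_in - 1; if (i0 > g_in - 1) i0 = g_in - 1; w = (i0 == i1) ? 0 : w; }
    t.i0[j] = i0 - r_in; t.i1[j] = i1 - r_in; t.w[j] = (float)w;
  }
  return t;
}

static void up_into(const BTen& in, int g_in, BTen& dest, int ch_off,
                    int r_out, int s_out) {
  UpTab t = up_table(r_out, s_out, g_in, in.r);
  for (int ci = 0; ci < in.c; ++ci)
    for (int i = 0; i < in.n; ++i) {
      const float* src = in.ch(ci, i);
      float* dst = dest.ch(ch_off + ci, i);
      for (int z = 0; z < s_out; ++z) {
        const int z0 = t.i0[z], z1 = t.i1[z]; const float wz = t.w[z];
        for (int y = 0; y < s_out; ++y) {
          const int y0 = t.i0[y], y1 = t.i1[y]; const float wy = t.w[y];
          float* drow = dst + (size_t)s_out * (y + (size_t)s_out * z);
          const float* p00 = src + (size_t)in.s * (y0 + (size_t)in.s * z0);
          const float* p10 = src + (size_t)in.s * (y1 + (size_t)in.s * z0);
          const float* p01 = src + (size_t)in.s * (y0 + (size_t)in.s * z1);
          const float* p11 = src + (size_t)in.s * (y1 + (size_t)in.s * z1);
          for (int x = 0; x < s_out; ++x) {
            const int x0 = t.i0[x], x1 = t.i1[x]; const float wx = t.w[x];
            const float v00 = p00[x0] + wx * (p00[x1] - p00[x0]);
            const float v10 = p10[x0] + wx * (p10[x1] - p10[x0]);
            const float v01 = p01[x0] + wx * (p01[x1] - p01[x0]);
            const float v11 = p11[x0] + wx * (p11[x1] - p11[x0]);
            const float v0 = v00 + wy * (v10 - v00);
            const float v1 = v01 + wy * (v11 - v01);
            drow[x] = v0 + wz * (v1 - v0);
          }
        }
      }
    }
}

static void up_bwd_add(const BTen& dcat, int ch_off, int nch, int g_in,
                       int r_out, int s_out, BTen& dsrc) {
  UpTab t = up_table(r_out, s_out, g_in, dsrc.r);
  for (int ci = 0; ci < nch; ++ci)
    for (int i = 0; i < dcat.n; ++i) {
      const float* d = dcat.ch(ch_off + ci, i);
      float* dst = dsrc.ch(ci, i);
      for (int z = 0; z < s_out; ++z) {
        const int z0 = t.i0[z], z1 = t.i1[z]; const float wz = t.w[z];
        for (int y = 0; y < s_out; ++y) {
          const int y0 = t.i0[y], y1 = t.i1[y]; const float wy = t.w[y];
          const float* drow = d + (size_t)s_out * (y + (size_t)s_out * z);
          for (int x = 0; x < s_out; ++x) {
            const int x0 = t.i0[x], x1 = t.i1[x]; const float wx = t.w[x];
            const float g = drow[x];
            const float w000 = (1 - wz) * (1 - wy) * (1 - wx), w001 = (1 - wz) * (1 - wy) * wx;
            const float w010 = (1 - wz) * wy * (1 - wx), w011 = (1 - wz) * wy * wx;
            const float w100 = wz * (1 - wy) * (1 - wx), w101 = wz * (1 - wy) * wx;
            const float w110 = wz * wy * (1 - wx), w111 = wz * wy * wx;
            dst[x0 + (size_t)dsrc.s * (y0 + (size_t)dsrc.s * z0)] += g * w000;
            dst[x1 + (size_t)dsrc.s * (y0 + (size_t)dsrc.s * z0)] += g * w001;
            dst[x0 + (size_t)dsrc.s * (y1 + (size_t)dsrc.s * z0)] += g * w010;
            dst[x1 + (size_t)dsrc.s * (y1 + (size_t)dsrc.s * z0)] += g * w011;
            dst[x0 + (size_t)dsrc.s * (y0 + (size_t)dsrc.s * z1)] += g * w100;
            dst[x1 + (size_t)dsrc.s * (y0 + (size_t)dsrc.s * z1)] += g * w101;
            dst[x0 + (size_t)dsrc.s * (y1 + (size_t)dsrc.s * z1)] += g * w110;
            dst[x1 + (size_t)dsrc.s * (y1 + (size_t)dsrc.s * z1)] += g * w111;
          }
        }
      }
    }
}

// ---------------------------------------------------------------- crop copy
static void crop_into(const BTen& src, BTen& dest, int ch_off, int r, int s) {
  const int off = r - src.r;
  for (int ci = 0; ci < src.c; ++ci)
    for (int i = 0; i < src.n; ++i) {
      const float* sp = src.ch(ci, i);
      float* dp = dest.ch(ch_off + ci, i);
      for (int z = 0; z < s; ++z)
        for (int y = 0; y < s; ++y)
          std::memcpy(dp + (size_t)s * (y + (size_t)s * z),
                      sp + (off + (size_t)src.s * ((y + off) + (size_t)src.s * (z + off))),
                      (size_t)s * sizeof(float));
    }
}

static void crop_bwd_add(const BTen& dcat, int ch_off, int nch, int r, int s,
                         BTen& dsrc) {
  const int off = r - dsrc.r;
  for (int ci = 0; ci < nch; ++ci)
    for (int i = 0; i < dcat.n; ++i) {
      const float* dp = dcat.ch(ch_off + ci, i);
      float* sp = dsrc.ch(ci, i);
      for (int z = 0; z < s; ++z)
        for (int y = 0; y < s; ++y) {
          float* row = sp + off + (size_t)dsrc.s * ((y + off) + (size_t)dsrc.s * (z + off));
          const float* drow = dp + (size_t)s * (y + (size_t)s * z);
          for (int x = 0; x < s; ++x) row[x] += drow[x];
        }
    }
}

// ---------------------------------------------------------------- topology
static void build_topology(Net& net) {
  const int b = net.base;
  const int c0 = b, c1 = 2 * b, c2 = 4 * b, c3 = 8 * b;
  auto mk = [&](int level, int cin, int cout, int r, int s, bool same,
                std::vector<Src> srcs) {
    Node nd;
    nd.level = level; nd.g = 40 >> level;
    nd.r = r; nd.s = s; nd.same = same;
    nd.rin = same ? r : r - 2;
    nd.sin = same ? s : s + 4;
    nd.srcs = std::move(srcs);
    nd.conv1.cin = cin; nd.conv1.cout = cout; nd.conv1.k = 3; nd.conv1.same = same;
    nd.conv2.cin = cout; nd.conv2.cout = cout; nd.conv2.k = 3; nd.conv2.same = same;
    nd.bn1.c = cout; nd.bn2.c = cout;
    net.nodes.push_back(nd);
  };
  // backbone
  mk(0, net.in_ch, c0, 0, 40, true, {{0, 0}});
  mk(1, c0, c1, 0, 20, true, {{3, 0}});
  mk(2, c1, c2, 0, 10, true, {{3, 1}});
  mk(3, c2, c3, 0, 5, true, {{3, 2}});
  if (net.crop) {
    mk(2, c2 + c3, c2, 0, 10, true, {{1, 2}, {2, 3}});          // X21
    mk(1, c1 + c2, c1, 3, 14, false, {{1, 1}, {2, 2}});         // X11
    mk(1, 2 * c1 + c2, c1, 5, 10, false, {{1, 1}, {1, 5}, {2, 4}}); // X12
    mk(0, c0 + c1, c0, 9, 22, false, {{1, 0}, {2, 1}});         // X01
    mk(0, 2 * c0 + c1, c0, 11, 18, false, {{1, 0}, {1, 7}, {2, 5}}); // X02
    mk(0, 3 * c0 + c1, c0, 13, 14, false, {{1, 0}, {1, 7}, {1, 8}, {2, 6}}); // X03
  } else {
    mk(2, c2 + c3, c2, 0, 10, true, {{1, 2}, {2, 3}});
    mk(1, c1 + c2, c1, 0, 20, true, {{1, 1}, {2, 2}});
    mk(1, 2 * c1 + c2, c1, 0, 20, true, {{1, 1}, {1, 5}, {2, 4}});
    mk(0, c0 + c1, c0, 0, 40, true, {{1, 0}, {2, 1}});
    mk(0, 2 * c0 + c1, c0, 0, 40, true, {{1, 0}, {1, 7}, {2, 5}});
    mk(0, 3 * c0 + c1, c0, 0, 40, true, {{1, 0}, {1, 7}, {1, 8}, {2, 6}});
  }
  net.head1.cin = c0; net.head1.cout = c0; net.head1.k = 1;
  net.head2.cin = c0; net.head2.cout = net.out_ch; net.head2.k = 1;
}

static void assign_params(Net& net, unsigned seed) {
  size_t off = 0;
  auto place_conv = [&](Conv& cv) {
    cv.woff = off; off += (size_t)cv.K() * cv.cout;
    cv.boff = off; off += cv.cout;
  };
  auto place_bn = [&](BNorm& bn) {
    bn.goff = off; off += bn.c;
    bn.boff = off; off += bn.c;
    bn.rmean.assign(bn.c, 0.0f);
    bn.rvar.assign(bn.c, 1.0f);
  };
  for (auto& nd : net.nodes) {
    place_conv(nd.conv1); place_bn(nd.bn1);
    place_conv(nd.conv2); place_bn(nd.bn2);
  }
  place_conv(net.head1); place_conv(net.head2);
  net.P.assign(off, 0.0f);
  net.G.assign(off, 0.0f);
  net.Am.assign(off, 0.0f);
  net.Av.assign(off, 0.0f);

  // Kaiming-normal initialisation (deterministic Box-Muller on mt19937)
  std::mt19937 rng(seed);
  auto runif = [&]() { return (rng() + 0.5) / 4294967296.0; };
  auto rnorm = [&]() {
    double u1 = runif(), u2 = runif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  };
  auto init_conv = [&](Conv& cv) {
    const double sd = std::sqrt(2.0 / cv.K());
    for (size_t j = 0; j < (size_t)cv.K() * cv.cout; ++j)
      net.P[cv.woff + j] = (float)(sd * rnorm());
  };
  auto init_bn = [&](BNorm& bn) {
    for (int j = 0; j < bn.c; ++j) net.P[bn.goff + j] = 1.0f;
  };
  for (auto& nd : net.nodes) {
    init_conv(nd.conv1); init_bn(nd.bn1);
    init_conv(nd.conv2); init_bn(nd.bn2);
  }
  init_conv(net.head1); init_conv(net.head2);
}

// ---------------------------------------------------------------- forward
static void node_fwd(Net& net, int ni, const BTen& input, bool train) {
  Node& nd = net.nodes[ni];
  NodeActs& a = net.acts[ni];
  // assemble concatenated input
  if (nd.srcs.size() == 1 && nd.srcs[0].kind == 0) {
    a.in = input;  // X00
  } else if (nd.srcs.size() == 1 && nd.srcs[0].kind == 3) {
    pool_fwd(net.acts[nd.srcs[0].idx].out, a.in, a.poolarg);
  } else {
    int cin = 0;
    for (auto& sp : nd.srcs)
      cin += net.acts[sp.idx].out.c;
    a.in.alloc(input.n, cin, nd.rin, nd.sin);
    int co = 0;
    for (auto& sp : nd.srcs) {
      const BTen& src = net.acts[sp.idx].out;
      if (sp.kind == 1) crop_into(src, a.in, co, nd.rin, nd.sin);
      else up_into(src, net.nodes[sp.idx].g, a.in, co, nd.rin, nd.sin);
      co += src.c;
    }
  }
  conv_fwd(net, nd.conv1, a.in, a.h1);
  bn_fwd(net, nd.bn1, a.h1, train, a.xhat1, a.inv1);
  relu_fwd(a.h1);
  conv_fwd(net, nd.conv2, a.h1, a.out);
  bn_fwd(net, nd.bn2, a.out, train, a.xhat2, a.inv2);
  relu_fwd(a.out);
}

static void net_forward(Net& net, const BTen& input, bool train) {
  net.acts.assign(10, NodeActs());
  net.last_train = train;
  for (int ni = 0; ni < 10; ++ni) node_fwd(net, ni, input, train);
  const BTen& xo = net.acts[9].out;
  if (net.crop) {
    net.hin.alloc(input.n, xo.c, 15, 10);
    crop_into(xo, net.hin, 0, 15, 10);
  } else {
    net.hin = xo;
  }
  conv1x1_fwd(net, net.head1, net.hin, net.hmid);
  relu_fwd(net.hmid);
  conv1x1_fwd(net, net.head2, net.hmid, net.out);
  if (net.softmax) {
    // two-channel softmax per voxel
    const size_t NS = (size_t)net.out.n * net.out.spn();
    float* z0 = net.out.v.data();
    float* z1 = net.out.v.data() + NS;
    for (size_t j = 0; j < NS; ++j) {
      const float m = z0[j] > z1[j] ? z0[j] : z1[j];
      const float e0 = std::exp(z0[j] - m), e1 = std::exp(z1[j] - m);
      const float d = e0 + e1;
      z0[j] = e0 / d; z1[j] = e1 / d;
    }
  }
}

// ---------------------------------------------------------------- backward
static void net_backward(Net& net, BTen& dout) {
  std::fill(net.G.begin(), net.G.end(), 0.0f);
  // head
  BTen dhmid, dhin;
  conv1x1_bwd(net, net.head2, net.hmid, dout, dhmid);
  relu_bwd(net.hmid, dhmid);
  conv1x1_bwd(net, net.head1, net.hin, dhmid, dhin);
  std::vector<BTen> gout(10);
  auto ensure = [&](int ni) {
    if (gout[ni].v.empty()) {
      const BTen& o = net.acts[ni].out;
      gout[ni].alloc(o.n, o.c, o.r, o.s);
    }
  };
  ensure(9);
  if (net.crop) crop_bwd_add(dhin, 0, dhin.c, 15, 10, gout[9]);
  else gout[9].v = dhin.v;

  for (int ni = 9; ni >= 0; --ni) {
    Node& nd = net.nodes[ni];
    NodeActs& a = net.acts[ni];
    ensure(ni);
    BTen& dY2 = gout[ni];
    relu_bwd(a.out, dY2);
    bn_bwd(net, nd.bn2, dY2, a.xhat2, a.inv2);
    BTen dH1;
    conv_bwd(net, nd.conv2, a.h1, dY2, dH1);
    relu_bwd(a.h1, dH1);
    bn_bwd(net, nd.bn1, dH1, a.xhat1, a.inv1);
    BTen dIn;
    conv_bwd(net, nd.conv1, a.in, dH1, dIn);
    // route input gradient to sources
    if (nd.srcs.size() == 1 && nd.srcs[0].kind == 3) {
      const int si = nd.srcs[0].idx;
      ensure(si);
      pool_bwd(dIn, a.poolarg, gout[si]);
    } else if (!(nd.srcs.size() == 1 && nd.srcs[0].kind == 0)) {
      int co = 0;
      for (auto& sp : nd.srcs) {
        const BTen& src = net.acts[sp.idx].out;
        ensure(sp.idx);
        if (sp.kind == 1) crop_bwd_add(dIn, co, src.c, nd.rin, nd.sin, gout[sp.idx]);
        else up_bwd_add(dIn, co, src.c, net.nodes[sp.idx].g, nd.rin, nd.sin, gout[sp.idx]);
        co += src.c;
      }
    }
    // this node's activations and output gradient are no longer needed
    net.acts[ni] = NodeActs();
    gout[ni] = BTen();
  }
}

static void adam_step(Net& net, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  net.adam_t += 1;
  const double c1 = 1.0 - std::pow(b1, (double)net.adam_t);
  const double c2 = 1.0 - std::pow(b2, (double)net.adam_t);
  for (size_t j = 0; j < net.P.size(); ++j) {
    const double g = net.G[j];
    net.Am[j] = (float)(b1 * net.Am[j] + (1 - b1) * g);
    net.Av[j] = (float)(b2 * net.Av[j] + (1 - b2) * g * g);
    net.P[j] -= (float)(lr * (net.Am[j] / c1) / (std::sqrt(net.Av[j] / c2) + eps));
  }
}

// ---------------------------------------------------------------- R bridge
static BTen r_to_bten(const NumericVector& arr) {
  IntegerVector d = arr.attr("dim");
  if (d.size() != 5) stop("input array must have dim (s, s, s, C, n)");
  const int s = d[0], c = d[3], n = d[4];
  if (d[1] != s || d[2] != s) stop("input boxes must be cubic");
  BTen t; t.alloc(n, c, 0, s);
  const double* src = arr.begin();
  const size_t S = t.spn();
  for (int i = 0; i < n; ++i)
    for (int ci = 0; ci < c; ++ci) {
      float* dst = t.ch(ci, i);
      const double* sp = src + S * ((size_t)ci + (size_t)c * i);
      for (size_t j = 0; j < S; ++j) dst[j] = (float)sp[j];
    }
  return t;
}

static Net* get_net(SEXP xp) {
  XPtr<Net> p(xp);
  if (!p) stop("invalid network handle");
  return p.get();
}

// [[Rcpp::export(name = ".cpp_nn_create")]]
SEXP cpp_nn_create(int in_channels, int base_channels, bool crop,
                   int out_channels, bool softmax, int seed) {
  Net* net = new Net();
  net->in_ch = in_channels; net->base = base_channels;
  net->crop = crop; net->out_ch = out_channels; net->softmax = softmax;
  build_topology(*net);
  assign_params(*net, (unsigned)seed);
  XPtr<Net> p(net, true);
  return p;
}

// [[Rcpp::export(name = ".cpp_nn_nparams")]]
double cpp_nn_nparams(SEXP xp) { return (double)get_net(xp)->P.size(); }

// [[Rcpp::export(name = ".cpp_nn_forward")]]
NumericVector cpp_nn_forward(SEXP xp, NumericVector input) {
  Net* net = get_net(xp);
  BTen in = r_to_bten(input);
  if (in.s != 40) stop("network input spatial size must be 40");
  if (in.c != net->in_ch)
    stop("input has %d channels; network expects %d", in.c, net->in_ch);
  net_forward(*net, in, false);
  const BTen& o = net->out;
  NumericVector res((R_xlen_t)o.v.size());
  const size_t S = o.spn();
  for (int i = 0; i < o.n; ++i)
    for (int ci = 0; ci < o.c; ++ci) {
      const float* sp = net->out.ch(ci, i);
      double* dst = res.begin() + S * ((size_t)ci + (size_t)o.c * i);
      for (size_t j = 0; j < S; ++j) dst[j] = sp[j];
    }
  res.attr("dim") = IntegerVector::create(o.s, o.s, o.s, o.c, o.n);
  // free activation storage
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return res;
}

// masked MSE loss and gradient on the 10^3 (or 40^3) output
static double mse_loss_grad(const BTen& out, const NumericVector& label,
                            const LogicalVector& mask, BTen* dout) {
  const size_t S = out.spn();
  size_t M = 0;
  for (R_xlen_t j = 0; j < mask.size(); ++j) if (mask[j]) ++M;
  if (M == 0) stop("empty mask: no labelled voxels in batch");
  if (dout) dout->alloc(out.n, out.c, out.r, out.s);
  double loss = 0;
  for (int i = 0; i < out.n; ++i) {
    const float* p = out.ch(0, i);
    const double* lb = label.begin() + (size_t)i * S;
    const int* mk = LOGICAL(mask) + (size_t)i * S;
    float* d = dout ? dout->ch(0, i) : nullptr;
    for (size_t j = 0; j < S; ++j) {
      if (mk[j]) {
        const double e = p[j] - lb[j];
        loss += e * e;
        if (d) d[j] = (float)(2.0 * e / M);
      }
    }
  }
  return loss / M;
}

// [[Rcpp::export(name = ".cpp_nn_train_mse")]]
double cpp_nn_train_mse(SEXP xp, NumericVector input, NumericVector label,
                        LogicalVector mask, double lr) {
  Net* net = get_net(xp);
  BTen in = r_to_bten(input);
  net_forward(*net, in, true);
  BTen dout;
  const double loss = mse_loss_grad(net->out, label, mask, &dout);
  net_backward(*net, dout);
  adam_step(*net, lr);
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return loss;
}

// [[Rcpp::export(name = ".cpp_nn_loss_mse")]]
double cpp_nn_loss_mse(SEXP xp, NumericVector input, NumericVector label,
                       LogicalVector mask) {
  Net* net = get_net(xp);
  BTen in = r_to_bten(input);
  net_forward(*net, in, false);
  const double loss = mse_loss_grad(net->out, label, mask, nullptr);
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return loss;
}

// weighted cross-entropy on softmax output; truth is 0/1 (occupied)
static double ce_loss_grad(const BTen& probs, const IntegerVector& truth,
                           double w0, double w1, BTen* dlogit) {
  const size_t NS = (size_t)probs.n * probs.spn();
  const float* p0 = probs.v.data();
  const float* p1 = probs.v.data() + NS;
  double wsum = 0, loss = 0;
  for (size_t j = 0; j < NS; ++j) wsum += truth[j] ? w1 : w0;
  if (wsum <= 0) stop("degenerate class weights");
  if (dlogit) dlogit->alloc(probs.n, 2, probs.r, probs.s);
  float* d0 = dlogit ? dlogit->v.data() : nullptr;
  float* d1 = dlogit ? dlogit->v.data() + NS : nullptr;
  for (size_t j = 0; j < NS; ++j) {
    const int y = truth[j] ? 1 : 0;
    const double w = y ? w1 : w0;
    const double py = y ? p1[j] : p0[j];
    loss += -w * std::log(py > 1e-12 ? py : 1e-12);
    if (dlogit) {
      d0[j] = (float)(w * (p0[j] - (y == 0 ? 1.0 : 0.0)) / wsum);
      d1[j] = (float)(w * (p1[j] - (y == 1 ? 1.0 : 0.0)) / wsum);
    }
  }
  return loss / wsum;
}

// [[Rcpp::export(name = ".cpp_nn_train_ce")]]
double cpp_nn_train_ce(SEXP xp, NumericVector input, IntegerVector truth,
                       double w0, double w1, double lr) {
  Net* net = get_net(xp);
  if (!net->softmax) stop("cross-entropy training requires a softmax network");
  BTen in = r_to_bten(input);
  net_forward(*net, in, true);
  BTen dout;
  const double loss = ce_loss_grad(net->out, truth, w0, w1, &dout);
  net_backward(*net, dout);
  adam_step(*net, lr);
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return loss;
}

// [[Rcpp::export(name = ".cpp_nn_loss_ce")]]
double cpp_nn_loss_ce(SEXP xp, NumericVector input, IntegerVector truth,
                      double w0, double w1) {
  Net* net = get_net(xp);
  BTen in = r_to_bten(input);
  net_forward(*net, in, false);
  const double loss = ce_loss_grad(net->out, truth, w0, w1, nullptr);
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return loss;
}

// training-mode loss and full gradient without an optimiser step; used by
// the finite-difference gradient tests
// [[Rcpp::export(name = ".cpp_nn_lossgrad")]]
List cpp_nn_lossgrad(SEXP xp, NumericVector input, SEXP label, SEXP mask,
                     double w0, double w1, bool train) {
  Net* net = get_net(xp);
  BTen in = r_to_bten(input);
  net_forward(*net, in, train);
  BTen dout;
  double loss;
  if (net->softmax) {
    loss = ce_loss_grad(net->out, as<IntegerVector>(label), w0, w1, &dout);
  } else {
    loss = mse_loss_grad(net->out, as<NumericVector>(label),
                         as<LogicalVector>(mask), &dout);
  }
  net_backward(*net, dout);
  NumericVector g(net->G.begin(), net->G.end());
  net->acts.clear(); net->hin = BTen(); net->hmid = BTen();
  return List::create(_["loss"] = loss, _["grad"] = g);
}

// [[Rcpp::export(name = ".cpp_nn_get_state")]]
List cpp_nn_get_state(SEXP xp) {
  Net* net = get_net(xp);
  std::vector<double> run;
  for (auto& nd : net->nodes)
    for (BNorm* bn : {&nd.bn1, &nd.bn2}) {
      run.insert(run.end(), bn->rmean.begin(), bn->rmean.end());
      run.insert(run.end(), bn->rvar.begin(), bn->rvar.end());
    }
  return List::create(
    _["params"] = NumericVector(net->P.begin(), net->P.end()),
    _["running"] = NumericVector(run.begin(), run.end()),
    _["adam_m"] = NumericVector(net->Am.begin(), net->Am.end()),
    _["adam_v"] = NumericVector(net->Av.begin(), net->Av.end()),
    _["adam_t"] = (double)net->adam_t);
}

// [[Rcpp::export(name = ".cpp_nn_set_state")]]
void cpp_nn_set_state(SEXP xp, List state) {
  Net* net = get_net(xp);
  NumericVector p = state["params"];
  if ((size_t)p.size() != net->P.size()) stop("parameter vector length mismatch");
  for (size_t j = 0; j < net->P.size(); ++j) net->P[j] = (float)p[j];
  NumericVector run = state["running"];
  size_t off = 0;
  for (auto& nd : net->nodes)
    for (BNorm* bn : {&nd.bn1, &nd.bn2}) {
      for (int j = 0; j < bn->c; ++j) bn->rmean[j] = (float)run[off + j];
      off += bn->c;
      for (int j = 0; j < bn->c; ++j) bn->rvar[j] = (float)run[off + j];
      off += bn->c;
    }
  if (state.containsElementNamed("adam_m")) {
    NumericVector m = state["adam_m"], v = state["adam_v"];
    if ((size_t)m.size() == net->Am.size())
      for (size_t j = 0; j < net->Am.size(); ++j) {
        net->Am[j] = (float)m[j]; net->Av[j] = (float)v[j];
      }
    net->adam_t = (long)Rcpp::as<double>(state["adam_t"]);
  }
}
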