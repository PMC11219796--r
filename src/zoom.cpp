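// Cubic B-spline resampling of 3D grids (separable IIR prefilter + kernel
// evaluation), used to bring density maps to a uniform voxel size.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Prefilter one line in place: converts samples to cubic B-spline
// coefficients (Unser's recursive algorithm, pole z1 = sqrt(3) - 2).
static void bspline_prefilter_line(double* c, int n) {
  if (n < 2) return;
  const double z1 = std::sqrt(3.0) - 2.0;
  const double lambda = 6.0; // gain (1 - z1)(1 - 1/z1) = 6 for cubic
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal init for the mirror boundary: truncated sum when the signal is
  // long enough, otherwise the exact mirror-periodic closed form
  int horizon = (int)std::ceil(std::log(1e-14) / std::log(std::fabs(z1)));
  double sum;
  if (horizon < n) {
    double zn = z1; sum = c[0];
    for (int i = 1; i < horizon; ++i) { sum += zn * c[i]; zn *= z1; }
  } else {
    double zn = z1;
    const double z2n2 = std::pow(z1, 2.0 * n - 2.0);
    sum = c[0];
    for (int k = 1; k <= n - 1; ++k) { sum += zn * c[k]; zn *= z1; }
    for (int k = n; k <= 2 * n - 3; ++k) { sum += zn * c[2 * n - 2 - k]; zn *= z1; }
    sum /= (1.0 - z2n2);
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z1 * c[i - 1];
  // anticausal init (mirror)
  c[n - 1] = (z1 / (z1 * z1 - 1.0)) * (c[n - 1] + z1 * c[n - 2]);
  for (int i = n - 2; i >= 0; --i) c[i] = z1 * (c[i + 1] - c[i]);
}

static inline void cubic_weights(double t, double* w) {
  // cubic B-spline kernel weights for offsets -1..2 given fraction t in [0,1)
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

static inline int mirror_idx(int i, int n) {
  // mirror reflection (matching the prefilter's boundary assumption)
  if (n == 1) return 0;
  while (i < 0 || i > n - 1) {
    if (i < 0) i = -i;
    if (i > n - 1) i = 2 * (n - 1) - i;
  }
  return i;
}

// Resample a 3D array so that output voxel centre i lies at input coordinate
// i * ratio (ratio = target_voxel / source_voxel), mirror-bounded.
// [[Rcpp::export(name = ".cpp_spline_zoom")]]
NumericVector cpp_spline_zoom(NumericVector values, IntegerVector in_dim,
                              IntegerVector out_dim, double ratio) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  const size_t N = (size_t)nx * ny * nz;
  std::vector<double> coef(values.begin(), values.end());

  // prefilter along x, y, z
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      double* p = coef.data() + (size_t)nx * (y + (size_t)ny * z);
      bspline_prefilter_line(p, nx);
    }
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) line[y] = coef[x + (size_t)nx * (y + (size_t)ny * z)];
      bspline_prefilter_line(line.data(), ny);
      for (int y = 0; y < ny; ++y) coef[x + (size_t)nx * (y + (size_t)ny * z)] = line[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) line[z] = coef[x + (size_t)nx * (y + (size_t)ny * z)];
      bspline_prefilter_line(line.data(), nz);
      for (int z = 0; z < nz; ++z) coef[x + (size_t)nx * (y + (size_t)ny * z)] = line[z];
    }
  (void)N;

  // per-axis sampling tables
  struct Tab { std::vector<int> idx; std::vector<double> w; };
  auto build = [&](int no, int ni) {
    Tab t; t.idx.resize((size_t)no * 4); t.w.resize((size_t)no * 4);
    for (int o = 0; o < no; ++o) {
      double c = o * ratio;
      int i0 = (int)std::floor(c);
      double fr = c - i0;
      double w4[4]; cubic_weights(fr, w4);
      for (int k = 0; k < 4; ++k) {
        t.idx[(size_t)o * 4 + k] = mirror_idx(i0 - 1 + k, ni);
        t.w[(size_t)o * 4 + k] = w4[k];
      }
    }
    return t;
  };
  Tab tx = build(ox, nx), ty = build(oy, ny), tz = build(oz, nz);

  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; ++z)
    for (int y = 0; y < oy; ++y)
      for (int x = 0; x < ox; ++x) {
        double acc = 0.0;
        for (int kz = 0; kz < 4; ++kz) {
          int iz = tz.idx[(size_t)z * 4 + kz]; double wz = tz.w[(size_t)z * 4 + kz];
          for (int ky = 0; ky < 4; ++ky) {
            int iy = ty.idx[(size_t)y * 4 + ky]; double wy = wz * ty.w[(size_t)y * 4 + ky];
            const double* row = coef.data() + (size_t)nx * (iy + (size_t)ny * iz);
            double s = 0.0;
            for (int kx = 0; kx < 4; ++kx)
              s += tx.w[(size_t)x * 4 + kx] * row[tx.idx[(size_t)x * 4 + kx]];
            acc += wy * s;
          }
        }
        out[x + (R_xlen_t)ox * (y + (R_xlen_t)oy * z)] = acc;
      }
  return out;
}
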