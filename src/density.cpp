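// Simulated density rendering: each atom contributes an isotropic Gaussian
// (sd = 0.225 * resolution, peak amplitude = atomic mass) truncated at 4 sd.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_simulate_density")]]
NumericVector cpp_simulate_density(NumericMatrix coords, NumericVector mass,
                                   IntegerVector dim, double voxel_size,
                                   NumericVector origin, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz); // zero-initialised
  const double cutoff = 4.0 * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const int n = coords.nrow();
  for (int a = 0; a < n; ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double m = mass[a];
    // voxel index range within the truncation radius
    int x0 = (int)std::ceil((ax - cutoff - origin[0]) / voxel_size);
    int x1 = (int)std::floor((ax + cutoff - origin[0]) / voxel_size);
    int y0 = (int)std::ceil((ay - cutoff - origin[1]) / voxel_size);
    int y1 = (int)std::floor((ay + cutoff - origin[1]) / voxel_size);
    int z0 = (int)std::ceil((az - cutoff - origin[2]) / voxel_size);
    int z1 = (int)std::floor((az + cutoff - origin[2]) / voxel_size);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 > nx - 1) x1 = nx - 1; if (y1 > ny - 1) y1 = ny - 1; if (z1 > nz - 1) z1 = nz - 1;
    for (int z = z0; z <= z1; ++z) {
      double dz = origin[2] + z * voxel_size - az;
      for (int y = y0; y <= y1; ++y) {
        double dy = origin[1] + y * voxel_size - ay;
        double r2yz = dz * dz + dy * dy;
        double* row = &out[(R_xlen_t)nx * (y + (R_xlen_t)ny * z)];
        for (int x = x0; x <= x1; ++x) {
          double dx = origin[0] + x * voxel_size - ax;
          double r2 = r2yz + dx * dx;
          if (r2 <= cutoff * cutoff) row[x] += m * std::exp(-r2 * inv2s2);
        }
      }
    }
  }
  return out;
}
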