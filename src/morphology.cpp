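#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large finite sentinel instead of Inf so the lower-envelope arithmetic below
// never produces NaN from Inf - Inf.
static const double BIG = 1e30;

// 1D squared-distance transform (lower envelope of parabolas) on a line of n
// samples with physical spacing s. f holds squared distances on input.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sep;
    while (true) {
      double xv = v[k] * s;
      sep = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (sep <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = sep;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest TRUE voxel
// of a 3D mask, honouring anisotropic voxel spacing. Voxels inside the mask get
// 0; if the mask is empty every voxel gets a BIG sentinel.
// [[Rcpp::export]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis x
  for (int kzi = 0; kzi < nz; ++kzi)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // axis y
  for (int kzi = 0; kzi < nz; ++kzi)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)kzi * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // axis z
  R_xlen_t pl = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int kzi = 0; kzi < nz; ++kzi) f[kzi] = out[base + kzi * pl];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int kzi = 0; kzi < nz; ++kzi) out[base + kzi * pl] = d[kzi];
    }
  return out;
}

// Connected-component labelling of a 3D logical mask with 6- or 26-neighbour
// connectivity. Labels are 1..K in first-encounter order; background is 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> offs_i, offs_j, offs_k;
  for (int dk = -1; dk <= 1; ++dk)
    for (int dj = -1; dj <= 1; ++dj)
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (connectivity == 6 && manh > 1) continue;
        offs_i.push_back(di);
        offs_j.push_back(dj);
        offs_k.push_back(dk);
      }

  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((R_xlen_t)nx * ny);
      for (size_t m = 0; m < offs_i.size(); ++m) {
        int ii = ci + offs_i[m], jj = cj + offs_j[m], kk = ck + offs_k[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}
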