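#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Separable truncated-Gaussian smoothing along one axis of a (possibly 4D)
// column-major array. The kernel is cut at ceil(3*sigma) and renormalized
// over the in-bounds support at every position, so constants are preserved
// at the edges.
static void smoothAxis(std::vector<double> &a, const int n0, const int n1,
                       const int n2, const double sigmaVox) {
  // smooth along the middle dimension of an (n0, n1, n2) view; work is
  // organised as contiguous axpy updates over the fastest dimension
  int hw = std::max(1, (int)std::ceil(3.0 * sigmaVox));
  std::vector<double> w(hw + 1);
  for (int d = 0; d <= hw; ++d)
    w[d] = std::exp(-0.5 * d * d / (sigmaVox * sigmaVox));
  if (n0 == 1) {
    // contiguous lines: direct convolution
    std::vector<double> den(n1);
    for (int j = 0; j < n1; ++j) {
      int lo = std::max(0, j - hw), hi = std::min(n1 - 1, j + hw);
      double d = 0.0;
      for (int l = lo; l <= hi; ++l) d += w[std::abs(l - j)];
      den[j] = d;
    }
    std::vector<double> line(n1);
    for (int k = 0; k < n2; ++k) {
      double *seg = &a[(R_xlen_t)k * n1];
      std::copy(seg, seg + n1, line.begin());
      for (int j = 0; j < n1; ++j) {
        int lo = std::max(0, j - hw), hi = std::min(n1 - 1, j + hw);
        double num = 0.0;
        for (int l = lo; l <= hi; ++l) num += w[std::abs(l - j)] * line[l];
        seg[j] = num / den[j];
      }
    }
    return;
  }
  const R_xlen_t planeSize = (R_xlen_t)n0 * n1;
  std::vector<double> tmp(planeSize);
  for (int k = 0; k < n2; ++k) {
    double *plane = &a[k * planeSize];
    std::fill(tmp.begin(), tmp.end(), 0.0);
    for (int j = 0; j < n1; ++j) {
      int lo = std::max(0, j - hw), hi = std::min(n1 - 1, j + hw);
      double den = 0.0;
      for (int l = lo; l <= hi; ++l) den += w[std::abs(l - j)];
      double *out = &tmp[(R_xlen_t)j * n0];
      for (int l = lo; l <= hi; ++l) {
        const double wd = w[std::abs(l - j)] / den;
        const double *in = &plane[(R_xlen_t)l * n0];
        for (int v = 0; v < n0; ++v) out[v] += wd * in[v];
      }
    }
    std::copy(tmp.begin(), tmp.end(), plane);
  }
}

// [[Rcpp::export]]
NumericVector cppSmoothSeparable(NumericVector arr, IntegerVector dims,
                                 double sigmaVox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nt = dims.size() > 3 ? dims[3] : 1;
  std::vector<double> a(arr.begin(), arr.end());
  // x axis: view (1, nx, ny*nz*nt)
  smoothAxis(a, 1, nx, ny * nz * nt, sigmaVox);
  // y axis: view (nx, ny, nz*nt)
  smoothAxis(a, nx, ny, nz * nt, sigmaVox);
  // z axis: view (nx*ny, nz, nt)
  smoothAxis(a, nx * ny, nz, nt, sigmaVox);
  NumericVector res(a.begin(), a.end());
  res.attr("dim") = arr.attr("dim");
  return res;
}

// Turn iid standard normals (nvox x nt, column-major) into the baseline
// BOLD background: AR(1) noise with unit marginal variance (stationary
// recursion), scaled by sigma (percent), plus drift, around the baseline:
//   out[v,t] = baseline * (1 + drift[t] + sigma/100 * e[v,t])
// Modifies e in place and returns it.
// [[Rcpp::export]]
NumericMatrix cppAr1Assemble(NumericMatrix e, double rho,
                             NumericVector drift, double sigma,
                             double baseline) {
  int nvox = e.nrow(), nt = e.ncol();
  double s = std::sqrt(1.0 - rho * rho);
  double sc = sigma / 100.0;
  if (rho != 0.0) {
    for (int t = 1; t < nt; ++t) {
      double *col = &e(0, t), *prev = &e(0, t - 1);
      for (int v = 0; v < nvox; ++v) col[v] = rho * prev[v] + s * col[v];
    }
  }
  for (int t = 0; t < nt; ++t) {
    double *col = &e(0, t);
    double b = baseline * (1.0 + drift[t]);
    for (int v = 0; v < nvox; ++v) col[v] = b + baseline * sc * col[v];
  }
  return e;
}
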