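// Separable 3D filters: Gaussian blur (PSF model) and sliding box sums
// (SSIM window statistics). Zero-padded borders with normalised kernels,
// so interior mass is preserved.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static std::vector<double> gauss_kernel(double sigma) {
  if (sigma <= 0.0) return std::vector<double>(1, 1.0);
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &v : k) v /= s;
  return k;
}

static void conv_axis(std::vector<double> &a, int n0, int n1, int n2,
                      const std::vector<double> &k, int axis) {
  // convolve along `axis` of an (n0,n1,n2) column-major array, zero padded
  const int r = ((int)k.size() - 1) / 2;
  if (r == 0) return;
  const int n[3] = {n0, n1, n2};
  const R_xlen_t stride[3] = {1, (R_xlen_t)n0, (R_xlen_t)n0 * n1};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  const int oa = (axis == 0) ? 1 : 0;
  const int ob = (axis == 2) ? 1 : 2;
  for (int b = 0; b < n[ob]; ++b) {
    for (int a2 = 0; a2 < n[oa]; ++a2) {
      const R_xlen_t base = (R_xlen_t)a2 * stride[oa] + (R_xlen_t)b * stride[ob];
      for (int i = 0; i < len; ++i) line[i] = a[base + st * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        const int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int j = lo; j <= hi; ++j) acc += line[j] * k[(i - j) + r];
        a[base + st * i] = acc;
      }
    }
  }
}

// sigma per axis in voxel units
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector img, IntegerVector dims, NumericVector sigma) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  std::vector<double> a(img.begin(), img.end());
  for (int ax = 0; ax < 3; ++ax) {
    std::vector<double> k = gauss_kernel(sigma[ax]);
    conv_axis(a, n0, n1, n2, k, ax);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// Sliding-window sums over all fully interior w^3 windows (stride 1).
// Returns array of dim (n0-w+1, n1-w+1, n2-w+1).
// [[Rcpp::export]]
NumericVector cpp_boxsum3(NumericVector img, IntegerVector dims, int w) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  if (w > n0 || w > n1 || w > n2) stop("window larger than array");
  const int m0 = n0 - w + 1, m1 = n1 - w + 1, m2 = n2 - w + 1;
  // running sums along each axis in turn
  std::vector<double> a(img.begin(), img.end());
  std::vector<double> b;
  // axis 0
  b.assign((R_xlen_t)m0 * n1 * n2, 0.0);
  for (int z = 0; z < n2; ++z)
    for (int y = 0; y < n1; ++y) {
      const double *src = &a[((R_xlen_t)z * n1 + y) * n0];
      double *dst = &b[((R_xlen_t)z * n1 + y) * m0];
      double s = 0.0;
      for (int i = 0; i < w; ++i) s += src[i];
      dst[0] = s;
      for (int i = 1; i < m0; ++i) { s += src[i + w - 1] - src[i - 1]; dst[i] = s; }
    }
  // axis 1
  a.assign((R_xlen_t)m0 * m1 * n2, 0.0);
  for (int z = 0; z < n2; ++z)
    for (int x = 0; x < m0; ++x) {
      double s = 0.0;
      for (int y = 0; y < w; ++y) s += b[((R_xlen_t)z * n1 + y) * m0 + x];
      a[((R_xlen_t)z * m1 + 0) * m0 + x] = s;
      for (int y = 1; y < m1; ++y) {
        s += b[((R_xlen_t)z * n1 + (y + w - 1)) * m0 + x] - b[((R_xlen_t)z * n1 + (y - 1)) * m0 + x];
        a[((R_xlen_t)z * m1 + y) * m0 + x] = s;
      }
    }
  // axis 2
  NumericVector out((R_xlen_t)m0 * m1 * m2);
  for (int y = 0; y < m1; ++y)
    for (int x = 0; x < m0; ++x) {
      double s = 0.0;
      for (int z = 0; z < w; ++z) s += a[((R_xlen_t)z * m1 + y) * m0 + x];
      out[((R_xlen_t)0 * m1 + y) * m0 + x] = s;
      for (int z = 1; z < m2; ++z) {
        s += a[((R_xlen_t)(z + w - 1) * m1 + y) * m0 + x] - a[((R_xlen_t)(z - 1) * m1 + y) * m0 + x];
        out[((R_xlen_t)z * m1 + y) * m0 + x] = s;
      }
    }
  out.attr("dim") = IntegerVector::create(m0, m1, m2);
  return out;
}
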