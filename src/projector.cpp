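// Slice-wise 2D parallel-beam projector pair (forward splat / adjoint
// backprojection) used by the analytic simulator and the OSEM solver.
// Pixel-driven with linear interpolation in the radial coordinate; the
// forward and backward operators are exact adjoints of each other, which
// the EM updates rely on.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// img: (nx, ny, nz); angles in radians; returns sinogram (nbins, nangles, nz).
// Bin values approximate line integrals in mm: each pixel contributes
// value * dy (the sampling pitch along the ray) split linearly between the
// two nearest radial bins at pitch ds.
// [[Rcpp::export]]
NumericVector cpp_project(NumericVector img, IntegerVector dims,
                          NumericVector angles, int nbins,
                          double dx, double dy, double ds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = angles.size();
  NumericVector sino(R_xlen_t(nbins) * na * nz);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cb = 0.5 * (nbins - 1);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int z = 0; z < nz; ++z) {
      const double *im = &img[R_xlen_t(z) * nx * ny];
      double *pr = &sino[(R_xlen_t(z) * na + a) * nbins];
      for (int j = 0; j < ny; ++j) {
        const double y = (j - cy) * dy;
        for (int i = 0; i < nx; ++i) {
          const double v = im[R_xlen_t(j) * nx + i];
          if (v == 0.0) continue;
          const double x = (i - cx) * dx;
          const double t = (x * ct + y * st) / ds + cb;
          const int b0 = (int)std::floor(t);
          const double w = t - b0;
          const double contrib = v * dy;
          if (b0 >= 0 && b0 < nbins)     pr[b0]     += contrib * (1.0 - w);
          if (b0 + 1 >= 0 && b0 + 1 < nbins) pr[b0 + 1] += contrib * w;
        }
      }
    }
  }
  sino.attr("dim") = IntegerVector::create(nbins, na, nz);
  return sino;
}

// Adjoint of cpp_project: sinogram (nbins, na, nz) -> image (nx, ny, nz).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector sino, IntegerVector sdims,
                              NumericVector angles, IntegerVector dims,
                              double dx, double dy, double ds) {
  const int nbins = sdims[0], na = sdims[1], nz = sdims[2];
  const int nx = dims[0], ny = dims[1];
  if (na != angles.size()) stop("angle count mismatch");
  NumericVector img(R_xlen_t(nx) * ny * nz);
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  const double cb = 0.5 * (nbins - 1);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int z = 0; z < nz; ++z) {
      const double *pr = &sino[(R_xlen_t(z) * na + a) * nbins];
      double *im = &img[R_xlen_t(z) * nx * ny];
      for (int j = 0; j < ny; ++j) {
        const double y = (j - cy) * dy;
        for (int i = 0; i < nx; ++i) {
          const double x = (i - cx) * dx;
          const double t = (x * ct + y * st) / ds + cb;
          const int b0 = (int)std::floor(t);
          const double w = t - b0;
          double acc = 0.0;
          if (b0 >= 0 && b0 < nbins)         acc += pr[b0] * (1.0 - w);
          if (b0 + 1 >= 0 && b0 + 1 < nbins) acc += pr[b0 + 1] * w;
          im[R_xlen_t(j) * nx + i] += acc * dy;
        }
      }
    }
  }
  img.attr("dim") = IntegerVector::create(nx, ny, nz);
  return img;
}
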