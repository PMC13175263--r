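// 3D convolutional network kernels: same-padded 3x3x3 convolutions via
// im2col + single-precision GEMM, ReLU, batch normalisation and inverted
// dropout, with full backpropagation. The network topology (7 conv layers,
// 32 filters, BN after every conv except the last, dropout after the first
// two BN layers, linear output) is fixed by the R-side model spec; these
// kernels only execute it. Parameters cross the boundary as double R
// matrices and are computed on in float for speed.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

// neighbour index map for a same-padded 3x3x3 kernel on an (n0,n1,n2) grid:
// nbr(v, k) = linear index of the k-th neighbour of voxel v, or -1 outside.
static arma::Mat<int> make_nbr(int n0, int n1, int n2) {
  const int nv = n0 * n1 * n2;
  arma::Mat<int> nbr(nv, 27);
  int v = 0;
  for (int z = 0; z < n2; ++z)
    for (int y = 0; y < n1; ++y)
      for (int x = 0; x < n0; ++x, ++v) {
        int k = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx, ++k) {
              const int xx = x + dx, yy = y + dy, zz = z + dz;
              nbr(v, k) = (xx < 0 || yy < 0 || zz < 0 || xx >= n0 || yy >= n1 || zz >= n2)
                            ? -1 : (zz * n1 + yy) * n0 + xx;
            }
      }
  return nbr;
}

static fmat im2col(const fmat &A, const arma::Mat<int> &nbr) {
  const int nv = nbr.n_rows, cin = A.n_cols;
  fmat X(nv, cin * 27, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const float *ac = A.colptr(c);
    for (int k = 0; k < 27; ++k) {
      float *xc = X.colptr(c * 27 + k);
      const int *nb = nbr.colptr(k);
      for (int v = 0; v < nv; ++v)
        if (nb[v] >= 0) xc[v] = ac[nb[v]];
    }
  }
  return X;
}

static void col2im_acc(const fmat &dX, const arma::Mat<int> &nbr, fmat &dA) {
  const int nv = nbr.n_rows, cin = dA.n_cols;
  for (int c = 0; c < cin; ++c) {
    float *ac = dA.colptr(c);
    for (int k = 0; k < 27; ++k) {
      const float *xc = dX.colptr(c * 27 + k);
      const int *nb = nbr.colptr(k);
      for (int v = 0; v < nv; ++v)
        if (nb[v] >= 0) ac[nb[v]] += xc[v];
    }
  }
}

static fmat as_fmat(SEXP m) {
  NumericMatrix nm(m);
  fmat out(nm.nrow(), nm.ncol());
  for (int j = 0; j < nm.ncol(); ++j)
    for (int i = 0; i < nm.nrow(); ++i) out(i, j) = (float)nm(i, j);
  return out;
}
static fvec as_fvec(SEXP v) {
  NumericVector nv(v);
  fvec out(nv.size());
  for (int i = 0; i < nv.size(); ++i) out[i] = (float)nv[i];
  return out;
}
static NumericMatrix to_rmat(const fmat &m) {
  NumericMatrix out(m.n_rows, m.n_cols);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i) out(i, j) = m(i, j);
  return out;
}
static NumericVector to_rvec(const fvec &v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

// Inference forward pass. x: (n0*n1*n2) x B matrix of input crops (one column
// per case, single channel); params: list of per-layer lists. Uses BN running
// statistics, no dropout. Returns matrix of same shape.
// [[Rcpp::export]]
NumericMatrix cnn_forward_cpp(NumericMatrix x, List params, IntegerVector dims,
                              double bn_eps) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const int nv = n0 * n1 * n2, B = x.ncol();
  if (x.nrow() != nv) stop("input size does not match dims");
  const int L = params.size();
  arma::Mat<int> nbr = make_nbr(n0, n1, n2);
  // preconvert parameters
  std::vector<fmat> W(L);
  std::vector<fvec> b(L), gamma(L), beta(L), rmean(L), rvar(L);
  for (int l = 0; l < L; ++l) {
    List pl = params[l];
    W[l] = as_fmat(pl["W"]); b[l] = as_fvec(pl["b"]);
    if (l < L - 1) {
      gamma[l] = as_fvec(pl["gamma"]); beta[l] = as_fvec(pl["beta"]);
      rmean[l] = as_fvec(pl["run_mean"]); rvar[l] = as_fvec(pl["run_var"]);
    }
  }
  NumericMatrix out(nv, B);
  for (int s = 0; s < B; ++s) {
    fmat A(nv, 1);
    for (int v = 0; v < nv; ++v) A(v, 0) = (float)x(v, s);
    for (int l = 0; l < L; ++l) {
      fmat X = im2col(A, nbr);
      fmat Z = X * W[l];
      Z.each_row() += b[l].t();
      if (l < L - 1) {
        Z.transform([](float z) { return z > 0.0f ? z : 0.0f; });
        for (arma::uword c = 0; c < Z.n_cols; ++c) {
          const float inv = 1.0f / std::sqrt(rvar[l][c] + (float)bn_eps);
          Z.col(c) = (Z.col(c) - rmean[l][c]) * inv * gamma[l][c] + beta[l][c];
        }
      }
      A = Z;
    }
    for (int v = 0; v < nv; ++v) out(v, s) = A(v, 0);
  }
  return out;
}

// One training step: forward with batch-statistics BN and dropout, MSE loss,
// full backward pass. Returns loss, per-layer gradients and the BN batch
// statistics (for the R side to fold into running averages).
// dropout_layers: 1-based hidden-layer indices that carry dropout.
// [[Rcpp::export]]
List cnn_train_step_cpp(NumericMatrix x, NumericMatrix y, List params,
                        IntegerVector dims, double bn_eps,
                        double dropout_rate, IntegerVector dropout_layers,
                        int seed) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const int nv = n0 * n1 * n2, B = x.ncol();
  if (x.nrow() != nv || y.nrow() != nv || y.ncol() != B)
    stop("input/target shape mismatch");
  const int L = params.size();
  const int N = nv * B;
  arma::Mat<int> nbr = make_nbr(n0, n1, n2);
  std::vector<fmat> W(L);
  std::vector<fvec> b(L), gamma(L), beta(L);
  std::vector<bool> has_drop(L, false);
  for (int i = 0; i < dropout_layers.size(); ++i) {
    const int l = dropout_layers[i] - 1;
    if (l >= 0 && l < L - 1) has_drop[l] = true;
  }
  for (int l = 0; l < L; ++l) {
    List pl = params[l];
    W[l] = as_fmat(pl["W"]); b[l] = as_fvec(pl["b"]);
    if (l < L - 1) { gamma[l] = as_fvec(pl["gamma"]); beta[l] = as_fvec(pl["beta"]); }
  }
  // ---- forward ----
  std::vector<fmat> A(L + 1), Zpre(L), Xhat(L), Drop(L);
  // cached im2col matrices, indexed [layer][sample]
  std::vector<std::vector<fmat>> Xcache(L, std::vector<fmat>(B));
  std::vector<fvec> invstd(L), bmean(L), bvar(L);
  A[0].set_size(N, 1);
  for (int s = 0; s < B; ++s)
    for (int v = 0; v < nv; ++v) A[0](s * nv + v, 0) = (float)x(v, s);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  for (int l = 0; l < L; ++l) {
    const int cout = W[l].n_cols;
    fmat Z(N, cout);
    for (int s = 0; s < B; ++s) {
      Xcache[l][s] = im2col(A[l].rows(s * nv, (s + 1) * nv - 1), nbr);
      Z.rows(s * nv, (s + 1) * nv - 1) = Xcache[l][s] * W[l];
    }
    Z.each_row() += b[l].t();
    if (l == L - 1) { A[l + 1] = Z; break; }
    Zpre[l] = Z;
    fmat R = Z;
    R.transform([](float z) { return z > 0.0f ? z : 0.0f; });
    // batch norm over all rows (batch x voxels), per channel
    bmean[l].set_size(cout); bvar[l].set_size(cout); invstd[l].set_size(cout);
    Xhat[l].set_size(N, cout);
    for (int c = 0; c < cout; ++c) {
      const float m = arma::mean(R.col(c));
      fvec d = R.col(c) - m;
      const float v2 = arma::dot(d, d) / N;
      bmean[l][c] = m; bvar[l][c] = v2;
      const float inv = 1.0f / std::sqrt(v2 + (float)bn_eps);
      invstd[l][c] = inv;
      Xhat[l].col(c) = d * inv;
      R.col(c) = Xhat[l].col(c) * gamma[l][c] + beta[l][c];
    }
    if (has_drop[l] && dropout_rate > 0.0) {
      const float scale = 1.0f / (1.0f - (float)dropout_rate);
      Drop[l].set_size(N, cout);
      for (int c = 0; c < cout; ++c)
        for (int i = 0; i < N; ++i)
          Drop[l](i, c) = unif(rng) < dropout_rate ? 0.0f : scale;
      R %= Drop[l];
    }
    A[l + 1] = R;
  }
  // ---- loss ----
  fmat diff(N, 1);
  for (int s = 0; s < B; ++s)
    for (int v = 0; v < nv; ++v)
      diff(s * nv + v, 0) = A[L](s * nv + v, 0) - (float)y(v, s);
  const double loss = arma::dot(diff.col(0), diff.col(0)) / N;
  // ---- backward ----
  List grads(L);
  fmat dA = diff * (2.0f / N);
  for (int l = L - 1; l >= 0; --l) {
    const int cout = W[l].n_cols;
    fmat dZ;
    fvec dgamma, dbeta;
    if (l == L - 1) {
      dZ = dA;
    } else {
      if (has_drop[l] && dropout_rate > 0.0) dA %= Drop[l];
      dgamma.set_size(cout); dbeta.set_size(cout);
      dZ.set_size(N, cout);
      for (int c = 0; c < cout; ++c) {
        fvec dxh = dA.col(c) * gamma[l][c];
        dgamma[c] = arma::dot(dA.col(c), Xhat[l].col(c));
        dbeta[c] = arma::accu(dA.col(c));
        const float sdxh = arma::accu(dxh);
        const float sdxx = arma::dot(dxh, Xhat[l].col(c));
        dZ.col(c) = (invstd[l][c] / N) * (N * dxh - sdxh - Xhat[l].col(c) * sdxx);
      }
      // ReLU mask
      for (int c = 0; c < cout; ++c) {
        float *dz = dZ.colptr(c);
        const float *zp = Zpre[l].colptr(c);
        for (int i = 0; i < N; ++i)
          if (zp[i] <= 0.0f) dz[i] = 0.0f;
      }
    }
    fmat dW(W[l].n_rows, cout, arma::fill::zeros);
    fvec db = arma::sum(dZ, 0).t();
    fmat dAprev(N, A[l].n_cols, arma::fill::zeros);
    for (int s = 0; s < B; ++s) {
      dW += Xcache[l][s].t() * dZ.rows(s * nv, (s + 1) * nv - 1);
      if (l > 0) {
        fmat dXs = dZ.rows(s * nv, (s + 1) * nv - 1) * W[l].t();
        fmat block(nv, A[l].n_cols, arma::fill::zeros);
        col2im_acc(dXs, nbr, block);
        dAprev.rows(s * nv, (s + 1) * nv - 1) = block;
      }
      Xcache[l][s].reset();
    }
    List gl;
    if (l == L - 1)
      gl = List::create(_["W"] = to_rmat(dW), _["b"] = to_rvec(db));
    else
      gl = List::create(_["W"] = to_rmat(dW), _["b"] = to_rvec(db),
                        _["gamma"] = to_rvec(dgamma), _["beta"] = to_rvec(dbeta));
    grads[l] = gl;
    if (l > 0) dA = dAprev;
  }
  List bstats(L - 1);
  for (int l = 0; l < L - 1; ++l)
    bstats[l] = List::create(_["mean"] = to_rvec(bmean[l]), _["var"] = to_rvec(bvar[l]));
  return List::create(_["loss"] = loss, _["grads"] = grads, _["bn_stats"] = bstats);
}
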