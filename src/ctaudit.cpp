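// Numerical core: separable Gaussian filtering, parallel-beam projection /
// back-projection, and the convolutional layer primitives used by the
// structure-predictor network. All grids are column-major H x W (x C).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gaussian filtering (separable, half-sample reflect boundary)
// ---------------------------------------------------------------------------

static arma::vec gauss_kernel(double sigma) {
  int r = (int)std::ceil(4.0 * sigma);
  if (r < 1) r = 1;
  arma::vec k(2 * r + 1);
  for (int i = -r; i <= r; ++i)
    k(i + r) = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
  return k / arma::accu(k);
}

static inline int reflect_idx(int i, int n) {
  // half-sample reflection: ... 1 0 | 0 1 ... n-1 | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static arma::mat conv1d_cols(const arma::mat& x, const arma::vec& k) {
  // filter along rows (i.e. down each column) with reflect boundary
  int H = x.n_rows, W = x.n_cols, r = ((int)k.n_elem - 1) / 2;
  arma::mat y(H, W, arma::fill::zeros);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t)
        acc += k(t + r) * x(reflect_idx(i + t, H), j);
      y(i, j) = acc;
    }
  }
  return y;
}

// [[Rcpp::export]]
arma::mat cpp_gauss_blur(const arma::mat& x, double sigma) {
  if (sigma <= 0) stop("sigma must be positive");
  arma::vec k = gauss_kernel(sigma);
  arma::mat tmp = conv1d_cols(x, k);
  return conv1d_cols(tmp.t(), k).t();
}

// Separable filtering with an arbitrary (odd-length) 1D kernel, reflect
// boundary; used by the SSIM window.
// [[Rcpp::export]]
arma::mat cpp_sep_filter(const arma::mat& x, const arma::vec& k) {
  if (k.n_elem % 2 == 0) stop("kernel length must be odd");
  arma::mat tmp = conv1d_cols(x, k);
  return conv1d_cols(tmp.t(), k).t();
}

// ---------------------------------------------------------------------------
// Parallel-beam Radon transform and pixel-driven back-projection
// ---------------------------------------------------------------------------

static inline double bilinear(const arma::mat& img, double row, double col) {
  int H = img.n_rows, W = img.n_cols;
  if (row < 0 || col < 0 || row > H - 1 || col > W - 1) return 0.0;
  int i0 = (int)std::floor(row), j0 = (int)std::floor(col);
  int i1 = std::min(i0 + 1, H - 1), j1 = std::min(j0 + 1, W - 1);
  double fi = row - i0, fj = col - j0;
  return (1 - fi) * ((1 - fj) * img(i0, j0) + fj * img(i0, j1)) +
         fi * ((1 - fj) * img(i1, j0) + fj * img(i1, j1));
}

// Line integrals (unit = pixel side); sinogram is n_det x n_angles,
// angles uniform over [0, pi).
// [[Rcpp::export]]
arma::mat cpp_radon(const arma::mat& img, int n_angles, int n_det) {
  int H = img.n_rows, W = img.n_cols;
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  double t0 = (n_det - 1) / 2.0;
  int n_steps = n_det;                      // ray length covers the grid
  double r0 = -(n_steps - 1) / 2.0;
  arma::mat sino(n_det, n_angles, arma::fill::zeros);
  for (int a = 0; a < n_angles; ++a) {
    double th = M_PI * a / n_angles, c = std::cos(th), s = std::sin(th);
    for (int d = 0; d < n_det; ++d) {
      double t = d - t0, acc = 0.0;
      for (int q = 0; q < n_steps; ++q) {
        double r = r0 + q;
        double x = t * c - r * s, y = t * s + r * c;
        acc += bilinear(img, cy + y, cx + x);
      }
      sino(d, a) = acc;
    }
  }
  return sino;
}

// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& sino, int H, int W) {
  int n_det = sino.n_rows, n_angles = sino.n_cols;
  double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0, t0 = (n_det - 1) / 2.0;
  arma::mat out(H, W, arma::fill::zeros);
  std::vector<double> cs(n_angles), sn(n_angles);
  for (int a = 0; a < n_angles; ++a) {
    double th = M_PI * a / n_angles;
    cs[a] = std::cos(th);
    sn[a] = std::sin(th);
  }
  for (int j = 0; j < W; ++j) {
    double x = j - cx;
    for (int i = 0; i < H; ++i) {
      double y = i - cy, acc = 0.0;
      for (int a = 0; a < n_angles; ++a) {
        double t = x * cs[a] + y * sn[a] + t0;
        if (t < 0 || t > n_det - 1) continue;
        int d0 = (int)std::floor(t);
        int d1 = std::min(d0 + 1, n_det - 1);
        double f = t - d0;
        acc += (1 - f) * sino(d0, a) + f * sino(d1, a);
      }
      out(i, j) = acc * M_PI / n_angles;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Convolutional network primitives (same-padding k x k conv, 2x2 max-pool,
// 2x nearest-neighbour upsampling). Weight layout: W is Cout x (Cin*k*k)
// with column index c*k*k + ky*k + kx for kernel offset (ky, kx).
// ---------------------------------------------------------------------------

// Patch matrix layout: (H*W) x (Cin*k*k); column index c*k*k + ky*k + kx.
// Each column is a zero-padded shifted copy of one input channel, written
// contiguously so the GEMM dominates the cost.
static arma::mat im2col(const arma::cube& x, int k) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices, pad = k / 2;
  arma::mat col((size_t)H * W, (size_t)C * k * k, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int dy = ky - pad, dx = kx - pad;
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        if (r1 <= r0 || c1 <= c0) continue;
        // alias the destination column as an H x W image (no copy)
        arma::mat dst(col.colptr((size_t)c * k * k + ky * k + kx),
                      H, W, false, true);
        dst.submat(r0, c0, r1 - 1, c1 - 1) =
          x.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx);
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wm,
                        const arma::vec& b, int k) {
  int H = x.n_rows, W = x.n_cols;
  int Cout = Wm.n_rows;
  arma::mat col = im2col(x, k);
  arma::cube out(H, W, Cout);
  arma::mat y(out.memptr(), (size_t)H * W, Cout, false, true);
  y = col * Wm.t();
  y.each_row() += b.t();
  return out;
}

// Forward pass that also returns the patch matrix for reuse in backward.
// [[Rcpp::export]]
List cpp_conv_fwd_cache(const arma::cube& x, const arma::mat& Wm,
                        const arma::vec& b, int k) {
  int H = x.n_rows, W = x.n_cols;
  int Cout = Wm.n_rows;
  arma::mat col = im2col(x, k);
  arma::cube out(H, W, Cout);
  arma::mat y(out.memptr(), (size_t)H * W, Cout, false, true);
  y = col * Wm.t();
  y.each_row() += b.t();
  return List::create(_["y"] = out, _["col"] = col);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& col, const arma::mat& Wm,
                  const arma::cube& dY, int k, int Cin) {
  int H = dY.n_rows, W = dY.n_cols, pad = k / 2;
  int Cout = Wm.n_rows;
  const arma::mat dYm(const_cast<double*>(dY.memptr()),
                      (size_t)H * W, Cout, false, true);
  arma::mat dW = dYm.t() * col;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dcol = dYm * Wm;              // (H*W) x (Cin*k*k)
  arma::cube dX(H, W, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int ky = 0; ky < k; ++ky) {
      for (int kx = 0; kx < k; ++kx) {
        int dy = ky - pad, dx = kx - pad;
        int r0 = std::max(0, -dy), r1 = std::min(H, H - dy);
        int c0 = std::max(0, -dx), c1 = std::min(W, W - dx);
        if (r1 <= r0 || c1 <= c0) continue;
        arma::mat src(dcol.colptr((size_t)c * k * k + ky * k + kx),
                      H, W, false, true);
        dX.slice(c).submat(r0 + dy, c0 + dx, r1 - 1 + dy, c1 - 1 + dx) +=
          src.submat(r0, c0, r1 - 1, c1 - 1);
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::cube idx(Ho, Wo, C);    // 0..3: which corner of the 2x2 block won
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double v00 = x(2 * i, 2 * j, c),     v10 = x(2 * i + 1, 2 * j, c);
        double v01 = x(2 * i, 2 * j + 1, c), v11 = x(2 * i + 1, 2 * j + 1, c);
        double best = v00; int w = 0;
        if (v10 > best) { best = v10; w = 1; }
        if (v01 > best) { best = v01; w = 2; }
        if (v11 > best) { best = v11; w = 3; }
        y(i, j, c) = best;
        idx(i, j, c) = (double)w;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dY, const arma::cube& idx) {
  int Ho = dY.n_rows, Wo = dY.n_cols, C = dY.n_slices;
  arma::cube dX(2 * Ho, 2 * Wo, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        int w = (int)(idx(i, j, c) + 0.5);
        dX(2 * i + (w & 1), 2 * j + (w >> 1), c) = dY(i, j, c);
      }
  return dX;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_fwd(const arma::cube& x) {
  int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;     y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bwd(const arma::cube& dY) {
  int H = dY.n_rows / 2, W = dY.n_cols / 2, C = dY.n_slices;
  arma::cube dX(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dX(i, j, c) = dY(2 * i, 2 * j, c) + dY(2 * i + 1, 2 * j, c) +
                      dY(2 * i, 2 * j + 1, c) + dY(2 * i + 1, 2 * j + 1, c);
  return dX;
}
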