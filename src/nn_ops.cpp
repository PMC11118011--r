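// Low-level numeric kernels: same-size 2-D convolution via im2col + GEMM,
// average pooling, and a polyline rasterizer for the synthetic renderer.
// Array layout follows R's column-major image convention (H, W, C, N).
#include <RcppArmadillo.h>
using namespace Rcpp;

// scatter-add counterpart of im2col (single image)
static void col2im_same(const arma::mat& cols, arma::cube& x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int si = i + di - pad;
            if (si < 0 || si >= H) continue;
            x(si, sj, c) += cols(row, j * H + i);
          }
        }
      }
    }
  }
}

// im2col over the whole image batch: cols is (k*k*C, H*W*N)
static void im2col_batch(const double* px, arma::mat& cols, int H, int W,
                         int C, int N, int k, int pad) {
  for (int n = 0; n < N; ++n) {
    const double* xn = px + static_cast<R_xlen_t>(n) * H * W * C;
    const int coloff = n * H * W;
    for (int c = 0; c < C; ++c) {
      const double* xc = xn + static_cast<R_xlen_t>(c) * H * W;
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          const int row = c * k * k + dj * k + di;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dj - pad;
            if (sj < 0 || sj >= W) continue;
            for (int i = 0; i < H; ++i) {
              const int si = i + di - pad;
              if (si < 0 || si >= H) continue;
              cols(row, coloff + j * H + i) = xc[sj * H + si];
            }
          }
        }
      }
    }
  }
}

// x: (H,W,C,N), w: (k,k,C,F), b: length F. Stride 1, zero pad = (k-1)/2.
// Optionally fuses a ReLU. Returns y: (H,W,F,N).
// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                        bool relu = false) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], F = dw[3], pad = (k - 1) / 2;
  if (dw[2] != C) stop("channel mismatch between input and kernel");
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  arma::mat cols(k * k * C, static_cast<size_t>(H) * W * N,
                 arma::fill::zeros);
  im2col_batch(x.begin(), cols, H, W, C, N, k, pad);
  arma::mat out = wm.t() * cols;                 // (F, HW*N)
  out.each_col() += arma::vec(const_cast<double*>(b.begin()), F, false, true);
  if (relu) out.transform([](double v) { return v > 0 ? v : 0.0; });
  NumericVector y(static_cast<R_xlen_t>(H) * W * F * N);
  y.attr("dim") = IntegerVector::create(H, W, F, N);
  const int HW = H * W;
  for (int n = 0; n < N; ++n) {
    double* py = y.begin() + static_cast<R_xlen_t>(n) * HW * F;
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < HW; ++p) py[f * HW + p] = out(f, n * HW + p);
  }
  return y;
}

// Backward pass. y is the forward output (used for the fused-ReLU mask
// when relu = true). Set need_dx = false to skip the input gradient (first
// layer). Returns list(dx, dw, db).
// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
               NumericVector y, bool relu = false, bool need_dx = true) {
  IntegerVector dxd = x.attr("dim"), dwd = w.attr("dim");
  const int H = dxd[0], W = dxd[1], C = dxd[2], N = dxd[3];
  const int k = dwd[0], F = dwd[3], pad = (k - 1) / 2;
  const int HW = H * W;
  arma::mat wm(const_cast<double*>(w.begin()), k * k * C, F, false, true);
  arma::mat cols(k * k * C, static_cast<size_t>(HW) * N, arma::fill::zeros);
  im2col_batch(x.begin(), cols, H, W, C, N, k, pad);
  arma::mat dout(F, static_cast<size_t>(HW) * N);
  for (int n = 0; n < N; ++n) {
    const double* pdy = dy.begin() + static_cast<R_xlen_t>(n) * HW * F;
    const double* pyv = y.begin() + static_cast<R_xlen_t>(n) * HW * F;
    for (int f = 0; f < F; ++f)
      for (int p = 0; p < HW; ++p) {
        double g = pdy[f * HW + p];
        if (relu && pyv[f * HW + p] <= 0) g = 0;
        dout(f, n * HW + p) = g;
      }
  }
  arma::mat dwm = cols * dout.t();               // (kkC, F)
  arma::vec db = arma::sum(dout, 1);
  NumericVector dxv;
  if (need_dx) {
    dxv = NumericVector(static_cast<R_xlen_t>(H) * W * C * N);
    dxv.attr("dim") = IntegerVector::create(H, W, C, N);
    arma::mat dcols = wm * dout;                 // (kkC, HW*N)
    for (int n = 0; n < N; ++n) {
      arma::cube dxs(H, W, C, arma::fill::zeros);
      col2im_same(dcols.cols(static_cast<size_t>(n) * HW,
                             static_cast<size_t>(n + 1) * HW - 1),
                  dxs, k, pad);
      std::copy(dxs.memptr(), dxs.memptr() + (R_xlen_t)H * W * C,
                dxv.begin() + static_cast<R_xlen_t>(n) * H * W * C);
    }
  }
  NumericVector dwv(dwm.memptr(), dwm.memptr() + dwm.n_elem);
  dwv.attr("dim") = dwd;
  return List::create(_["dx"] = dxv, _["dw"] = dwv,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Non-overlapping s x s average pooling on (H,W,C,N); H, W divisible by s.
// [[Rcpp::export]]
NumericVector avgpool_fw(NumericVector x, int s) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % s || W % s) stop("pooling window must tile the input exactly");
  const int Ho = H / s, Wo = W / s;
  NumericVector y(static_cast<R_xlen_t>(Ho) * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const double inv = 1.0 / (s * s);
  const double* px = x.begin();
  double* py = y.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* xp = px + cn * H * W;
    double* yp = py + cn * Ho * Wo;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double acc = 0;
        for (int jj = 0; jj < s; ++jj)
          for (int ii = 0; ii < s; ++ii)
            acc += xp[(j * s + jj) * H + i * s + ii];
        yp[j * Ho + i] = acc * inv;
      }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool_bw(NumericVector dy, int s, int H, int W) {
  IntegerVector d = dy.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx(static_cast<R_xlen_t>(H) * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double inv = 1.0 / (s * s);
  const double* py = dy.begin();
  double* px = dx.begin();
  for (R_xlen_t cn = 0; cn < static_cast<R_xlen_t>(C) * N; ++cn) {
    const double* yp = py + cn * Ho * Wo;
    double* xp = px + cn * H * W;
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const double g = yp[j * Ho + i] * inv;
        for (int jj = 0; jj < s; ++jj)
          for (int ii = 0; ii < s; ++ii)
            xp[(j * s + jj) * H + i * s + ii] += g;
      }
  }
  return dx;
}

// Rasterize thick line segments onto an H x W canvas (1 = ink).
// segs: n x 4 matrix, columns x0, y0, x1, y1 in pixel coordinates
// (x = column in [1, W], y = row in [1, H]). halfwidth in pixels.
// [[Rcpp::export]]
IntegerMatrix raster_segments(int H, int W, NumericMatrix segs,
                              double halfwidth) {
  IntegerMatrix img(H, W);
  const double hw2 = halfwidth * halfwidth;
  for (int srow = 0; srow < segs.nrow(); ++srow) {
    const double x0 = segs(srow, 0), y0 = segs(srow, 1);
    const double x1 = segs(srow, 2), y1 = segs(srow, 3);
    const double dx = x1 - x0, dy = y1 - y0;
    const double len2 = dx * dx + dy * dy;
    const int jlo = std::max(0, (int)std::floor(std::min(x0, x1) - halfwidth) - 1);
    const int jhi = std::min(W - 1, (int)std::ceil(std::max(x0, x1) + halfwidth));
    const int ilo = std::max(0, (int)std::floor(std::min(y0, y1) - halfwidth) - 1);
    const int ihi = std::min(H - 1, (int)std::ceil(std::max(y0, y1) + halfwidth));
    for (int j = jlo; j <= jhi; ++j) {
      const double px = j + 1;
      for (int i = ilo; i <= ihi; ++i) {
        const double py = i + 1;
        double t = 0;
        if (len2 > 0) {
          t = ((px - x0) * dx + (py - y0) * dy) / len2;
          t = std::min(1.0, std::max(0.0, t));
        }
        const double qx = x0 + t * dx - px, qy = y0 + t * dy - py;
        if (qx * qx + qy * qy <= hw2) img(i, j) = 1;
      }
    }
  }
  return img;
}
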