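#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Batched 2-D layer kernels for the package's compact CNN engine.
//
// A batch is an R matrix of dim N x (C*H*W); within a row the flat index of
// pixel (c, i, j) is c*H*W + i*W + j (channel-major, then row-major spatial).
// Weights for a conv layer are F x (C*kh*kw) with flat index
// c*kh*kw + ki*kw + kj. All convolutions are stride 1 with symmetric zero
// padding `pad`; pooling is 2x2 max with stride 2 (floor semantics).
// Per-sample rows are staged into contiguous buffers so the hot loops touch
// plain arrays. Everything is single-threaded and deterministic.

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericMatrix conv2d_fwd(NumericMatrix X, NumericMatrix Wt, NumericVector b,
                         int C, int H, int Wd, int kh, int kw, int pad) {
  const int N = X.nrow();
  const int F = Wt.nrow();
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = Wd + 2 * pad - kw + 1;
  NumericMatrix Y(N, F * Ho * Wo);
  std::vector<double> xbuf(C * H * Wd), ybuf(F * Ho * Wo);
  std::vector<double> wbuf((size_t)F * C * kh * kw);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < C * kh * kw; ++t)
      wbuf[(size_t)f * C * kh * kw + t] = Wt(f, t);

  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < C * H * Wd; ++t) xbuf[t] = X(n, t);
    for (int f = 0; f < F; ++f) {
      const double* wf = &wbuf[(size_t)f * C * kh * kw];
      double* yf = &ybuf[(size_t)f * Ho * Wo];
      const double bf = b[f];
      for (int t = 0; t < Ho * Wo; ++t) yf[t] = bf;
      for (int c = 0; c < C; ++c) {
        const double* xc = &xbuf[(size_t)c * H * Wd];
        const double* wc = &wf[(size_t)c * kh * kw];
        for (int ki = 0; ki < kh; ++ki) {
          for (int kj = 0; kj < kw; ++kj) {
            const double w = wc[ki * kw + kj];
            if (w == 0.0) continue;
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Ho, H + pad - ki);
            for (int io = i0; io < i1; ++io) {
              const int ii = io + ki - pad;
              const int j0 = std::max(0, pad - kj);
              const int j1 = std::min(Wo, Wd + pad - kj);
              const double* xr = &xc[ii * Wd + (j0 + kj - pad)];
              double* yr = &yf[io * Wo + j0];
              for (int t = 0; t < j1 - j0; ++t) yr[t] += w * xr[t];
            }
          }
        }
      }
    }
    for (int t = 0; t < F * Ho * Wo; ++t) Y(n, t) = ybuf[t];
  }
  return Y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericMatrix X, NumericMatrix Wt, NumericMatrix dY,
                int C, int H, int Wd, int kh, int kw, int pad) {
  const int N = X.nrow();
  const int F = Wt.nrow();
  const int Ho = H + 2 * pad - kh + 1;
  const int Wo = Wd + 2 * pad - kw + 1;
  NumericMatrix dX(N, C * H * Wd);
  NumericMatrix dW(F, C * kh * kw);
  NumericVector db(F);
  std::vector<double> xbuf(C * H * Wd), dxbuf(C * H * Wd), dybuf(F * Ho * Wo);
  std::vector<double> wbuf((size_t)F * C * kh * kw),
      dwbuf((size_t)F * C * kh * kw, 0.0);
  std::vector<double> dbbuf(F, 0.0);
  for (int f = 0; f < F; ++f)
    for (int t = 0; t < C * kh * kw; ++t)
      wbuf[(size_t)f * C * kh * kw + t] = Wt(f, t);

  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < C * H * Wd; ++t) { xbuf[t] = X(n, t); dxbuf[t] = 0.0; }
    for (int t = 0; t < F * Ho * Wo; ++t) dybuf[t] = dY(n, t);
    for (int f = 0; f < F; ++f) {
      const double* wf = &wbuf[(size_t)f * C * kh * kw];
      double* dwf = &dwbuf[(size_t)f * C * kh * kw];
      const double* gf = &dybuf[(size_t)f * Ho * Wo];
      for (int t = 0; t < Ho * Wo; ++t) dbbuf[f] += gf[t];
      for (int c = 0; c < C; ++c) {
        const double* xc = &xbuf[(size_t)c * H * Wd];
        double* dxc = &dxbuf[(size_t)c * H * Wd];
        const double* wc = &wf[(size_t)c * kh * kw];
        double* dwc = &dwf[(size_t)c * kh * kw];
        for (int ki = 0; ki < kh; ++ki) {
          for (int kj = 0; kj < kw; ++kj) {
            const double w = wc[ki * kw + kj];
            double dwacc = 0.0;
            const int i0 = std::max(0, pad - ki);
            const int i1 = std::min(Ho, H + pad - ki);
            for (int io = i0; io < i1; ++io) {
              const int ii = io + ki - pad;
              const int j0 = std::max(0, pad - kj);
              const int j1 = std::min(Wo, Wd + pad - kj);
              const double* xr = &xc[ii * Wd + (j0 + kj - pad)];
              double* dxr = &dxc[ii * Wd + (j0 + kj - pad)];
              const double* gr = &gf[io * Wo + j0];
              for (int t = 0; t < j1 - j0; ++t) {
                dwacc += gr[t] * xr[t];
                dxr[t] += gr[t] * w;
              }
            }
            dwc[ki * kw + kj] += dwacc;
          }
        }
      }
    }
    for (int t = 0; t < C * H * Wd; ++t) dX(n, t) = dxbuf[t];
  }
  for (int f = 0; f < F; ++f) {
    db[f] = dbbuf[f];
    for (int t = 0; t < C * kh * kw; ++t)
      dW(f, t) = dwbuf[(size_t)f * C * kh * kw + t];
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericMatrix X, int C, int H, int Wd) {
  const int N = X.nrow();
  const int Ho = H / 2, Wo = Wd / 2;
  NumericMatrix Y(N, C * Ho * Wo);
  IntegerMatrix idx(N, C * Ho * Wo);  // 0-based flat input index of the max
  std::vector<double> xbuf(C * H * Wd);
  for (int n = 0; n < N; ++n) {
    for (int t = 0; t < C * H * Wd; ++t) xbuf[t] = X(n, t);
    for (int c = 0; c < C; ++c) {
      for (int io = 0; io < Ho; ++io) {
        for (int jo = 0; jo < Wo; ++jo) {
          int best = c * H * Wd + (2 * io) * Wd + 2 * jo;
          double bv = xbuf[best];
          for (int di = 0; di < 2; ++di) {
            for (int dj = 0; dj < 2; ++dj) {
              const int k = c * H * Wd + (2 * io + di) * Wd + (2 * jo + dj);
              if (xbuf[k] > bv) { bv = xbuf[k]; best = k; }
            }
          }
          const int ko = c * Ho * Wo + io * Wo + jo;
          Y(n, ko) = bv;
          idx(n, ko) = best;
        }
      }
    }
  }
  return List::create(_["Y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericMatrix maxpool2_bwd(NumericMatrix dY, IntegerMatrix idx,
                           int C, int H, int Wd) {
  const int N = dY.nrow();
  NumericMatrix dX(N, C * H * Wd);
  const int M = dY.ncol();
  for (int n = 0; n < N; ++n)
    for (int k = 0; k < M; ++k)
      dX(n, idx(n, k)) += dY(n, k);
  return dX;
}
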