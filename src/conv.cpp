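#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cstring>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// "Same"-padding 2D convolution on maps stored as [C, H*W, B] (h fastest).
// Because H is small (12 and below) the h-axis is folded into the channel
// axis: the map is viewed as a [C*H, W*B] matrix and the kernel's kh
// vertical taps become a band-structured [Cout*H, C*H] weight matrix. A
// horizontal tap dw is then one contiguous shifted copy of the map (a
// single large memcpy per batch element) followed by one well-shaped
// dgemm, instead of kh*kw skinny products on scattered small copies.

namespace {

// buf [CH, W, B] <- X shifted by dw columns (zero padding at the edges)
void gather_w(const double* X, double* buf, int CH, int W, int B, int dw) {
  const int wlo = std::max(0, -dw), whi = std::min(W - 1, W - 1 - dw);
  for (int b = 0; b < B; ++b) {
    const double* xb = X + (size_t)b * CH * W;
    double* ob = buf + (size_t)b * CH * W;
    if (wlo > 0) std::memset(ob, 0, (size_t)wlo * CH * sizeof(double));
    if (whi >= wlo)
      std::memcpy(ob + (size_t)wlo * CH, xb + (size_t)(wlo + dw) * CH,
                  (size_t)(whi - wlo + 1) * CH * sizeof(double));
    if (whi < W - 1)
      std::memset(ob + (size_t)(whi + 1) * CH, 0,
                  (size_t)(W - 1 - whi) * CH * sizeof(double));
  }
}

// dX[:, w+dw, b] += g[:, w, b] over the valid range
void scatter_w(double* dX, const double* g, int CH, int W, int B, int dw) {
  const int wlo = std::max(0, -dw), whi = std::min(W - 1, W - 1 - dw);
  if (whi < wlo) return;
  const size_t run = (size_t)(whi - wlo + 1) * CH;
  for (int b = 0; b < B; ++b) {
    double* dst = dX + ((size_t)b * W + (wlo + dw)) * CH;
    const double* src = g + ((size_t)b * W + wlo) * CH;
    for (size_t i = 0; i < run; ++i) dst[i] += src[i];
  }
}

// Band-expand the vertical taps of horizontal tap dwi into big [CoutH, CH].
// Wt is [Cout, C, K] with K = kh*kw, k = dhi + dwi*kh, dh = dhi - kh/2.
void expand_w(const double* Wt, double* big, int Cout, int C, int H,
              int kh, int dwi) {
  const int hh = (kh - 1) / 2;
  const size_t CoutH = (size_t)Cout * H, CH = (size_t)C * H;
  std::memset(big, 0, CoutH * CH * sizeof(double));
  for (int dhi = 0; dhi < kh; ++dhi) {
    const int dh = dhi - hh;
    const double* wk = Wt + (size_t)(dhi + dwi * kh) * Cout * C;
    for (int ho = 0; ho < H; ++ho) {
      const int hs = ho + dh;
      if (hs < 0 || hs >= H) continue;
      for (int c = 0; c < C; ++c) {
        double* dst = big + (size_t)(c + hs * C) * CoutH + (size_t)ho * Cout;
        const double* src = wk + (size_t)c * Cout;
        for (int co = 0; co < Cout; ++co) dst[co] = src[co];
      }
    }
  }
}

// Contract a big gradient back onto the vertical taps of tap dwi.
void contract_w(double* dWt, const double* dbig, int Cout, int C, int H,
                int kh, int dwi) {
  const int hh = (kh - 1) / 2;
  const size_t CoutH = (size_t)Cout * H;
  for (int dhi = 0; dhi < kh; ++dhi) {
    const int dh = dhi - hh;
    double* wk = dWt + (size_t)(dhi + dwi * kh) * Cout * C;
    for (int ho = 0; ho < H; ++ho) {
      const int hs = ho + dh;
      if (hs < 0 || hs >= H) continue;
      for (int c = 0; c < C; ++c) {
        const double* src =
          dbig + (size_t)(c + hs * C) * CoutH + (size_t)ho * Cout;
        double* dst = wk + (size_t)c * Cout;
        for (int co = 0; co < Cout; ++co) dst[co] += src[co];
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector X, NumericVector Wt,
                           NumericVector bias, int kh, int kw,
                           int H, int W) {
  IntegerVector dx = X.attr("dim");
  int C = dx[0], P = dx[1], B = dx[2];
  IntegerVector dw_ = Wt.attr("dim");
  int Cout = dw_[0];
  if (dw_[1] != C || dw_[2] != kh * kw)
    stop("weight dimensions do not match input/kernel");
  if (P != H * W) stop("P != H*W");
  const int CH = C * H, CoutH = Cout * H, WB = W * B;
  const int hw = (kw - 1) / 2;
  NumericVector Y(Dimension(Cout, P, B));
  double* yp = REAL(Y);
  const double* bp = REAL(bias);
  for (size_t j = 0; j < (size_t)P * B; ++j)
    for (int c = 0; c < Cout; ++c) yp[j * Cout + c] = bp[c];
  std::vector<double> buf((size_t)CH * WB);
  std::vector<double> big((size_t)CoutH * CH);
  const double one = 1.0;
  for (int dwi = 0; dwi < kw; ++dwi) {
    expand_w(REAL(Wt), big.data(), Cout, C, H, kh, dwi);
    gather_w(REAL(X), buf.data(), CH, W, B, dwi - hw);
    F77_CALL(dgemm)("N", "N", &CoutH, &WB, &CH, &one, big.data(), &CoutH,
                    buf.data(), &CH, &one, yp, &CoutH FCONE FCONE);
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector dY, NumericVector X, NumericVector Wt,
                  int kh, int kw, int H, int W) {
  IntegerVector dx = X.attr("dim");
  int C = dx[0], P = dx[1], B = dx[2];
  IntegerVector dw_ = Wt.attr("dim");
  int Cout = dw_[0];
  const int CH = C * H, CoutH = Cout * H, WB = W * B;
  const int hw = (kw - 1) / 2;
  NumericVector dX(Dimension(C, P, B));
  NumericVector dWt(Dimension(Cout, C, kh * kw));
  NumericVector db(Cout);
  const double* dyp = REAL(dY);
  double* dbp = REAL(db);
  for (size_t j = 0; j < (size_t)P * B; ++j)
    for (int c = 0; c < Cout; ++c) dbp[c] += dyp[j * Cout + c];
  std::vector<double> buf((size_t)CH * WB);
  std::vector<double> big((size_t)CoutH * CH);
  std::vector<double> dbig((size_t)CoutH * CH);
  std::vector<double> dcol((size_t)CH * WB);
  const double one = 1.0, zero = 0.0;
  for (int dwi = 0; dwi < kw; ++dwi) {
    const int dw = dwi - hw;
    gather_w(REAL(X), buf.data(), CH, W, B, dw);
    // dBig = dY %*% t(buf)
    F77_CALL(dgemm)("N", "T", &CoutH, &CH, &WB, &one, dyp, &CoutH,
                    buf.data(), &CH, &zero, dbig.data(), &CoutH FCONE FCONE);
    contract_w(REAL(dWt), dbig.data(), Cout, C, H, kh, dwi);
    // dcol = t(Big) %*% dY
    expand_w(REAL(Wt), big.data(), Cout, C, H, kh, dwi);
    F77_CALL(dgemm)("T", "N", &CH, &WB, &CoutH, &one, big.data(), &CoutH,
                    dyp, &CoutH, &zero, dcol.data(), &CH FCONE FCONE);
    scatter_w(REAL(dX), dcol.data(), CH, W, B, dw);
  }
  return List::create(_["dX"] = dX, _["dW"] = dWt, _["db"] = db);
}
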